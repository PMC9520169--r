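#' Closed-set cross-entropy loss
#'
#' `-(1/B) sum_b log p(y_b | x_b)` over a labeled batch, natural log.
#'
#' @param p n x K probability matrix from the closed-set softmax head.
#' @param labels Integer labels in `0..K-1`.
#' @return A nonnegative scalar.
#' @export
loss_cross_entropy <- function(p, labels) {
  p <- as_prob_matrix(p)
  if (length(labels) != nrow(p)) abort("`labels` must match the batch size.")
  if (any(labels < 0 | labels >= ncol(p))) abort("labels must lie in 0..K-1.")
  -mean(clamp_log(p[cbind(seq_len(nrow(p)), labels + 1L)]))
}

#' One-vs-all (OVA) loss on labeled inliers
#'
#' For each labeled sample, the true-class OVA head is pushed toward
#' "inlier" and the hardest (most inlier-looking) non-true class toward
#' "outlier":
#' `(1/B) sum_b [ -log p_{y_b}(t=0|x_b) - min_{i != y_b} log p_i(t=1|x_b) ]`.
#'
#' @param p_ova0 n x K matrix of per-class inlier probabilities `p_j(t=0)`.
#' @param labels Integer labels in `0..K-1`; `K >= 2` is required (the
#'   hard-negative minimum needs a non-true class).
#' @return A nonnegative scalar.
#' @export
loss_ova <- function(p_ova0, labels) {
  p_ova0 <- as_prob_matrix(p_ova0, "p_ova0")
  K <- ncol(p_ova0)
  if (K < 2L) abort("OVA loss requires K >= 2 (no non-true class exists).")
  if (length(labels) != nrow(p_ova0)) abort("`labels` must match the batch size.")
  if (any(labels < 0 | labels >= K)) abort("labels must lie in 0..K-1.")
  terms <- vapply(seq_len(nrow(p_ova0)), function(b) {
    y <- labels[b] + 1L
    p1_other <- (1 - p_ova0[b, -y])
    -clamp_log(p_ova0[b, y]) - min(clamp_log(p1_other))
  }, numeric(1))
  mean(terms)
}

#' OVA loss on exposed outliers
#'
#' Every OVA head is pushed to call a known outlier an outlier:
#' `(1/|O|) sum_o (1/K) sum_j -log p_j(t=1|x_o)`.
#'
#' @param p_ova0 n x K inlier-probability matrix on the outlier batch.
#' @return A nonnegative scalar; an empty batch yields 0 with a warning.
#' @export
loss_ova_outlier <- function(p_ova0) {
  p_ova0 <- as_prob_matrix(p_ova0, "p_ova0")
  if (nrow(p_ova0) == 0) {
    warn("Empty outlier batch: OVA outlier loss is 0.")
    return(0)
  }
  -mean(rowMeans(matrix(clamp_log(1 - p_ova0), nrow(p_ova0))))
}

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' Entropy-minimization loss on unlabeled data
#'
#' Sum over classes of the binary entropy of each OVA pair, averaged over the
#' unlabeled batch; bounded by `K * log(2)`. Minimization pushes every OVA
#' decision on unlabeled data toward confidence.
#'
#' @param p_ova0 n x K inlier-probability matrix on the unlabeled batch.
#' @return A scalar in `[0, K log 2]`.
#' @export
loss_entropy_min <- function(p_ova0) {
  p_ova0 <- as_prob_matrix(p_ova0, "p_ova0")
  if (nrow(p_ova0) == 0) return(0)
  mean(rowSums(matrix(-xlogx(p_ova0) - xlogx(1 - p_ova0), nrow(p_ova0))))
}

#' Soft open-set consistency regularization (SOCR) loss
#'
#' Absolute difference of all OVA output pairs across two augmented views of
#' each unlabeled sample, summed over classes and both pair members and
#' averaged over the batch; bounded by `2K`.
#'
#' @param p_view1,p_view2 n x K inlier-probability matrices under
#'   augmentations A1 and A2 (rows aligned).
#' @return A scalar in `[0, 2K]`.
#' @export
loss_socr <- function(p_view1, p_view2) {
  p_view1 <- as_prob_matrix(p_view1, "p_view1")
  p_view2 <- as_prob_matrix(p_view2, "p_view2")
  if (!all(dim(p_view1) == dim(p_view2))) {
    abort("The two views must cover the same samples and classes.")
  }
  if (nrow(p_view1) == 0) return(0)
  # |p0 - p0'| + |p1 - p1'| = 2 |p0 - p0'| for complementary pairs
  mean(rowSums(matrix(2 * abs(p_view1 - p_view2), nrow(p_view1))))
}

#' Select pseudo-inliers from OpenMatch outputs
#'
#' `y_hat = argmax` of the closed-set probabilities; a sample is selected iff
#' the OVA head of that class calls it an inlier with confidence strictly
#' above `tau`: `p_{y_hat}(t=0 | u_b) > tau`.
#'
#' @param outputs A list with `p_closed`, `p_ova0` (and optionally
#'   `sample_id`), as from [forward_openmatch()].
#' @param tau Confidence threshold in (0, 1); default 0.95.
#' @return A tibble with `sample_id` and `pseudo_label`.
#' @export
select_pseudo_inliers_openmatch <- function(outputs, tau = 0.95) {
  p <- as_prob_matrix(outputs$p_closed, "p_closed")
  p0 <- as_prob_matrix(outputs$p_ova0, "p_ova0")
  if (nrow(p) == 0) return(tibble(sample_id = character(), pseudo_label = integer()))
  yhat <- max.col(p, ties.method = "first")
  conf <- p0[cbind(seq_len(nrow(p0)), yhat)]
  keep <- conf > tau
  tibble(
    sample_id = (outputs$sample_id %||% sprintf("s%04d", seq_len(nrow(p))))[keep],
    pseudo_label = (yhat - 1L)[keep]
  )
}

#' FixMatch consistency loss over a mu*B unlabeled batch
#'
#' Cross-entropy of the strong-view closed-set prediction at the pseudo
#' label, restricted to selected pseudo-inliers, normalized by the full
#' unlabeled batch size `mu_B` (unselected samples contribute 0):
#' `(1/mu_B) sum_b 1(selected_b) * (-log p(y_hat_b | A(u_b)))`.
#'
#' @param p_strong n x K closed-set probabilities on the strong views.
#' @param pseudo_labels Integer pseudo labels in `0..K-1` (ignored where not
#'   selected).
#' @param selected Logical selection mask of length n.
#' @param mu_B Normalizing batch size (defaults to `n`).
#' @return A nonnegative scalar.
#' @export
loss_fixmatch <- function(p_strong, pseudo_labels, selected, mu_B = nrow(p_strong)) {
  p_strong <- as_prob_matrix(p_strong, "p_strong")
  if (!any(selected)) return(0)
  idx <- cbind(which(selected), pseudo_labels[selected] + 1L)
  sum(-clamp_log(p_strong[idx])) / mu_B
}

#' OpenMatch open-set decision rule
#'
#' `y_hat = argmax` closed-set class; the outlier evidence is the OVA outlier
#' probability of that class, `p_{y_hat}(t=1)`. Scores at or above 0.5
#' resolve to unknown (ties conservatively reject).
#'
#' @inheritParams select_pseudo_inliers_openmatch
#' @return A tibble with `sample_id`, `pred_label`, `ood_score`.
#' @export
predict_openmatch <- function(outputs) {
  p <- as_prob_matrix(outputs$p_closed, "p_closed")
  p0 <- as_prob_matrix(outputs$p_ova0, "p_ova0")
  if (ncol(p) < 2L) abort("K >= 2 is required.")
  yhat <- max.col(p, ties.method = "first")
  score <- 1 - p0[cbind(seq_len(nrow(p0)), yhat)]
  tibble(
    sample_id = outputs$sample_id %||% sprintf("s%04d", seq_len(nrow(p))),
    pred_label = ifelse(score >= 0.5, label_unknown(), yhat - 1L),
    ood_score = score
  )
}
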
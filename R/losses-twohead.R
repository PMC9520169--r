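as_prob_matrix <- function(p, arg = "p") {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (!all(is.finite(p)) || any(p < 0)) {
    abort(sprintf("`%s` must be finite nonnegative probabilities.", arg))
  }
  p
}

clamp_log <- function(p) {
  if (any(p < 1e-12)) {
    warn("Probability at true label clamped to 1e-12 in cross-entropy.")
    p <- pmax(p, 1e-12)
  }
  log(p)
}

#' Two-head cross-entropy loss
#'
#' Mean over the batch of the summed negative log-likelihood of the true
#' label under both softmax heads (natural log):
#' `-(1/|X|) sum_b sum_{i=1,2} log p_i(y_b | x_b)`.
#'
#' @param p1,p2 n x K probability matrices from the two heads.
#' @param labels Integer vector of true labels in `0..K-1`.
#' @return A nonnegative scalar.
#' @export
loss_cross_entropy_two <- function(p1, p2, labels) {
  p1 <- as_prob_matrix(p1, "p1"); p2 <- as_prob_matrix(p2, "p2")
  if (length(labels) != nrow(p1)) abort("`labels` must match the batch size.")
  if (any(labels < 0 | labels >= ncol(p1))) abort("labels must lie in 0..K-1.")
  idx <- cbind(seq_len(nrow(p1)), labels + 1L)
  -mean(clamp_log(p1[idx]) + clamp_log(p2[idx]))
}

#' L1 discrepancy between two probability vectors
#'
#' `sum_i |p1_i - p2_i|`; lies in `[0, 2]` for probability vectors. This is
#' the per-sample outlier evidence of the two-head network.
#'
#' @param p1,p2 Probability vectors of equal length.
#' @return A scalar in `[0, 2]`.
#' @export
#' @examples
#' discrepancy_l1(c(0.6, 0.4), c(0.5, 0.5))
discrepancy_l1 <- function(p1, p2) {
  if (length(p1) != length(p2)) abort("`p1` and `p2` must have equal length.")
  sum(abs(p1 - p2))
}

discrepancy_rows <- function(P1, P2) rowSums(abs(P1 - P2))

#' Margin hinge on the mean inter-head discrepancy over an outlier batch
#'
#' `max(margin - mean_o d(p1, p2), 0)`. Minimizing this during fine-tuning
#' drives the mean discrepancy on exposed outliers up toward the margin,
#' while the hinge floor at 0 prevents unbounded divergence (overfitting to
#' the exposure set).
#'
#' @param p1,p2 n x K probability matrices on the outlier batch.
#' @param margin Nonnegative margin `m` (default 1.2).
#' @return A scalar in `[0, margin]`.
#' @export
loss_discrepancy <- function(p1, p2, margin = 1.2) {
  p1 <- as_prob_matrix(p1, "p1"); p2 <- as_prob_matrix(p2, "p2")
  if (nrow(p1) == 0) abort("Outlier batch must be nonempty.")
  if (margin < 0) abort("`margin` must be >= 0.")
  max(margin - mean(discrepancy_rows(p1, p2)), 0)
}

#' Two-head open-set decision rule
#'
#' A sample receives the shared argmax label only when (i) both heads agree
#' on the argmax, (ii) the L1 discrepancy is below `theta_d`, and (iii) both
#' heads are confident (`min(max p1, max p2) >= theta_p`); otherwise it is
#' declared unknown. The discrepancy itself is returned as `ood_score`.
#'
#' @param outputs A list with `p1`, `p2` (and optionally `sample_id`), as
#'   returned by [forward_twohead()].
#' @param theta_p Confidence threshold (default 0.95).
#' @param theta_d Discrepancy threshold in (0, 1), typically from
#'   [grid_search_theta_d()].
#' @return A tibble with `sample_id` (if available), `pred_label`
#'   ([label_unknown()] for rejections) and `ood_score`.
#' @export
predict_twohead <- function(outputs, theta_p = 0.95, theta_d = 0.5) {
  p1 <- as_prob_matrix(outputs$p1, "p1"); p2 <- as_prob_matrix(outputs$p2, "p2")
  a1 <- max.col(p1, ties.method = "first")
  a2 <- max.col(p2, ties.method = "first")
  m1 <- p1[cbind(seq_len(nrow(p1)), a1)]
  m2 <- p2[cbind(seq_len(nrow(p2)), a2)]
  score <- discrepancy_rows(p1, p2)
  unknown <- (a1 != a2) | (score >= theta_d) | (pmin(m1, m2) < theta_p)
  tibble(
    sample_id = outputs$sample_id %||% sprintf("s%04d", seq_len(nrow(p1))),
    pred_label = ifelse(unknown, label_unknown(), a1 - 1L),
    ood_score = score
  )
}

#' Grid search for the discrepancy threshold
#'
#' Evaluates `theta` over the 99-point grid `0.01, 0.02, ..., 0.99` with the
#' detection rule `score >= theta => outlier` and returns the smallest grid
#' point maximizing detection accuracy.
#'
#' @param scores Numeric outlier scores (higher = more outlier-like).
#' @param is_outlier Logical ground truth, same length.
#' @return The selected threshold.
#' @export
grid_search_theta_d <- function(scores, is_outlier) {
  if (length(scores) != length(is_outlier)) abort("Inputs must have equal length.")
  if (length(unique(is_outlier)) < 2L) {
    abort("Grid search needs both inliers and outliers.")
  }
  grid <- seq(0.01, 0.99, by = 0.01)
  acc <- vapply(grid, function(th) mean((scores >= th) == is_outlier), numeric(1))
  grid[which.max(acc)]
}

#' Select pseudo-inliers from two-head outputs on unlabeled data
#'
#' High-confidence pseudo-inliers are the unlabeled samples whose heads agree
#' on the argmax, whose discrepancy is strictly below `theta_d`, and whose
#' per-head confidence clears `theta_p`. The shared argmax becomes the pseudo
#' label used by FixMatch.
#'
#' @inheritParams predict_twohead
#' @return A tibble with `sample_id` and `pseudo_label` for selected rows.
#' @export
select_pseudo_inliers_twohead <- function(outputs, theta_p = 0.95, theta_d = 0.5) {
  p1 <- as_prob_matrix(outputs$p1, "p1"); p2 <- as_prob_matrix(outputs$p2, "p2")
  if (nrow(p1) == 0) {
    return(tibble(sample_id = character(), pseudo_label = integer()))
  }
  a1 <- max.col(p1, ties.method = "first")
  a2 <- max.col(p2, ties.method = "first")
  m1 <- p1[cbind(seq_len(nrow(p1)), a1)]
  m2 <- p2[cbind(seq_len(nrow(p2)), a2)]
  score <- discrepancy_rows(p1, p2)
  keep <- (a1 == a2) & (score < theta_d) & (pmin(m1, m2) >= theta_p)
  tibble(
    sample_id = (outputs$sample_id %||% sprintf("s%04d", seq_len(nrow(p1))))[keep],
    pseudo_label = (a1 - 1L)[keep]
  )
}
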
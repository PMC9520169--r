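#' Configuration for FixMatch with contrastive regularization
#'
#' @param m_aug Strong-augmented views pooled per pseudo-inlier (>= 1);
#'   default 2.
#' @param temperature Temperature `T` of the contrastive loss (> 0); default
#'   0.07, the usual contrastive-learning scale.
#' @param enabled Set `FALSE` to disable the contrastive term (FixMatch
#'   consistency only).
#' @return A `fixmatch_cr_config` list.
#' @export
fixmatch_cr_config <- function(m_aug = 2L, temperature = 0.07, enabled = TRUE) {
  if (!is.numeric(m_aug) || m_aug < 1) abort("`m_aug` must be a count >= 1.")
  if (!is.numeric(temperature) || temperature <= 0) {
    abort("`temperature` must be > 0.")
  }
  structure(list(m_aug = as.integer(m_aug), temperature = temperature,
                 enabled = isTRUE(enabled)),
            class = "fixmatch_cr_config")
}

#' Build a pool of strong-augmented pseudo-inlier embeddings
#'
#' Each pseudo-inlier contributes exactly `m_aug` strong-augmented views,
#' passed through the backbone and the L2-normalizing projection head; the
#' pseudo label is copied onto every view. The pool is where contrastive
#' positives (same pseudo label) and negatives (different) live.
#'
#' @param samples Bundle rows for the selected pseudo-inliers.
#' @param pseudo_labels Integer pseudo labels aligned with `samples`.
#' @param m_aug Views per pseudo-inlier.
#' @param strong_policy A strong [augmentation_policy()] (ignored for feature
#'   data, whose views are identity copies).
#' @param net The `osr_network` providing backbone and projection head.
#' @return A `contrastive_pool`: a tibble with `origin_id`, `pseudo_label`
#'   and an `embedding` list-column of unit-norm vectors.
#' @export
build_contrastive_pool <- function(samples, pseudo_labels, m_aug, strong_policy,
                                   net) {
  if (nrow(samples) == 0) {
    out <- tibble(origin_id = character(), pseudo_label = integer(),
                  embedding = list())
    return(structure(out, class = c("contrastive_pool", class(out))))
  }
  if (m_aug < 1) abort("`m_aug` must be >= 1.")
  views <- samples[rep(seq_len(nrow(samples)), each = m_aug), , drop = FALSE]
  if ("pixels" %in% names(views)) {
    views$pixels <- lapply(views$pixels, function(px) {
      aug_pixels(strong_augment(px, strong_policy))
    })
  }
  bb <- forward_backbone(net$params, design_matrix(net, views))
  proj <- forward_projection_raw(net$params, bb$E)
  out <- tibble(
    origin_id = views$sample_id,
    pseudo_label = rep(as.integer(pseudo_labels), each = m_aug),
    embedding = lapply(seq_len(nrow(proj$Z)), function(i) proj$Z[i, ])
  )
  structure(out, class = c("contrastive_pool", class(out)))
}

pool_matrix_z <- function(pool) do.call(rbind, pool$embedding)

#' Contrastive loss of one pool entry
#'
#' With positives `P(u') = ` other entries sharing the anchor's pseudo label,
#' returns `-(1/|P|) sum_{p in P} log[ exp(<z_u, z_p>/T) /
#' sum_{v != u} exp(<z_u, z_v>/T) ]`; the denominator runs over the whole
#' pool minus the anchor. Entries with no positive partner are skipped
#' (contribute 0 and are excluded from the pool mean).
#'
#' @param pool A `contrastive_pool` of size >= 2.
#' @param index 1-based entry index of the anchor.
#' @param temperature Temperature `T` (> 0).
#' @return A nonnegative scalar.
#' @export
contrastive_loss_sample <- function(pool, index, temperature = 0.07) {
  n <- nrow(pool)
  if (n < 2L) abort("Contrastive loss needs a pool of size >= 2.")
  Z <- pool_matrix_z(pool)
  q <- pool$pseudo_label
  pos <- setdiff(which(q == q[index]), index)
  if (length(pos) == 0L) return(0)
  sims <- drop(Z[-index, , drop = FALSE] %*% Z[index, ]) / temperature
  lse <- max(sims) + log(sum(exp(sims - max(sims))))
  sims_all <- drop(Z %*% Z[index, ]) / temperature
  -mean(sims_all[pos] - lse)
}

#' Mean contrastive loss over a pool
#'
#' Average of [contrastive_loss_sample()] over entries that have at least one
#' positive partner; 0 (with a warning) when no entry has positives.
#'
#' @inheritParams contrastive_loss_sample
#' @return A nonnegative scalar.
#' @export
contrastive_loss_pool <- function(pool, temperature = 0.07) {
  n <- nrow(pool)
  if (n < 2L) abort("Contrastive loss needs a pool of size >= 2.")
  has_pos <- vapply(seq_len(n), function(i) {
    sum(pool$pseudo_label == pool$pseudo_label[i]) > 1L
  }, logical(1))
  if (!any(has_pos)) {
    warn("No pool entry has a positive partner: contrastive loss is 0.")
    return(0)
  }
  losses <- vapply(which(has_pos), contrastive_loss_sample,
                   numeric(1), pool = pool, temperature = temperature)
  mean(losses)
}

# Gradient of the mean pool contrastive loss w.r.t. the embedding matrix Z
# (rows unit-norm). Returns dL/dZ; the normalization back through the
# projection head is handled by projection_backward().
contrastive_grad_z <- function(Z, q, temperature) {
  n <- nrow(Z)
  dZ <- matrix(0, n, ncol(Z))
  has_pos <- vapply(seq_len(n), function(i) sum(q == q[i]) > 1L, logical(1))
  n_active <- sum(has_pos)
  if (n_active == 0L) return(dZ)
  S <- Z %*% t(Z) / temperature
  for (u in which(has_pos)) {
    pos <- setdiff(which(q == q[u]), u)
    others <- setdiff(seq_len(n), u)
    s <- S[u, others]
    sm <- exp(s - max(s)); sm <- sm / sum(sm)
    # dL_u/ds_{uv} = (softmax_v - 1(v in P)/|P|) / n_active (temperature
    # already folded into S's scale below)
    g <- sm
    g[match(pos, others)] <- g[match(pos, others)] - 1 / length(pos)
    g <- g / (temperature * n_active)
    dZ[u, ] <- dZ[u, ] + drop(g %*% Z[others, , drop = FALSE])
    dZ[others, ] <- dZ[others, ] + outer(g, Z[u, ])
  }
  dZ
}
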
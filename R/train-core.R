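# Internal training machinery: per-loss gradient computations over the
# network's parameter list, plain SGD, and batch plumbing. All losses here
# mirror the exported loss_* functions; tests check the two routes agree.

clamp01 <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

# Apply an augmentation view to bundle rows. Feature data: weak = identity,
# strong = small isotropic jitter (documented desk-scale convention).
augment_rows <- function(rows, kind, policy) {
  if (nrow(rows) == 0) return(rows)
  if ("features" %in% names(rows)) {
    if (kind == "strong") {
      rows$features <- lapply(rows$features, function(f) f + rnorm(length(f), sd = 0.1))
    }
    return(rows)
  }
  rows$pixels <- lapply(rows$pixels, function(px) {
    if (kind == "weak") {
      aug_pixels(weak_augment(px, policy))
    } else {
      aug_pixels(strong_augment(px, policy))
    }
  })
  rows
}

minibatches <- function(n, size) {
  if (n == 0) return(list())
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / size))
}

# Cross-entropy through a softmax head; returns head + embedding gradients.
ce_head_grads <- function(E, P, labels, W, weight) {
  n <- nrow(P)
  Y <- matrix(0, n, ncol(P))
  Y[cbind(seq_len(n), labels + 1L)] <- 1
  dlog <- (P - Y) * (weight / n)
  list(dW = crossprod(E, dlog), db = colSums(dlog), dE = dlog %*% t(W))
}

# Summed two-head cross-entropy on weak-augmented labeled rows.
grads_ce_two <- function(net, rows, policy, weight = 1) {
  rows <- augment_rows(rows, "weak", policy)
  bb <- forward_backbone(net$params, design_matrix(net, rows))
  P1 <- head_softmax(bb$E, net$params$Wh1, net$params$bh1)
  P2 <- head_softmax(bb$E, net$params$Wh2, net$params$bh2)
  g1 <- ce_head_grads(bb$E, P1, rows$label, net$params$Wh1, weight)
  g2 <- ce_head_grads(bb$E, P2, rows$label, net$params$Wh2, weight)
  grads <- backbone_backward(net$params, bb, g1$dE + g2$dE)
  grads$Wh1 <- g1$dW; grads$bh1 <- g1$db
  grads$Wh2 <- g2$dW; grads$bh2 <- g2$db
  idx <- cbind(seq_len(nrow(P1)), rows$label + 1L)
  list(grads = grads,
       loss = -mean(log(clamp01(P1[idx])) + log(clamp01(P2[idx]))) * weight)
}

# Margin hinge on the mean inter-head discrepancy of an outlier batch.
grads_discrepancy <- function(net, rows, policy, margin, weight = 1) {
  rows <- augment_rows(rows, "weak", policy)
  bb <- forward_backbone(net$params, design_matrix(net, rows))
  P1 <- head_softmax(bb$E, net$params$Wh1, net$params$bh1)
  P2 <- head_softmax(bb$E, net$params$Wh2, net$params$bh2)
  mean_d <- mean(discrepancy_rows(P1, P2))
  if (mean_d >= margin) return(list(grads = NULL, loss = 0))
  n <- nrow(P1)
  s <- sign(P1 - P2)
  dP1 <- -s * (weight / n)
  dP2 <- s * (weight / n)
  dl1 <- softmax_backward(P1, dP1)
  dl2 <- softmax_backward(P2, dP2)
  grads <- backbone_backward(net$params, bb,
                             dl1 %*% t(net$params$Wh1) + dl2 %*% t(net$params$Wh2))
  grads$Wh1 <- crossprod(bb$E, dl1); grads$bh1 <- colSums(dl1)
  grads$Wh2 <- crossprod(bb$E, dl2); grads$bh2 <- colSums(dl2)
  list(grads = grads, loss = (margin - mean_d) * weight)
}

# Closed-set cross-entropy + OVA hard-negative loss on labeled rows.
grads_openmatch_labeled <- function(net, rows, policy, weight = 1) {
  rows <- augment_rows(rows, "weak", policy)
  bb <- forward_backbone(net$params, design_matrix(net, rows))
  P <- head_softmax(bb$E, net$params$Wc, net$params$bc)
  P0 <- head_ova(bb$E, net$params$Wo, net$params$bo)
  n <- nrow(P)
  gc <- ce_head_grads(bb$E, P, rows$label, net$params$Wc, weight)
  # OVA: -log p0[true] and -log(1 - p0[hardest non-true])
  g0 <- matrix(0, n, net$K)
  for (b in seq_len(n)) {
    y <- rows$label[b] + 1L
    g0[b, y] <- g0[b, y] - 1 / clamp01(P0[b, y])
    others <- setdiff(seq_len(net$K), y)
    jstar <- others[which.max(P0[b, others])]
    g0[b, jstar] <- g0[b, jstar] + 1 / clamp01(1 - P0[b, jstar])
  }
  g0 <- g0 * (weight / n)
  dlo <- ova_backward(P0, g0, matrix(0, n, net$K))
  grads <- backbone_backward(net$params, bb, gc$dE + dlo %*% t(net$params$Wo))
  grads$Wc <- gc$dW; grads$bc <- gc$db
  grads$Wo <- crossprod(bb$E, dlo); grads$bo <- colSums(dlo)
  loss <- loss_cross_entropy(P, rows$label) + loss_ova(P0, rows$label)
  list(grads = grads, loss = loss * weight)
}

# Stage-1 OoD exposure: all OVA heads pushed to "outlier" on known outliers.
grads_ova_outlier <- function(net, rows, policy, weight = 1) {
  rows <- augment_rows(rows, "weak", policy)
  bb <- forward_backbone(net$params, design_matrix(net, rows))
  P0 <- head_ova(bb$E, net$params$Wo, net$params$bo)
  n <- nrow(P0)
  g0 <- (1 / clamp01(1 - P0)) * (weight / (n * net$K))
  dlo <- ova_backward(P0, g0, matrix(0, n, net$K))
  grads <- backbone_backward(net$params, bb, dlo %*% t(net$params$Wo))
  grads$Wo <- crossprod(bb$E, dlo); grads$bo <- colSums(dlo)
  list(grads = grads, loss = loss_ova_outlier(P0) * weight)
}

# Entropy minimization (view 1) + SOCR (across two weak views) on an
# unlabeled batch; weights folded per term.
grads_unlabeled_ova <- function(net, rows, policy, lambda_em, lambda_oc) {
  v1 <- augment_rows(rows, "weak", policy)
  v2 <- augment_rows(rows, "weak", policy)
  bb1 <- forward_backbone(net$params, design_matrix(net, v1))
  bb2 <- forward_backbone(net$params, design_matrix(net, v2))
  P01 <- head_ova(bb1$E, net$params$Wo, net$params$bo)
  P02 <- head_ova(bb2$E, net$params$Wo, net$params$bo)
  n <- nrow(P01)
  p1c <- clamp01(P01)
  g0_em <- log((1 - p1c) / p1c) * (lambda_em / n)
  s <- sign(P01 - P02)
  g0_oc1 <- 2 * s * (lambda_oc / n)
  g0_oc2 <- -2 * s * (lambda_oc / n)
  dlo1 <- ova_backward(P01, g0_em + g0_oc1, matrix(0, n, net$K))
  dlo2 <- ova_backward(P02, g0_oc2, matrix(0, n, net$K))
  grads <- backbone_backward(net$params, bb1, dlo1 %*% t(net$params$Wo))
  grads <- grad_accumulate(grads,
                           backbone_backward(net$params, bb2, dlo2 %*% t(net$params$Wo)))
  grads$Wo <- crossprod(bb1$E, dlo1) + crossprod(bb2$E, dlo2)
  grads$bo <- colSums(dlo1) + colSums(dlo2)
  list(grads = grads,
       loss_em = loss_entropy_min(P01) * lambda_em,
       loss_oc = loss_socr(P01, P02) * lambda_oc,
       outputs_view1 = list(bb = bb1, P0 = P01))
}

# FixMatch cross-entropy on strong views of selected pseudo-inliers, for one
# softmax head identified by (Wname, bname); normalized by mu_B.
grads_fixmatch_head <- function(net, rows, pseudo_labels, policy, Wname, bname,
                                mu_B, weight = 1) {
  rows <- augment_rows(rows, "strong", policy)
  bb <- forward_backbone(net$params, design_matrix(net, rows))
  P <- head_softmax(bb$E, net$params[[Wname]], net$params[[bname]])
  n <- nrow(P)
  Y <- matrix(0, n, ncol(P))
  Y[cbind(seq_len(n), pseudo_labels + 1L)] <- 1
  dlog <- (P - Y) * (weight / mu_B)
  grads <- backbone_backward(net$params, bb, dlog %*% t(net$params[[Wname]]))
  grads[[Wname]] <- crossprod(bb$E, dlog)
  grads[[bname]] <- colSums(dlog)
  idx <- cbind(seq_len(n), pseudo_labels + 1L)
  list(grads = grads, loss = sum(-log(clamp01(P[idx]))) * weight / mu_B)
}

# Contrastive regularization over a within-batch pool of m_aug strong views
# per pseudo-inlier. Gradient flows to projection head and backbone only.
grads_contrastive <- function(net, rows, pseudo_labels, policy, fixmatch_cfg,
                              weight = 1) {
  m_aug <- fixmatch_cfg$m_aug
  views <- rows[rep(seq_len(nrow(rows)), each = m_aug), , drop = FALSE]
  q <- rep(as.integer(pseudo_labels), each = m_aug)
  views <- augment_rows(views, "strong", policy)
  bb <- forward_backbone(net$params, design_matrix(net, views))
  proj <- forward_projection_raw(net$params, bb$E)
  if (nrow(proj$Z) < 2L || !any(duplicated(q))) {
    return(list(grads = NULL, loss = 0))
  }
  pool <- structure(
    tibble(origin_id = views$sample_id, pseudo_label = q,
           embedding = lapply(seq_len(nrow(proj$Z)), function(i) proj$Z[i, ])),
    class = c("contrastive_pool", class(tibble()))
  )
  loss <- contrastive_loss_pool(pool, fixmatch_cfg$temperature)
  dZ <- contrastive_grad_z(proj$Z, q, fixmatch_cfg$temperature) * weight
  dV <- projection_backward(proj, dZ)
  grads <- backbone_backward(net$params, bb, dV %*% t(net$params$Wp))
  grads$Wp <- crossprod(bb$E, dV)
  grads$bp <- colSums(dV)
  list(grads = grads, loss = loss * weight)
}

# Momentum SGD (momentum 0.9, the usual convention for vision backbones);
# velocity lives in the network's optimizer environment so it persists
# across batches within a training stage.
apply_grads <- function(net, gradsets, lr, momentum = 0.9) {
  total <- list()
  for (g in gradsets) if (!is.null(g)) total <- grad_accumulate(total, g)
  vel <- net$opt$velocity
  for (nm in names(total)) {
    v_old <- vel[[nm]]
    vel[[nm]] <- if (is.null(v_old)) total[[nm]] else momentum * v_old + total[[nm]]
    net$params[[nm]] <- net$params[[nm]] - lr * vel[[nm]]
  }
  net$opt$velocity <- vel
  net
}

reset_optimizer <- function(net) {
  net$opt$velocity <- list()
  net
}
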
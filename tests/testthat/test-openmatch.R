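# Literal term-by-term transcriptions of the OVA-family losses.
oracle_ce <- function(p, labels) {
  s <- 0
  for (b in seq_len(nrow(p))) s <- s - log(p[b, labels[b] + 1])
  s / nrow(p)
}
oracle_ova <- function(p0, labels) {
  s <- 0
  for (b in seq_len(nrow(p0))) {
    y <- labels[b] + 1
    worst <- Inf
    for (i in seq_len(ncol(p0))) {
      if (i != y) worst <- min(worst, log(1 - p0[b, i]))
    }
    s <- s - log(p0[b, y]) - worst
  }
  s / nrow(p0)
}
oracle_ova_out <- function(p0) {
  s <- 0
  for (b in seq_len(nrow(p0))) {
    for (j in seq_len(ncol(p0))) s <- s - log(1 - p0[b, j]) / ncol(p0)
  }
  s / nrow(p0)
}
oracle_entropy <- function(p0) {
  h <- function(p) {
    out <- 0
    for (q in c(p, 1 - p)) if (q > 0) out <- out - q * log(q)
    out
  }
  s <- 0
  for (b in seq_len(nrow(p0))) for (j in seq_len(ncol(p0))) s <- s + h(p0[b, j])
  s / nrow(p0)
}
oracle_socr <- function(pa, pb) {
  s <- 0
  for (b in seq_len(nrow(pa))) {
    for (j in seq_len(ncol(pa))) {
      s <- s + abs(pa[b, j] - pb[b, j]) + abs((1 - pa[b, j]) - (1 - pb[b, j]))
    }
  }
  s / nrow(pa)
}

test_that("closed-set cross-entropy: hand value and oracle", {
  expect_equal(loss_cross_entropy(matrix(c(1, 0), 1), 0L), 0)
  expect_equal(loss_cross_entropy(matrix(c(exp(-2), 1 - exp(-2)), 1), 0L), 2)
  set.seed(5)
  for (i in 1:10) {
    n <- sample(1:4, 1); K <- sample(2:3, 1)
    p <- random_prob(n, K); y <- sample(0:(K - 1), n, replace = TRUE)
    expect_equal(loss_cross_entropy(p, y), oracle_ce(p, y), tolerance = 1e-10)
  }
})

test_that("OVA loss: perfect case, hand values, hard-negative min, oracle", {
  perfect <- matrix(c(1, 0, 0), 1)  # p0: true class inlier prob 1, others 0
  expect_equal(loss_ova(perfect, 0L), 0)
  expect_equal(loss_ova(matrix(c(0.5, 0.5), 1), 0L), 2 * log(2),
               tolerance = 1e-12)
  # K = 3 worked case: y = 0, p0 = (0.8, 0.1, 0.4) so p(t=1) = (_, 0.9, 0.6);
  # the min picks class 2 (log 0.6 < log 0.9)
  expect_equal(loss_ova(matrix(c(0.8, 0.1, 0.4), 1), 0L),
               -log(0.8) - log(0.6), tolerance = 1e-12)
  expect_error(loss_ova(matrix(0.5, 1, 1), 0L), "K >= 2")
  set.seed(6)
  for (i in 1:10) {
    n <- sample(1:4, 1); K <- sample(2:3, 1)
    p0 <- random_ova(n, K); y <- sample(0:(K - 1), n, replace = TRUE)
    expect_equal(loss_ova(p0, y), oracle_ova(p0, y), tolerance = 1e-10)
  }
})

test_that("OVA outlier loss: hand value, monotonicity, empty batch", {
  expect_equal(loss_ova_outlier(matrix(0, 1, 2)), 0)  # p(t=1) = 1 everywhere
  # both heads at p(t=1) = exp(-1)
  p0 <- matrix(1 - exp(-1), 1, 2)
  expect_equal(loss_ova_outlier(p0), 1, tolerance = 1e-12)
  expect_warning(v <- loss_ova_outlier(matrix(numeric(0), 0, 2)), "Empty")
  expect_equal(v, 0)
  # decreases as any p(t=1) increases
  lo <- loss_ova_outlier(matrix(c(0.4, 0.3), 1))
  hi <- loss_ova_outlier(matrix(c(0.3, 0.3), 1))
  expect_lt(hi, lo)
  set.seed(7)
  p0r <- random_ova(3, 3)
  expect_equal(loss_ova_outlier(p0r), oracle_ova_out(p0r), tolerance = 1e-10)
})

test_that("entropy minimization: extremes, hand value, bound, oracle", {
  expect_equal(loss_entropy_min(rbind(c(1, 0), c(0, 1))), 0)
  expect_equal(loss_entropy_min(matrix(0.5, 1, 1)), log(2), tolerance = 1e-12)
  expect_equal(loss_entropy_min(matrix(0.9, 1, 1)),
               -0.9 * log(0.9) - 0.1 * log(0.1), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:10) {
    n <- sample(1:4, 1); K <- sample(1:3, 1)
    p0 <- random_ova(n, K)
    v <- loss_entropy_min(p0)
    expect_equal(v, oracle_entropy(p0), tolerance = 1e-10)
    expect_gte(v, 0); expect_lte(v, K * log(2) + 1e-12)
  }
})

test_that("SOCR: identical views, bound attainment, worked case, oracle", {
  p <- random_ova(3, 2)
  expect_equal(loss_socr(p, p), 0)
  K <- 3
  flip1 <- matrix(1, 2, K); flip2 <- matrix(0, 2, K)
  expect_equal(loss_socr(flip1, flip2), 2 * K)  # every pair flips
  v1 <- rbind(c(0.7, 0.6)); v2 <- rbind(c(0.5, 0.6))
  expect_equal(loss_socr(v1, v2), 0.4, tolerance = 1e-12)
  expect_error(loss_socr(random_ova(2, 2), random_ova(3, 2)), "same samples")
  set.seed(9)
  pa <- random_ova(4, 3); pb <- random_ova(4, 3)
  expect_equal(loss_socr(pa, pb), oracle_socr(pa, pb), tolerance = 1e-10)
})

test_that("pseudo-inlier selection thresholds on the argmax class OVA head", {
  p_closed <- rbind(c(0.9, 0.1), c(0.8, 0.2), c(0.2, 0.8))
  p0 <- rbind(c(0.99, 0.1), c(0.90, 0.5), c(0.3, 0.96))
  out <- list(p_closed = p_closed, p_ova0 = p0, sample_id = c("u1", "u2", "u3"))
  sel <- select_pseudo_inliers_openmatch(out, tau = 0.95)
  expect_equal(sel$sample_id, c("u1", "u3"))
  expect_equal(sel$pseudo_label, c(0L, 1L))
  # tau at or above every attainable probability selects nothing
  expect_equal(nrow(select_pseudo_inliers_openmatch(out, tau = 0.999)), 0L)
})

test_that("FixMatch loss: empty selection, perfect strong view, worked value", {
  p_strong <- rbind(c(0.5, 0.5), c(0.9, 0.1))
  expect_equal(loss_fixmatch(p_strong, c(0L, 0L), c(FALSE, FALSE), mu_B = 2), 0)
  expect_equal(loss_fixmatch(rbind(c(1, 0)), 0L, TRUE, mu_B = 1), 0)
  expect_equal(loss_fixmatch(rbind(c(0.5, 0.5), c(0.9, 0.1)), c(0L, 0L),
                             c(TRUE, FALSE), mu_B = 2),
               -log(0.5) / 2, tolerance = 1e-12)
})

test_that("OpenMatch decision rule: extremes and the 0.5 tie", {
  mk <- function(p0_at_yhat) {
    list(p_closed = rbind(c(0.9, 0.1)), p_ova0 = rbind(c(p0_at_yhat, 0.5)))
  }
  expect_equal(predict_openmatch(mk(1))$pred_label, 0L)     # p(t=1) = 0
  expect_equal(predict_openmatch(mk(0))$pred_label, label_unknown())
  expect_equal(predict_openmatch(mk(0.5))$pred_label, label_unknown())  # tie
  expect_equal(predict_openmatch(mk(0.3))$ood_score, 0.7)
})

test_that("openmatch driver: stage-1 report precedes unlabeled consumption, seeded", {
  b <- tiny_feature_bundle(seed = 31)
  cfg <- openmatch_config(epochs_stage1 = 4, epochs_stage2 = 3,
                          fixmatch_warmup_epochs = 1, batch_size = 8,
                          hidden = 12, embed = 8, proj_dim = 4, seed = 31)
  r <- run_openmatch_pipeline(b, cfg)
  expect_s3_class(r$reports$stage1, "osr_eval")
  h <- r$history
  expect_true(max(which(h$stage == "stage1")) < min(which(h$stage == "stage2")))
  expect_true(all(is.na(h$loss_fixmatch[h$stage == "stage1"]) |
                    h$stage != "stage1"))
  r2 <- run_openmatch_pipeline(b, cfg)
  expect_identical(r$reports$final$confusion, r2$reports$final$confusion)
  expect_identical(r$net$params, r2$net$params)
})

test_that("disabling FixMatch terms reproduces the no-FixMatch ablation arm", {
  b <- tiny_feature_bundle(seed = 32)
  cfg <- openmatch_config(epochs_stage1 = 3, epochs_stage2 = 3,
                          fixmatch_warmup_epochs = 1, batch_size = 8,
                          hidden = 10, embed = 6, proj_dim = 4, seed = 32,
                          lambda_fm = 0, lambda_cr = 0)
  r <- run_openmatch_pipeline(b, cfg)
  expect_equal(sum(r$history$loss_fixmatch, na.rm = TRUE), 0)
  expect_equal(sum(r$history$loss_contrastive, na.rm = TRUE), 0)
  expect_equal(r$n_pseudo_selected, 0L)
})
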
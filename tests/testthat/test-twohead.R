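# Brute-force transcriptions of the two-head losses, written term by term and
# kept independent of the package implementations they check.
oracle_ce_two <- function(p1, p2, labels) {
  total <- 0
  for (b in seq_len(nrow(p1))) {
    for (p in list(p1, p2)) total <- total - log(p[b, labels[b] + 1])
  }
  total / nrow(p1)
}
oracle_l1 <- function(u, v) {
  s <- 0
  for (i in seq_along(u)) s <- s + abs(u[i] - v[i])
  s
}
oracle_hinge <- function(p1, p2, m) {
  ds <- vapply(seq_len(nrow(p1)), function(b) oracle_l1(p1[b, ], p2[b, ]),
               numeric(1))
  max(m - mean(ds), 0)
}

test_that("two-head cross-entropy matches hand values and the oracle", {
  p_sure <- matrix(c(1, 0), 1)
  expect_equal(loss_cross_entropy_two(p_sure, p_sure, 0L), 0)
  p_e <- matrix(c(exp(-1), 1 - exp(-1)), 1)
  expect_equal(loss_cross_entropy_two(p_e, p_e, 0L), 2)
  set.seed(1)
  for (i in 1:10) {
    n <- sample(1:4, 1); K <- sample(2:3, 1)
    p1 <- random_prob(n, K); p2 <- random_prob(n, K)
    y <- sample(0:(K - 1), n, replace = TRUE)
    expect_equal(loss_cross_entropy_two(p1, p2, y), oracle_ce_two(p1, p2, y),
                 tolerance = 1e-10)
    perm <- sample(n)
    expect_equal(loss_cross_entropy_two(p1[perm, , drop = FALSE],
                                        p2[perm, , drop = FALSE], y[perm]),
                 loss_cross_entropy_two(p1, p2, y), tolerance = 1e-12)
  }
})

test_that("L1 discrepancy: hand values, bounds, length guard", {
  expect_equal(discrepancy_l1(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(discrepancy_l1(c(1, 0), c(0, 1)), 2)
  expect_equal(discrepancy_l1(c(0.6, 0.4), c(0.5, 0.5)), 0.2)
  expect_error(discrepancy_l1(c(1, 0), c(1, 0, 0)), "equal length")
  set.seed(2)
  for (i in 1:20) {
    p <- random_prob(2, 4)
    d <- discrepancy_l1(p[1, ], p[2, ])
    expect_gte(d, 0); expect_lte(d, 2)
  }
})

test_that("discrepancy hinge: worked examples, bounds, oracle agreement", {
  same <- random_prob(3, 2)
  expect_equal(loss_discrepancy(same, same, margin = 1.2), 1.2)
  p1 <- rbind(c(1, 0), c(0.5, 0.5))
  p2 <- rbind(c(0, 1), c(0.5, 0.5))  # d = 2 and 0
  expect_equal(loss_discrepancy(p1, p2, margin = 1.2), 0.2)
  wide <- rbind(c(1, 0)); wide2 <- rbind(c(0, 1))
  expect_equal(loss_discrepancy(wide, wide2, margin = 1.2), 0)  # hinge floor
  expect_error(loss_discrepancy(matrix(numeric(0), 0, 2), same, margin = 1),
               "nonempty")
  set.seed(3)
  for (i in 1:10) {
    n <- sample(1:4, 1)
    q1 <- random_prob(n, 3); q2 <- random_prob(n, 3)
    m <- runif(1, 0, 2)
    val <- loss_discrepancy(q1, q2, margin = m)
    expect_equal(val, oracle_hinge(q1, q2, m), tolerance = 1e-10)
    expect_gte(val, 0); expect_lte(val, m)
  }
})

test_that("two-head decision rule gates label assignment", {
  conf <- rbind(c(0.99, 0.01, 0))
  out <- list(p1 = conf, p2 = conf)
  pred <- predict_twohead(out, theta_p = 0.95, theta_d = 0.5)
  expect_equal(pred$pred_label, 0L)
  expect_equal(pred$ood_score, 0)
  # argmax disagreement alone forces unknown
  out2 <- list(p1 = rbind(c(0.97, 0.02, 0.01)), p2 = rbind(c(0.01, 0.97, 0.02)))
  pred2 <- predict_twohead(out2, theta_p = 0.01, theta_d = 1.99)
  expect_equal(pred2$pred_label, label_unknown())
  # discrepancy at or above the threshold forces unknown
  out3 <- list(p1 = rbind(c(0.99, 0.01)), p2 = rbind(c(0.7, 0.3)))
  pred3 <- predict_twohead(out3, theta_p = 0.5, theta_d = 0.5)
  expect_equal(pred3$pred_label, label_unknown())
  # low confidence forces unknown
  out4 <- list(p1 = rbind(c(0.6, 0.4)), p2 = rbind(c(0.6, 0.4)))
  pred4 <- predict_twohead(out4, theta_p = 0.95, theta_d = 0.5)
  expect_equal(pred4$pred_label, label_unknown())
})

test_that("grid search scans 0.01..0.99 and returns the smallest maximizer", {
  expect_equal(grid_search_theta_d(c(0.1, 0.9), c(FALSE, TRUE)), 0.11)
  # all scores identical: every theta <= score classifies all as outlier;
  # with outliers the majority, theta = 0.01 wins as the smallest maximizer
  expect_equal(grid_search_theta_d(rep(0.5, 5), c(TRUE, TRUE, TRUE, FALSE, TRUE)),
               0.01)
  # majority inliers: any theta > score classifies all as inlier
  th <- grid_search_theta_d(rep(0.5, 5), c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(th, 0.51)
  expect_error(grid_search_theta_d(c(0.2, 0.4), c(TRUE, TRUE)), "both")
  set.seed(4)
  inl <- runif(20, 0, 0.3); outl <- runif(20, 0.6, 1)
  th2 <- grid_search_theta_d(c(inl, outl), rep(c(FALSE, TRUE), each = 20))
  acc <- mean((c(inl, outl) >= th2) == rep(c(FALSE, TRUE), each = 20))
  expect_equal(acc, 1)  # perfect separation is found
})

test_that("pseudo-inlier selection applies all three gates", {
  empty <- list(p1 = matrix(numeric(0), 0, 2), p2 = matrix(numeric(0), 0, 2))
  expect_equal(nrow(select_pseudo_inliers_twohead(empty, 0.95, 0.5)), 0L)
  p1 <- rbind(c(0.99, 0.01, 0), c(0.99, 0.01, 0), c(0.99, 0.01, 0))
  p2 <- rbind(c(0.94, 0.05, 0.01),   # agree, d = 0.1 < 0.5... but min conf 0.94 < 0.95
              c(0.99, 0.01, 0),      # clean agreement
              c(0.01, 0.99, 0))      # disagree
  out <- list(p1 = p1, p2 = p2, sample_id = c("a", "b", "c"))
  sel <- select_pseudo_inliers_twohead(out, theta_p = 0.95, theta_d = 0.5)
  expect_equal(sel$sample_id, "b")
  expect_equal(sel$pseudo_label, 0L)
  # the spec's gate-by-gate tally: (agree, d, minmax) combinations
  p1b <- rbind(c(0.99, 0.01), c(0.99, 0.01), c(0.99, 0.01))
  p2b <- rbind(c(0.96, 0.04), c(0.69, 0.31), c(0.01, 0.99))
  outb <- list(p1 = p1b, p2 = p2b, sample_id = c("s1", "s2", "s3"))
  selb <- select_pseudo_inliers_twohead(outb, theta_p = 0.95, theta_d = 0.5)
  expect_equal(selb$sample_id, "s1")
})

test_that("pipeline driver: stage ordering, step gating, empty-ood warning", {
  b <- tiny_feature_bundle(seed = 21)
  cfg <- twohead_config(epochs_pretrain = 4, epochs_finetune = 2,
                        epochs_fixmatch = 2, batch_size = 8, hidden = 12,
                        embed = 8, proj_dim = 4, seed = 21)
  r <- run_twohead_pipeline(b, cfg)
  expect_s3_class(r$reports$stage1, "osr_eval")
  expect_s3_class(r$reports$final, "osr_eval")
  stages <- unique(r$history$stage)
  expect_equal(stages, sort(stages))  # logged strictly in step order
  expect_true(all(stages %in% c("1", "2", "3", "4")))
  expect_true(r$theta_d > 0 && r$theta_d < 1)
  # steps 1-2 only: final report identical to stage-1 report
  cfg12 <- cfg; cfg12$steps <- 1:2
  r12 <- run_twohead_pipeline(b, cfg12)
  expect_identical(r12$reports$final$confusion, r12$reports$stage1$confusion)
  expect_equal(r12$reports$final$accuracy, r12$reports$stage1$accuracy)
  # empty exposure split degrades gracefully
  b_noood <- b[b$split != "ood_train", ]
  b_noood <- opensetr:::new_bundle(b_noood, bundle_schema(b))
  expect_warning(run_twohead_pipeline(b_noood, cfg12), "ood_train")
})

test_that("pipeline runs are deterministic under a fixed seed", {
  b <- tiny_feature_bundle(seed = 22)
  cfg <- twohead_config(epochs_pretrain = 3, epochs_finetune = 1,
                        epochs_fixmatch = 1, batch_size = 8, hidden = 10,
                        embed = 6, proj_dim = 4, seed = 5)
  r1 <- run_twohead_pipeline(b, cfg)
  r2 <- run_twohead_pipeline(b, cfg)
  expect_identical(r1$reports$final$confusion, r2$reports$final$confusion)
  expect_identical(r1$net$params, r2$net$params)
})

test_that("discrepancy fine-tuning does not decrease outlier discrepancy", {
  # low dimension + dense outlier coverage so the hinge learned on the
  # exposure set transfers to held-out outliers
  b <- generate_feature_dataset(3, 3, 6, 40, separation = 5, seed = 23,
                                n_unlabeled = 20, n_val = 16, n_test = 40)
  lab <- bundle_split(b, "labeled_train")
  ood <- bundle_split(b, "ood_train")
  held_out <- bundle_split(b, "test")
  held_out <- held_out[held_out$label == label_unknown(), ]
  pol <- augmentation_policy("weak", seed = 1)
  net <- osr_network(bundle_schema(b), "twohead", hidden = 12, embed = 8,
                     seed = 23)
  cfg <- twohead_config(batch_size = 8, seed = 23)
  set.seed(23)
  for (ep in 1:6) {
    for (bi in opensetr:::minibatches(nrow(lab), 8)) {
      st <- opensetr:::grads_ce_two(net, lab[bi, ], pol)
      net <- opensetr:::apply_grads(net, list(st$grads), 0.01)
    }
  }
  mean_disc <- function(net) {
    out <- forward_twohead(net, held_out)
    mean(opensetr:::discrepancy_rows(out$p1, out$p2))
  }
  before <- mean_disc(net)
  net <- opensetr:::reset_optimizer(net)
  for (ep in 1:8) {
    ft <- opensetr:::finetune_epoch_twohead(net, lab, ood, pol, cfg, 2e-3)
    net <- ft$net
  }
  expect_gte(mean_disc(net), before)
})
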
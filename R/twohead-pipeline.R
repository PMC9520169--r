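#' Configuration for the two-head pipeline
#'
#' Defaults are the desk-scale profile used throughout the tests (a few
#' hundred 64 x 64 images, the small trainable backbone). The full-scale
#' profile the method was designed around (batch 64, 300 pre-training and 10
#' fine-tuning epochs, learning rate decaying from 0.01, fine-tuning rate
#' 2e-4, confidence gate 0.95, discrepancy threshold grid-searched on (0,1))
#' is available via `profile = "full"`.
#'
#' @param margin_m Margin `m` of the discrepancy hinge (>= 0). The default
#'   1.6 sits deliberately above the 1.2 convention of the two-head
#'   discrepancy literature: the hinge acts on the batch-mean discrepancy,
#'   and with heterogeneous outlier families a low margin is satisfied once
#'   the easy families saturate (L1 tops out at 2), leaving hard families
#'   untouched; a margin near the ceiling keeps pressure on them.
#' @param theta_p Softmax-confidence threshold in (0, 1]; default 0.95.
#' @param theta_d Discrepancy threshold in (0, 1), or `"grid_search"` to pick
#'   it on the validation split by [grid_search_theta_d()].
#' @param epochs_pretrain,epochs_finetune,epochs_fixmatch Stage epoch counts.
#' @param batch_size Labeled batch size.
#' @param lr_pretrain Initial learning rate of the cosine-decayed pre-training
#'   schedule.
#' @param lr_finetune Fixed fine-tuning learning rate.
#' @param lr_fixmatch Initial learning rate of the Step-3 FixMatch schedule.
#' @param steps Which of the four pipeline steps to run (default `1:4`).
#' @param hidden,embed,proj_dim,pool Backbone hyperparameters, see
#'   [osr_network()].
#' @param seed Integer seed covering initialization, batching and
#'   augmentation draws.
#' @param profile `"desk"` (default) or `"full"`.
#' @return A `twohead_config` list.
#' @export
twohead_config <- function(margin_m = 1.6, theta_p = 0.95, theta_d = "grid_search",
                           epochs_pretrain = 40, epochs_finetune = 10,
                           epochs_fixmatch = 10, batch_size = 32,
                           lr_pretrain = 0.01, lr_finetune = 2e-3,
                           lr_fixmatch = 5e-4, steps = 1:4,
                           hidden = 64, embed = 32, proj_dim = 16, pool = 10,
                           seed = 1, profile = c("desk", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") {
    epochs_pretrain <- 300; epochs_finetune <- 10; epochs_fixmatch <- 50
    batch_size <- 64; lr_finetune <- 2e-4
  }
  if (margin_m < 0) abort("`margin_m` must be >= 0.")
  if (theta_p <= 0 || theta_p > 1) abort("`theta_p` must lie in (0, 1].")
  if (!identical(theta_d, "grid_search") &&
      (!is.numeric(theta_d) || theta_d <= 0 || theta_d >= 1)) {
    abort("`theta_d` must lie in (0, 1) or be \"grid_search\".")
  }
  structure(
    list(margin_m = margin_m, theta_p = theta_p, theta_d = theta_d,
         epochs_pretrain = epochs_pretrain, epochs_finetune = epochs_finetune,
         epochs_fixmatch = epochs_fixmatch, batch_size = batch_size,
         lr_pretrain = lr_pretrain, lr_finetune = lr_finetune,
         lr_fixmatch = lr_fixmatch, steps = steps, hidden = hidden,
         embed = embed, proj_dim = proj_dim, pool = pool, seed = seed,
         profile = profile),
    class = "twohead_config"
  )
}

eval_twohead_split <- function(net, rows, theta_p, theta_d, class_names) {
  out <- forward_twohead(net, rows)
  preds <- predict_twohead(out, theta_p, theta_d)
  preds$true_label <- rows$label
  evaluate_predictions(preds, net$K, class_names)
}

resolve_theta_d <- function(net, bundle, config) {
  if (!identical(config$theta_d, "grid_search")) return(config$theta_d)
  val <- bundle_split(bundle, "validation")
  if (nrow(val) == 0 || length(unique(val$label == label_unknown())) < 2L) {
    warn("Validation split unusable for grid search; theta_d fixed at 0.5.")
    return(0.5)
  }
  out <- forward_twohead(net, val)
  grid_search_theta_d(discrepancy_rows(out$p1, out$p2),
                      val$label == label_unknown())
}

# One joint fine-tuning pass: labeled cross-entropy anchors the heads'
# agreement on inliers while the hinge on outlier batches drives their
# discrepancy up to the margin.
finetune_epoch_twohead <- function(net, labeled, ood, policy, config, lr) {
  losses <- c(ce = 0, disc = 0)
  batches <- minibatches(nrow(labeled), config$batch_size)
  for (bi in batches) {
    gs <- list()
    ce <- grads_ce_two(net, labeled[bi, ], policy)
    gs <- c(gs, list(ce$grads))
    losses["ce"] <- losses["ce"] + ce$loss
    if (nrow(ood) > 0) {
      oi <- sample.int(nrow(ood), min(config$batch_size, nrow(ood)))
      dc <- grads_discrepancy(net, ood[oi, ], policy, config$margin_m)
      gs <- c(gs, list(dc$grads))
      losses["disc"] <- losses["disc"] + dc$loss
    }
    net <- apply_grads(net, gs, lr)
  }
  list(net = net, losses = losses / max(length(batches), 1))
}

#' Run the four-step two-head continual-learning pipeline
#'
#' Step 1 pre-trains both softmax heads on labeled inliers (two-head
#' cross-entropy) and fine-tunes with the discrepancy hinge on the exposed
#' outlier split. Step 2 runs inference on the unlabeled split: the
#' discrepancy threshold is grid-searched on the validation split, confident
#' agreeing samples become pseudo-inliers, and samples scoring at or above
#' the threshold become pseudo-outliers. Step 3 retrains with FixMatch —
#' each head receives its own consistency loss on strong-augmented views of
#' the pseudo-inliers — plus contrastive regularization of the backbone over
#' a pool of strong views. Step 4 fine-tunes once more on the original
#' outliers joined with the pseudo-outliers. Evaluation reports on the test
#' split are emitted after Step 1 and after the last step.
#'
#' @param bundle An `osr_bundle` with labeled_train, unlabeled, validation,
#'   test and ood_train splits.
#' @param config A [twohead_config()].
#' @param fixmatch A [fixmatch_cr_config()].
#' @return An `osr_run` with elements `net`, `reports` (`stage1`, `final`),
#'   `theta_d`, `pseudo_inliers`, `pseudo_outliers`, `history`, `config`.
#' @export
run_twohead_pipeline <- function(bundle, config = twohead_config(),
                                 fixmatch = fixmatch_cr_config()) {
  stopifnot(inherits(bundle, "osr_bundle"))
  schema <- bundle_schema(bundle)
  labeled <- bundle_split(bundle, "labeled_train")
  ood <- bundle_split(bundle, "ood_train")
  unl <- bundle_split(bundle, "unlabeled")
  test <- bundle_split(bundle, "test")
  if (nrow(labeled) == 0) abort("`bundle` has no labeled_train samples.")
  history <- list()
  log_row <- function(stage, epoch, ...) {
    history[[length(history) + 1L]] <<- tibble(stage = stage, epoch = epoch, ...)
  }
  net <- osr_network(schema, "twohead", config$hidden, config$embed,
                     config$proj_dim, config$pool, seed = config$seed)
  weak <- augmentation_policy("weak", seed = derive_seed(config$seed, 11))
  strong <- augmentation_policy("strong", seed = derive_seed(config$seed, 12))
  run <- with_seed(derive_seed(config$seed, 13), {
    # Step 1: supervised pre-training, then discrepancy fine-tuning
    for (ep in seq_len(config$epochs_pretrain)) {
      lr <- cosine_lr(config$lr_pretrain, ep, config$epochs_pretrain)
      loss <- 0
      for (bi in minibatches(nrow(labeled), config$batch_size)) {
        st <- grads_ce_two(net, labeled[bi, ], weak)
        net <- apply_grads(net, list(st$grads), lr)
        loss <- loss + st$loss
      }
      log_row("1", ep, loss_ce = loss, loss_disc = NA_real_)
    }
    if (nrow(ood) == 0) {
      warn("Empty ood_train: Step-1 fine-tuning skipped (closed-set model).")
    } else {
      net <- reset_optimizer(net)
      for (ep in seq_len(config$epochs_finetune)) {
        ft <- finetune_epoch_twohead(net, labeled, ood, weak, config,
                                     config$lr_finetune)
        net <- ft$net
        log_row("1", config$epochs_pretrain + ep,
                loss_ce = ft$losses["ce"], loss_disc = ft$losses["disc"])
      }
    }
    theta_d <- resolve_theta_d(net, bundle, config)
    stage1 <- eval_twohead_split(net, test, config$theta_p, theta_d,
                                 schema$class_names)
    # Step 2: inference on the unlabeled split
    pseudo_in <- tibble(sample_id = character(), pseudo_label = integer())
    pseudo_out <- character()
    if (2 %in% config$steps && nrow(unl) > 0) {
      out_u <- forward_twohead(net, unl)
      pseudo_in <- select_pseudo_inliers_twohead(out_u, config$theta_p, theta_d)
      scores <- discrepancy_rows(out_u$p1, out_u$p2)
      pseudo_out <- unl$sample_id[scores >= theta_d]
      log_row("2", 1L, n_pseudo_inliers = nrow(pseudo_in),
              n_pseudo_outliers = length(pseudo_out))
    }
    # Step 3: FixMatch with contrastive regularization on pseudo-inliers
    if (3 %in% config$steps && nrow(pseudo_in) > 0) {
      prows <- unl[match(pseudo_in$sample_id, unl$sample_id), , drop = FALSE]
      net <- reset_optimizer(net)
      for (ep in seq_len(config$epochs_fixmatch)) {
        lr <- cosine_lr(config$lr_fixmatch, ep, config$epochs_fixmatch)
        loss_fm <- 0; loss_cr <- 0
        for (bi in minibatches(nrow(prows), config$batch_size)) {
          rows_b <- prows[bi, ]; labs_b <- pseudo_in$pseudo_label[bi]
          # FixMatch keeps its supervised term: labeled CE anchors both heads
          li <- sample.int(nrow(labeled), min(config$batch_size, nrow(labeled)))
          ce <- grads_ce_two(net, labeled[li, ], weak)
          g1 <- grads_fixmatch_head(net, rows_b, labs_b, strong,
                                    "Wh1", "bh1", mu_B = length(bi))
          g2 <- grads_fixmatch_head(net, rows_b, labs_b, strong,
                                    "Wh2", "bh2", mu_B = length(bi))
          gs <- list(ce$grads, g1$grads, g2$grads)
          loss_fm <- loss_fm + g1$loss + g2$loss
          if (fixmatch$enabled) {
            cr <- grads_contrastive(net, rows_b, labs_b, strong, fixmatch)
            gs <- c(gs, list(cr$grads))
            loss_cr <- loss_cr + cr$loss
          }
          net <- apply_grads(net, gs, lr)
        }
        log_row("3", ep, loss_fixmatch = loss_fm, loss_contrastive = loss_cr)
      }
    }
    # Step 4: fine-tune on original plus pseudo outliers
    if (4 %in% config$steps && nrow(ood) + length(pseudo_out) > 0) {
      ood4 <- dplyr::bind_rows(ood, unl[unl$sample_id %in% pseudo_out, ])
      net <- reset_optimizer(net)
      for (ep in seq_len(config$epochs_finetune)) {
        ft <- finetune_epoch_twohead(net, labeled, ood4, weak, config,
                                     config$lr_finetune)
        net <- ft$net
        log_row("4", ep, loss_ce = ft$losses["ce"], loss_disc = ft$losses["disc"])
      }
      theta_d <- resolve_theta_d(net, bundle, config)
    }
    final <- eval_twohead_split(net, test, config$theta_p, theta_d,
                                schema$class_names)
    list(net = net, theta_d = theta_d, stage1 = stage1, final = final,
         pseudo_in = pseudo_in, pseudo_out = pseudo_out)
  })
  structure(
    list(method = "twohead", net = run$net,
         reports = list(stage1 = run$stage1, final = run$final),
         theta_d = run$theta_d, theta_p = config$theta_p,
         pseudo_inliers = run$pseudo_in, pseudo_outliers = run$pseudo_out,
         history = dplyr::bind_rows(history), config = config),
    class = "osr_run"
  )
}

#' @export
print.osr_run <- function(x, ...) {
  g <- glance(x)
  cat("<osr_run> method = ", x$method,
      ", final accuracy = ", sprintf("%.3f", g$accuracy),
      ", AUROC = ", sprintf("%.3f", g$auroc), "\n", sep = "")
  invisible(x)
}

#' @rdname run_twohead_pipeline
#' @param x,object An `osr_run`.
#' @param ... Unused.
#' @export
tidy.osr_run <- function(x, ...) x$history

#' @rdname run_twohead_pipeline
#' @export
glance.osr_run <- function(x, ...) {
  dplyr::bind_cols(tibble(method = x$method), glance(x$reports$final))
}

#' Predict labels and outlier scores for new samples
#'
#' @param object An `osr_run` from [run_twohead_pipeline()] or
#'   [run_openmatch_pipeline()].
#' @param newdata Bundle rows.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `pred_label`, `ood_score`.
#' @export
predict.osr_run <- function(object, newdata, ...) {
  if (object$method == "twohead") {
    predict_twohead(forward_twohead(object$net, newdata),
                    object$theta_p, object$theta_d)
  } else {
    predict_openmatch(forward_openmatch(object$net, newdata))
  }
}

#' Training-history curves for a fitted run
#' @param object An `osr_run`.
#' @param ... Unused.
#' @return A ggplot object of per-epoch loss terms by stage.
#' @export
autoplot.osr_run <- function(object, ...) {
  h <- object$history
  long <- tidyr::pivot_longer(h, cols = dplyr::starts_with("loss_"),
                              names_to = "term", values_to = "value",
                              names_prefix = "loss_")
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     color = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stage, scales = "free") +
    ggplot2::labs(x = "epoch", y = "loss", color = "term") +
    ggplot2::theme_minimal()
}
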
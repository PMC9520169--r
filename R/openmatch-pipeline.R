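#' Configuration for the disassembled OpenMatch pipeline
#'
#' Stage 1 trains the closed-set softmax and the K OVA heads on labeled
#' inliers plus the exposed outlier split (OpenMatch as an OoD detector);
#' Stage 2 continues from those parameters with the semi-supervised loop
#' (entropy minimization, SOCR, and — after a warm-up — FixMatch with
#' contrastive regularization). Loss weights default to the values customary
#' in the OpenMatch lineage and are all configurable.
#'
#' @param tau Pseudo-inlier confidence threshold in (0, 1); default 0.95.
#' @param lambda_em,lambda_oc,lambda_fm,lambda_cr Nonnegative weights of the
#'   entropy-minimization, SOCR, FixMatch and contrastive terms (defaults
#'   0.1, 0.5, 1, 1).
#' @param fixmatch_warmup_epochs Stage-2 epochs before the FixMatch and
#'   contrastive terms switch on ("after the training is stabilized");
#'   desk-scale default 3.
#' @param epochs_stage1,epochs_stage2 Stage epoch counts.
#' @param batch_size Labeled batch size `B`.
#' @param mu Unlabeled-to-labeled batch ratio (>= 1); unlabeled batches have
#'   size `mu * B`.
#' @param lr Initial learning rate of the cosine-decayed Stage-1 schedule.
#' @param lr_stage2 Initial learning rate of the Stage-2 schedule (the
#'   continuation runs at a lower rate).
#' @param ood_loss `"uniform"` (every OVA head pushed to outlier on exposed
#'   outliers; default, more stable) or `"none"`.
#' @param hidden,embed,proj_dim,pool Backbone hyperparameters.
#' @param seed Integer seed.
#' @param profile `"desk"` (default) or `"full"` (batch 64, 300/300 epochs,
#'   warm-up 10).
#' @return An `openmatch_config` list.
#' @export
openmatch_config <- function(tau = 0.95, lambda_em = 0.1, lambda_oc = 0.5,
                             lambda_fm = 1, lambda_cr = 1,
                             fixmatch_warmup_epochs = 3,
                             epochs_stage1 = 40, epochs_stage2 = 15,
                             batch_size = 32, mu = 2, lr = 0.01,
                             lr_stage2 = 0.001, ood_loss = c("uniform", "none"),
                             hidden = 64, embed = 32, proj_dim = 16, pool = 10,
                             seed = 1, profile = c("desk", "full")) {
  profile <- match.arg(profile)
  ood_loss <- match.arg(ood_loss)
  if (profile == "full") {
    epochs_stage1 <- 300; epochs_stage2 <- 300
    fixmatch_warmup_epochs <- 10; batch_size <- 64
  }
  if (tau <= 0 || tau >= 1) abort("`tau` must lie in (0, 1).")
  for (nm in c("lambda_em", "lambda_oc", "lambda_fm", "lambda_cr")) {
    if (get(nm) < 0) abort(sprintf("`%s` must be >= 0.", nm))
  }
  if (mu < 1) abort("`mu` must be >= 1.")
  structure(
    list(tau = tau, lambda_em = lambda_em, lambda_oc = lambda_oc,
         lambda_fm = lambda_fm, lambda_cr = lambda_cr,
         fixmatch_warmup_epochs = fixmatch_warmup_epochs,
         epochs_stage1 = epochs_stage1, epochs_stage2 = epochs_stage2,
         batch_size = batch_size, mu = mu, lr = lr, lr_stage2 = lr_stage2,
         ood_loss = ood_loss, hidden = hidden, embed = embed,
         proj_dim = proj_dim, pool = pool, seed = seed, profile = profile),
    class = "openmatch_config"
  )
}

eval_openmatch_split <- function(net, rows, class_names) {
  preds <- predict_openmatch(forward_openmatch(net, rows))
  preds$true_label <- rows$label
  evaluate_predictions(preds, net$K, class_names)
}

#' Run the two-stage disassembled OpenMatch pipeline
#'
#' Stage 1 minimizes the closed-set cross-entropy plus the OVA inlier loss on
#' labeled batches, and (by default) pushes every OVA head toward "outlier"
#' on the exposed outlier split; an evaluation report on the test split is
#' emitted before any unlabeled data is touched. Stage 2 continues from the
#' Stage-1 parameters with the semi-supervised loop: labeled batches of size
#' `B` are paired with unlabeled batches of size `mu * B` drawn from the
#' unlabeled split joined with the Stage-1 outliers; each unlabeled batch
#' contributes entropy minimization and SOCR across two weak views, and,
#' after the warm-up, confident pseudo-inliers (closed-set argmax whose OVA
#' head clears `tau`) contribute the FixMatch consistency loss on strong
#' views and the contrastive loss over a pool of `m_aug` strong views.
#'
#' @param bundle An `osr_bundle`.
#' @param config An [openmatch_config()].
#' @param fixmatch A [fixmatch_cr_config()].
#' @return An `osr_run` with `reports$stage1` and `reports$final`.
#' @export
run_openmatch_pipeline <- function(bundle, config = openmatch_config(),
                                   fixmatch = fixmatch_cr_config()) {
  stopifnot(inherits(bundle, "osr_bundle"))
  schema <- bundle_schema(bundle)
  labeled <- bundle_split(bundle, "labeled_train")
  ood <- bundle_split(bundle, "ood_train")
  test <- bundle_split(bundle, "test")
  unl_pool <- dplyr::bind_rows(bundle_split(bundle, "unlabeled"), ood)
  if (nrow(labeled) == 0) abort("`bundle` has no labeled_train samples.")
  history <- list()
  log_row <- function(stage, epoch, ...) {
    history[[length(history) + 1L]] <<- tibble(stage = stage, epoch = epoch, ...)
  }
  net <- osr_network(schema, "openmatch", config$hidden, config$embed,
                     config$proj_dim, config$pool, seed = config$seed)
  weak <- augmentation_policy("weak", seed = derive_seed(config$seed, 21))
  strong <- augmentation_policy("strong", seed = derive_seed(config$seed, 22))
  run <- with_seed(derive_seed(config$seed, 23), {
    # Stage 1: supervised OVA + closed-set training with outlier exposure
    for (ep in seq_len(config$epochs_stage1)) {
      lr <- cosine_lr(config$lr, ep, config$epochs_stage1)
      loss_sup <- 0; loss_ood <- 0
      for (bi in minibatches(nrow(labeled), config$batch_size)) {
        gs <- list()
        sup <- grads_openmatch_labeled(net, labeled[bi, ], weak)
        gs <- c(gs, list(sup$grads)); loss_sup <- loss_sup + sup$loss
        if (config$ood_loss == "uniform" && nrow(ood) > 0) {
          oi <- sample.int(nrow(ood), min(config$batch_size, nrow(ood)))
          oo <- grads_ova_outlier(net, ood[oi, ], weak)
          gs <- c(gs, list(oo$grads)); loss_ood <- loss_ood + oo$loss
        }
        net <- apply_grads(net, gs, lr)
      }
      log_row("stage1", ep, loss_supervised = loss_sup, loss_ood = loss_ood)
    }
    stage1 <- eval_openmatch_split(net, test, schema$class_names)
    # Stage 2: semi-supervised loop
    net <- reset_optimizer(net)
    n_sel_total <- 0L
    for (ep in seq_len(config$epochs_stage2)) {
      lr <- cosine_lr(config$lr_stage2, ep, config$epochs_stage2)
      fixmatch_on <- ep > config$fixmatch_warmup_epochs
      terms <- c(sup = 0, em = 0, oc = 0, fm = 0, cr = 0)
      for (bi in minibatches(nrow(labeled), config$batch_size)) {
        gs <- list()
        sup <- grads_openmatch_labeled(net, labeled[bi, ], weak)
        gs <- c(gs, list(sup$grads)); terms["sup"] <- terms["sup"] + sup$loss
        mu_B <- min(config$mu * config$batch_size, nrow(unl_pool))
        if (mu_B > 0) {
          ui <- sample.int(nrow(unl_pool), mu_B)
          urows <- unl_pool[ui, ]
          ug <- grads_unlabeled_ova(net, urows, weak, config$lambda_em,
                                    config$lambda_oc)
          gs <- c(gs, list(ug$grads))
          terms["em"] <- terms["em"] + ug$loss_em
          terms["oc"] <- terms["oc"] + ug$loss_oc
          if (fixmatch_on && (config$lambda_fm > 0 || config$lambda_cr > 0)) {
            P <- head_softmax(ug$outputs_view1$bb$E, net$params$Wc, net$params$bc)
            sel <- select_pseudo_inliers_openmatch(
              list(p_closed = P, p_ova0 = ug$outputs_view1$P0,
                   sample_id = urows$sample_id),
              config$tau
            )
            n_sel_total <- n_sel_total + nrow(sel)
            if (nrow(sel) > 0) {
              srows <- urows[match(sel$sample_id, urows$sample_id), , drop = FALSE]
              if (config$lambda_fm > 0) {
                fm <- grads_fixmatch_head(net, srows, sel$pseudo_label, strong,
                                          "Wc", "bc", mu_B = mu_B,
                                          weight = config$lambda_fm)
                gs <- c(gs, list(fm$grads)); terms["fm"] <- terms["fm"] + fm$loss
              }
              if (config$lambda_cr > 0 && fixmatch$enabled && nrow(sel) > 1) {
                cr <- grads_contrastive(net, srows, sel$pseudo_label, strong,
                                        fixmatch, weight = config$lambda_cr)
                gs <- c(gs, list(cr$grads)); terms["cr"] <- terms["cr"] + cr$loss
              }
            }
          }
        }
        net <- apply_grads(net, gs, lr)
      }
      log_row("stage2", ep, loss_supervised = terms[["sup"]],
              loss_em = terms[["em"]], loss_socr = terms[["oc"]],
              loss_fixmatch = terms[["fm"]], loss_contrastive = terms[["cr"]])
    }
    final <- eval_openmatch_split(net, test, schema$class_names)
    list(net = net, stage1 = stage1, final = final, n_selected = n_sel_total)
  })
  structure(
    list(method = "openmatch", net = run$net,
         reports = list(stage1 = run$stage1, final = run$final),
         n_pseudo_selected = run$n_selected,
         history = dplyr::bind_rows(history), config = config),
    class = "osr_run"
  )
}
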
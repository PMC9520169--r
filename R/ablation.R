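composition_mix <- function(code) {
  mixes <- list(
    "I" = c(1, 0, 0), "N" = c(0, 1, 0), "D" = c(0, 0, 1),
    "I+N" = c(0.5, 0.5, 0), "N+D" = c(0, 0.5, 0.5),
    "I+N+D" = c(1, 1, 1) / 3
  )
  if (!code %in% names(mixes)) {
    abort(sprintf("Unknown composition code '%s'; use %s.", code,
                  paste(names(mixes), collapse = ", ")))
  }
  setNames(mixes[[code]], c("irrelevant", "normal", "unknown_disease"))
}

#' Outlier-composition ablation for the exposure set
#'
#' Trains the selected method once per composition of the outlier-exposure
#' split — irrelevant textures (I), healthy tissue (N), unknown-disease
#' motifs (D), or their mixes — holding the labeled data, all other splits
#' and the seed fixed, and reports accuracy and AUROC per arm. This probes
#' which kind of exposed outlier actually teaches the detector: hard
#' negatives that share the plant context (N, D) versus arbitrary non-plant
#' images (I).
#'
#' @param schema An image [dataset_schema()].
#' @param compositions Character codes among `I, N, D, I+N, N+D, I+N+D`.
#' @param method `"twohead"` or `"openmatch"`.
#' @param n_labeled_per_class,n_unlabeled,n_ood,n_val,n_test Bundle sizes
#'   passed to [generate_dataset()].
#' @param seeds One or more seeds; each seed reruns every composition.
#' @param config Method config (defaults to the desk-scale profile with the
#'   per-arm seed injected).
#' @param fixmatch A [fixmatch_cr_config()].
#' @param out_csv Optional path; when given, the result table is also written
#'   as CSV (the first six columns mirror the composition table layout).
#' @return A tibble with `seed`, `composition`, `accuracy`, `auroc`.
#' @export
run_ablation_ood_types <- function(schema,
                                   compositions = c("I", "N", "D", "I+N",
                                                    "N+D", "I+N+D"),
                                   method = c("twohead", "openmatch"),
                                   n_labeled_per_class = 15, n_unlabeled = 120,
                                   n_ood = 60, n_val = 80, n_test = 120,
                                   seeds = 1, config = NULL,
                                   fixmatch = fixmatch_cr_config(),
                                   out_csv = NULL) {
  method <- match.arg(method)
  rows <- purrr::map_dfr(seeds, function(sd) {
    purrr::map_dfr(compositions, function(code) {
      mix <- composition_mix(code)
      bundle <- generate_dataset(schema, n_labeled_per_class, n_unlabeled,
                                 n_ood, n_val, n_test, seed = sd,
                                 ood_train_mix = mix)
      cfg <- config %||% if (method == "twohead") {
        twohead_config(seed = sd)
      } else {
        openmatch_config(seed = sd)
      }
      cfg$seed <- sd
      run <- if (method == "twohead") {
        run_twohead_pipeline(bundle, cfg, fixmatch)
      } else {
        run_openmatch_pipeline(bundle, cfg, fixmatch)
      }
      g <- glance(run$reports$final)
      tibble(seed = sd, composition = code,
             accuracy = g$accuracy, auroc = g$auroc)
    })
  })
  if (!is.null(out_csv)) {
    wide <- tidyr::pivot_wider(rows, names_from = "composition",
                               values_from = c("accuracy", "auroc"))
    write.csv(wide, out_csv, row.names = FALSE)
  }
  rows
}

#' Stage ablation of the disassembled OpenMatch trainer
#'
#' For each seed, runs the two-stage pipeline twice on the same bundle: once
#' with the FixMatch and contrastive terms disabled (`lambda_fm = lambda_cr
#' = 0`) and once with them enabled. Three arms are reported per seed — the
#' Stage-1 OoD detector, Stage 2 without FixMatch, Stage 2 with
#' FixMatch-CR — so the expected left-to-right improvement of the
#' semi-supervised additions can be checked directionally over seed medians.
#'
#' @inheritParams run_ablation_ood_types
#' @param config Base [openmatch_config()]; the per-seed value is injected.
#' @return A tibble with `seed`, `arm`, `accuracy`, `auroc`.
#' @export
run_ablation_openmatch_stages <- function(schema, n_labeled_per_class = 15,
                                          n_unlabeled = 120, n_ood = 60,
                                          n_val = 80, n_test = 120, seeds = 1,
                                          config = openmatch_config(),
                                          fixmatch = fixmatch_cr_config()) {
  purrr::map_dfr(seeds, function(sd) {
    bundle <- generate_dataset(schema, n_labeled_per_class, n_unlabeled,
                               n_ood, n_val, n_test, seed = sd)
    cfg_no <- config; cfg_no$seed <- sd
    cfg_no$lambda_fm <- 0; cfg_no$lambda_cr <- 0
    run_no <- run_openmatch_pipeline(bundle, cfg_no, fixmatch)
    cfg_fm <- config; cfg_fm$seed <- sd
    run_fm <- run_openmatch_pipeline(bundle, cfg_fm, fixmatch)
    arms <- list(
      stage1 = run_no$reports$stage1,
      stage2_no_fixmatch = run_no$reports$final,
      stage2_fixmatch_cr = run_fm$reports$final
    )
    purrr::map_dfr(names(arms), function(a) {
      g <- glance(arms[[a]])
      tibble(seed = sd, arm = a, accuracy = g$accuracy, auroc = g$auroc)
    })
  })
}
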
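eval_levels <- function(K, class_names = NULL) {
  c(class_names %||% sprintf("class%02d", seq_len(K)), "unknown")
}

#' Confusion matrix over K known classes plus the unknown outcome
#'
#' Rows are truth, columns are predictions; the last row/column is the
#' unknown class ([label_unknown()]). Per-class recall is the diagonal over
#' the row sum, precision the diagonal over the column sum; empty
#' denominators yield 0 and are flagged in the `undefined` column.
#'
#' @param truth,pred Integer labels in `0..K-1` or [label_unknown()].
#' @param K Number of known classes.
#' @param class_names Optional class names (length `K`).
#' @return An `osr_eval` object: confusion matrix, accuracy, per-class
#'   precision/recall tibble, and an `auroc` slot (`NA` until scores are
#'   supplied, see [evaluate_predictions()]).
#' @export
eval_confusion <- function(truth, pred, K, class_names = NULL) {
  if (length(truth) != length(pred)) abort("`truth` and `pred` must align.")
  ok <- function(x) all(x == label_unknown() | (x >= 0 & x < K))
  if (!ok(truth) || !ok(pred)) abort("labels must lie in 0..K-1 or be unknown.")
  lev <- eval_levels(K, class_names)
  to_f <- function(x) factor(ifelse(x == label_unknown(), K, x),
                             levels = 0:K, labels = lev)
  cm <- table(truth = to_f(truth), predicted = to_f(pred))
  cm <- matrix(as.integer(cm), K + 1L, K + 1L, dimnames = dimnames(cm))
  per_class <- confusion_margins(cm)
  structure(
    list(confusion = cm, accuracy = accuracy_from_confusion(cm),
         per_class = per_class, auroc = NA_real_, n = length(truth)),
    class = "osr_eval"
  )
}

confusion_margins <- function(cm) {
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  tibble(
    class = rownames(cm),
    recall = unname(safe_div(diag(cm), rowSums(cm))),
    precision = unname(safe_div(diag(cm), colSums(cm))),
    undefined = unname(rowSums(cm) == 0 | colSums(cm) == 0)
  )
}

#' Accuracy from a (K+1) x (K+1) confusion matrix
#'
#' The unknown outcome counts as an ordinary (K+1)-th class: accuracy is the
#' trace over the total.
#'
#' @param confusion A square count matrix (rows truth, columns predicted).
#' @return A scalar in `[0, 1]`.
#' @export
accuracy_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (sum(confusion) == 0) abort("Confusion matrix has zero total count.")
  sum(diag(confusion)) / sum(confusion)
}

#' Area under the ROC curve for an outlier score
#'
#' Computed by the rank-based Mann-Whitney identity with midranks for ties,
#' which equals the mean over all (outlier, inlier) pairs of
#' `1` if the outlier outscores the inlier, `0.5` on ties, `0` otherwise.
#' Higher scores must indicate more outlier-like samples.
#'
#' @param scores Numeric scores.
#' @param is_outlier Logical ground truth.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, is_outlier) {
  if (length(scores) != length(is_outlier)) abort("Inputs must align.")
  is_outlier <- as.logical(is_outlier)
  n1 <- sum(is_outlier); n0 <- sum(!is_outlier)
  if (n1 == 0 || n0 == 0) abort("AUROC needs both inliers and outliers.")
  r <- rank(scores)
  (sum(r[is_outlier]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a prediction table into a full report
#'
#' @param predictions A tibble with columns `true_label`, `pred_label` and
#'   (for AUROC) `ood_score`; typically built by joining [predict_twohead()]
#'   or [predict_openmatch()] output with ground truth.
#' @param K Number of known classes.
#' @param class_names Optional class names.
#' @return An `osr_eval` with accuracy, confusion, per-class margins and
#'   AUROC (when scores are present and both classes occur).
#' @export
evaluate_predictions <- function(predictions, K, class_names = NULL) {
  rep <- eval_confusion(predictions$true_label, predictions$pred_label, K,
                        class_names)
  if (!is.null(predictions$ood_score)) {
    isout <- predictions$true_label == label_unknown()
    if (length(unique(isout)) == 2L) {
      rep$auroc <- auroc(predictions$ood_score, isout)
    }
  }
  rep
}

#' @export
print.osr_eval <- function(x, ...) {
  cat("<osr_eval> n = ", x$n %||% sum(x$confusion),
      ", accuracy = ", sprintf("%.3f", x$accuracy),
      if (!is.na(x$auroc)) sprintf(", AUROC = %.3f", x$auroc) else "",
      "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @rdname eval_confusion
#' @param x An `osr_eval` object.
#' @param ... Unused.
#' @export
tidy.osr_eval <- function(x, ...) x$per_class

#' @rdname eval_confusion
#' @export
glance.osr_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, auroc = x$auroc,
         n = x$n %||% sum(x$confusion))
}

#' Confusion-matrix heatmap for an evaluation report
#' @param object An `osr_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.osr_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$confusion))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted", y = "true", fill = "count",
                  title = sprintf("accuracy %.3f", object$accuracy)) +
    ggplot2::theme_minimal()
}

#' Write / read an evaluation report
#'
#' The scalar metrics and per-class vectors go to JSON; the confusion matrix
#' goes to a CSV with a header row of class names. [read_eval_report()]
#' round-trips both.
#'
#' @param report An `osr_eval`.
#' @param path Basename; writes `<path>.json` and `<path>_confusion.csv`.
#' @return `path` (write) or an `osr_eval` (read), invisibly for write.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(accuracy = report$accuracy, auroc = report$auroc, n = report$n,
         per_class = report$per_class),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null"
  )
  cm <- report$confusion
  out <- cbind(data.frame(class = rownames(cm)),
               as.data.frame(cm, check.names = FALSE))
  write.csv(out, paste0(path, "_confusion.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cmdf <- read.csv(paste0(path, "_confusion.csv"), check.names = FALSE)
  cm <- as.matrix(cmdf[, -1])
  rownames(cm) <- cmdf[[1]]
  structure(
    list(confusion = cm, accuracy = meta$accuracy,
         per_class = as_tibble(meta$per_class),
         auroc = meta$auroc %||% NA_real_, n = meta$n),
    class = "osr_eval"
  )
}

#' Read a benchmark confusion matrix shipped as CSV
#'
#' Loads a confusion-matrix CSV (first column true-class names, remaining
#' columns predicted counts) into an `osr_eval`, recomputing accuracy and
#' per-class precision/recall from the printed integer counts. The package
#' ships two such reference tables from a published eight-class
#' strawberry-disease open-set study under `inst/extdata/`.
#'
#' @param path CSV file path.
#' @return An `osr_eval`.
#' @export
#' @examples
#' cm <- read_confusion_csv(system.file("extdata", "confusion_twohead.csv",
#'                                      package = "opensetr"))
#' glance(cm)
read_confusion_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  cm <- as.matrix(df[, -1])
  storage.mode(cm) <- "integer"
  rownames(cm) <- df[[1]]
  structure(
    list(confusion = cm, accuracy = accuracy_from_confusion(cm),
         per_class = confusion_margins(cm), auroc = NA_real_, n = sum(cm)),
    class = "osr_eval"
  )
}
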
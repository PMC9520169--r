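#' Write a dataset bundle to disk as PNG images plus CSV manifests
#'
#' Images go under `directory/images/<sample_id>.png`; each split gets a CSV
#' manifest (`<split>.csv`, UTF-8, header row) with columns `sample_id`,
#' `relative_path`, `label`, `outlier_type`; the schema is dumped to
#' `schema.json`. Generator output lives on the 8-bit intensity grid, so the
#' layout round-trips pixel-exactly through [read_manifest()]. Feature bundles
#' store vectors inline in a single `features.csv`.
#'
#' @param bundle An `osr_bundle`.
#' @param directory Target directory (created if missing).
#' @param overwrite Refuse to clobber an existing manifest unless `TRUE`.
#' @return `directory`, invisibly.
#' @export
write_manifest <- function(bundle, directory, overwrite = FALSE) {
  stopifnot(inherits(bundle, "osr_bundle"))
  schema <- bundle_schema(bundle)
  if (dir.exists(directory) && file.exists(file.path(directory, "schema.json")) &&
      !overwrite) {
    abort(sprintf("A manifest already exists in '%s'; use overwrite = TRUE.", directory))
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(K = schema$K, class_names = schema$class_names,
         image_size = schema$image_size, dim = schema$dim,
         separation = schema$separation,
         outlier_mix = as.list(schema$outlier_mix), type = schema$type),
    file.path(directory, "schema.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  is_image <- identical(schema$type, "image")
  if (is_image) {
    dir.create(file.path(directory, "images"), showWarnings = FALSE)
    for (i in seq_len(nrow(bundle))) {
      png::writePNG(bundle$pixels[[i]],
                    file.path(directory, "images", paste0(bundle$sample_id[i], ".png")))
    }
  } else {
    feat <- do.call(rbind, bundle$features)
    df <- data.frame(sample_id = bundle$sample_id)
    if (nrow(bundle)) df <- cbind(df, as.data.frame(feat)) else df$sample_id <- character()
    write.csv(df, file.path(directory, "features.csv"), row.names = FALSE,
              fileEncoding = "UTF-8")
  }
  for (sp in c("labeled_train", "unlabeled", "validation", "test", "ood_train")) {
    rows <- bundle[bundle$split == sp, , drop = FALSE]
    rel <- if (is_image) {
      vapply(rows$sample_id, function(id) file.path("images", paste0(id, ".png")),
             character(1), USE.NAMES = FALSE)
    } else {
      rep("features.csv", nrow(rows))
    }
    man <- data.frame(
      sample_id = rows$sample_id, relative_path = rel,
      label = rows$label, outlier_type = rows$outlier_type,
      stringsAsFactors = FALSE
    )
    write.csv(man, file.path(directory, paste0(sp, ".csv")), row.names = FALSE,
              fileEncoding = "UTF-8")
  }
  invisible(directory)
}

#' Read a dataset bundle written by [write_manifest()]
#'
#' @param directory Directory containing `schema.json` and split manifests.
#' @return An `osr_bundle`.
#' @export
read_manifest <- function(directory) {
  sj <- file.path(directory, "schema.json")
  if (!file.exists(sj)) abort(sprintf("No schema.json found in '%s'.", directory))
  sc <- jsonlite::read_json(sj, simplifyVector = TRUE)
  schema <- if (identical(sc$type, "image")) {
    dataset_schema(sc$K, sc$class_names, sc$image_size, unlist(sc$outlier_mix))
  } else {
    structure(
      list(K = as.integer(sc$K), class_names = sc$class_names,
           dim = as.integer(sc$dim), separation = sc$separation,
           type = "feature", outlier_mix = unlist(sc$outlier_mix)),
      class = "osr_schema"
    )
  }
  feats <- NULL
  if (!identical(sc$type, "image")) {
    fcsv <- read.csv(file.path(directory, "features.csv"), check.names = FALSE)
    feats <- setNames(
      lapply(seq_len(nrow(fcsv)), function(i) as.numeric(fcsv[i, -1])),
      fcsv$sample_id
    )
  }
  parts <- lapply(c("labeled_train", "unlabeled", "validation", "test", "ood_train"),
    function(sp) {
      man <- read.csv(file.path(directory, paste0(sp, ".csv")),
                      colClasses = c("character", "character", "integer", "character"))
      tbl <- tibble(
        sample_id = man$sample_id, split = rep(sp, nrow(man)),
        label = man$label, outlier_type = man$outlier_type
      )
      if (identical(sc$type, "image")) {
        tbl$pixels <- lapply(file.path(directory, man$relative_path), function(p) {
          px <- png::readPNG(p)
          if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
          px[, , 1:3, drop = FALSE]
        })
      } else {
        tbl$features <- unname(feats[man$sample_id])
      }
      tbl
    })
  new_bundle(dplyr::bind_rows(parts), schema)
}
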
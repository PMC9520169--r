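#' Define the schema of a synthetic open-set dataset
#'
#' A schema fixes the number of known classes `K`, their names, the square
#' image size, and the mixing proportions of the three outlier families used
#' throughout: `irrelevant` (non-plant texture), `normal` (healthy tissue, no
#' lesion) and `unknown_disease` (a lesion motif disjoint from every known
#' class).
#'
#' @param K Number of known classes (>= 2).
#' @param class_names Optional character vector of length `K`.
#' @param image_size Pixels per side of the square RGB images (default 64).
#' @param outlier_mix Named numeric vector of proportions over
#'   `c("irrelevant", "normal", "unknown_disease")`; must sum to 1.
#' @return An object of class `osr_schema`.
#' @export
#' @examples
#' dataset_schema(K = 4)
dataset_schema <- function(K,
                           class_names = NULL,
                           image_size = 64,
                           outlier_mix = c(irrelevant = 1 / 3,
                                           normal = 1 / 3,
                                           unknown_disease = 1 / 3)) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) abort("`K` must be an integer >= 2.")
  if (is.null(class_names)) class_names <- sprintf("class%02d", seq_len(K))
  if (length(class_names) != K) abort("`class_names` must have length `K`.")
  image_size <- as.integer(image_size)
  if (image_size < 8L) abort("`image_size` must be at least 8 pixels.")
  fam <- c("irrelevant", "normal", "unknown_disease")
  if (is.null(names(outlier_mix))) names(outlier_mix) <- fam
  outlier_mix <- outlier_mix[fam]
  if (anyNA(outlier_mix) || any(outlier_mix < 0)) {
    abort("`outlier_mix` must be nonnegative proportions over irrelevant/normal/unknown_disease.")
  }
  if (abs(sum(outlier_mix) - 1) > 1e-9) abort("`outlier_mix` must sum to 1.")
  structure(
    list(K = K, class_names = class_names, image_size = image_size,
         outlier_mix = outlier_mix, type = "image"),
    class = "osr_schema"
  )
}

#' @export
print.osr_schema <- function(x, ...) {
  cat("<osr_schema> ", x$type, " data, K = ", x$K, "\n", sep = "")
  cat("  classes: ", paste(x$class_names, collapse = ", "), "\n", sep = "")
  if (identical(x$type, "image")) {
    cat("  image size: ", x$image_size, "x", x$image_size, " RGB\n", sep = "")
    cat("  outlier mix: ",
        paste(sprintf("%s %.2f", names(x$outlier_mix), x$outlier_mix), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# Per-class visual motifs: a hue band, a lesion-ellipse eccentricity and a
# spot count. Known hues avoid the leaf-green band around 0.33 and the band
# >= 0.72 reserved for the unknown-disease motif, so the open-set structure
# is learnable by construction.
motif_table <- function(K) {
  cand <- seq(0.02, 0.68, length.out = 2 * K + 4)
  cand <- cand[abs(cand - 0.33) > 0.07]
  if (length(cand) < K) cand <- seq(0.0, 0.24, length.out = K)  # tiny-size fallback
  cand <- cand[round(seq(1, length(cand), length.out = K))]  # maximal hue spacing
  tibble(
    label = c(seq_len(K) - 1L, label_unknown()),
    motif = c(sprintf("known_%d", seq_len(K) - 1L), "unknown_disease"),
    hue = c(cand[seq_len(K)], 0.80),
    eccentricity = c(0.25 + 0.5 * ((seq_len(K) - 1L) %% 4) / 4, 0.95),
    spots = c(3L + ((seq_len(K) - 1L) %% 3), 8L)
  )
}

# Vectorized HSV -> RGB (h, s, v in [0,1]).
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

# Noisy green leaf background.
render_background <- function(size) {
  n <- size * size
  col <- hsv_to_rgb(h = 0.33 + runif(n, -0.02, 0.02),
                    s = runif(n, 0.45, 0.65),
                    v = runif(n, 0.35, 0.60))
  px <- array(0, dim = c(size, size, 3))
  px[, , 1] <- col$r
  px[, , 2] <- col$g
  px[, , 3] <- col$b
  px
}

# Lesioned leaf: `spots` rotated ellipses of the motif hue on a leaf background.
render_lesion <- function(size, hue, eccentricity, spots) {
  px <- render_background(size)
  xg <- matrix(seq_len(size), size, size)
  yg <- matrix(seq_len(size), size, size, byrow = TRUE)
  b_over_a <- sqrt(1 - eccentricity^2)
  for (s in seq_len(spots)) {
    cx <- runif(1, 0.2 * size, 0.8 * size)
    cy <- runif(1, 0.2 * size, 0.8 * size)
    a <- runif(1, 0.11 * size, 0.19 * size)
    b <- max(a * b_over_a, 1.2)
    th <- runif(1, 0, pi)
    dx <- (xg - cx) * cos(th) + (yg - cy) * sin(th)
    dy <- -(xg - cx) * sin(th) + (yg - cy) * cos(th)
    mask <- (dx / a)^2 + (dy / b)^2 <= 1
    n_in <- sum(mask)
    if (n_in == 0) next
    col <- hsv_to_rgb(h = hue + runif(n_in, -0.015, 0.015),
                      s = runif(n_in, 0.65, 0.9),
                      v = runif(n_in, 0.55, 0.85))
    r <- px[, , 1]; g <- px[, , 2]; bl <- px[, , 3]
    r[mask] <- col$r; g[mask] <- col$g; bl[mask] <- col$b
    px[, , 1] <- r; px[, , 2] <- g; px[, , 3] <- bl
  }
  px
}

# Non-plant outlier: smooth random color field.
render_irrelevant <- function(size) {
  base <- array(runif(3 * 16 * 16), dim = c(16, 16, 3))
  idx <- ceiling(seq_len(size) / (size / 16))
  px <- base[idx, idx, , drop = FALSE]
  px <- px + array(runif(3 * size * size, -0.08, 0.08), dim = c(size, size, 3))
  pmax(pmin(px, 1), 0)
}

render_sample <- function(kind, schema, motifs) {
  size <- schema$image_size
  switch(kind,
    irrelevant = render_irrelevant(size),
    normal = render_background(size),
    unknown_disease = {
      m <- motifs[motifs$motif == "unknown_disease", ]
      render_lesion(size, m$hue, m$eccentricity, m$spots)
    },
    {
      m <- motifs[motifs$label == as.integer(kind), ]
      render_lesion(size, m$hue, m$eccentricity, m$spots)
    }
  )
}

# Snap intensities to the 8-bit grid so PNG serialization is lossless and
# byte-identical across platforms.
quantize8 <- function(px) round(px * 255) / 255

# Integer allocation of n over proportions, exact under largest remainders.
split_counts <- function(n, probs) {
  raw <- n * probs / sum(probs)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

new_bundle <- function(tbl, schema) {
  if (anyDuplicated(tbl$sample_id)) abort("sample_ids must be unique across splits.")
  structure(tbl, class = c("osr_bundle", class(tibble())), schema = schema)
}

#' Schema attached to a dataset bundle
#' @param bundle An `osr_bundle` tibble.
#' @return The `osr_schema` the bundle was generated under.
#' @export
bundle_schema <- function(bundle) attr(bundle, "schema")

#' Extract one split of a dataset bundle
#' @param bundle An `osr_bundle` tibble.
#' @param split One of `"labeled_train"`, `"unlabeled"`, `"validation"`,
#'   `"test"`, `"ood_train"`.
#' @return The rows of that split (schema attribute preserved).
#' @export
bundle_split <- function(bundle, split) {
  split <- match.arg(split,
                     c("labeled_train", "unlabeled", "validation", "test", "ood_train"))
  new_bundle(bundle[bundle$split == split, , drop = FALSE], bundle_schema(bundle))
}

# One split's worth of samples: inlier labels drawn round-robin over classes,
# outliers drawn per family mix.
generate_split <- function(schema, motifs, prefix, n_inlier, n_outlier, mix) {
  fam <- c("irrelevant", "normal", "unknown_disease")
  labels <- integer(0)
  kinds <- character(0)
  if (n_inlier > 0) {
    labels <- rep(seq_len(schema$K) - 1L, length.out = n_inlier)
    kinds <- as.character(labels)
  }
  if (n_outlier > 0) {
    counts <- split_counts(n_outlier, mix)
    kinds <- c(kinds, rep(fam, counts))
    labels <- c(labels, rep(label_unknown(), n_outlier))
  }
  n <- length(labels)
  if (n == 0) {
    return(tibble(sample_id = character(), label = integer(),
                  outlier_type = character(), pixels = list()))
  }
  perm <- sample.int(n)
  labels <- labels[perm]
  kinds <- kinds[perm]
  tibble(
    sample_id = sprintf("%s-%04d", prefix, seq_len(n)),
    label = labels,
    outlier_type = ifelse(kinds %in% fam, kinds, "none"),
    pixels = lapply(kinds, function(k) {
      quantize8(render_sample(k, schema = schema, motifs = motifs))
    })
  )
}

#' Generate a deterministic synthetic open-set image dataset
#'
#' Emulates the structure of a multi-class plant-disease image study: `K`
#' known classes, each rendered as a class-specific lesion motif (hue band,
#' ellipse eccentricity, spot count) on a noisy green leaf background, plus
#' three outlier families — `irrelevant` non-plant textures, `normal`
#' lesion-free tissue, and an `unknown_disease` motif whose parameters are
#' disjoint from every known class. The unlabeled, validation and test splits
#' are mixtures of held-out inliers and outliers (default 50/50); `ood_train`
#' contains only outliers and is the exposure set used during fine-tuning.
#'
#' Identical `seed` yields byte-identical output. Ground-truth labels are
#' carried on every split (outliers as [label_unknown()]) so the quality of
#' pseudo-labeling can be evaluated; trainers only consume labels from
#' `labeled_train`.
#'
#' @param schema An [dataset_schema()].
#' @param n_labeled_per_class Labeled training images per known class.
#' @param n_unlabeled,n_val,n_test Total sizes of the mixed splits.
#' @param n_ood Size of the outlier-exposure training split.
#' @param seed Integer seed (mandatory).
#' @param inlier_fraction Proportion of inliers inside unlabeled/validation/
#'   test splits (default 0.5).
#' @param ood_train_mix Optional family mix for `ood_train` only (defaults to
#'   `schema$outlier_mix`); used by the outlier-composition ablation.
#' @return An `osr_bundle`: a tibble with columns `sample_id`, `split`,
#'   `label`, `outlier_type`, `pixels` and the schema as attribute.
#' @export
#' @examples
#' b <- generate_dataset(dataset_schema(K = 3, image_size = 16),
#'                       n_labeled_per_class = 2, n_unlabeled = 4, n_ood = 3,
#'                       n_val = 4, n_test = 4, seed = 1)
#' dplyr::count(b, split)
generate_dataset <- function(schema, n_labeled_per_class, n_unlabeled, n_ood,
                             n_val, n_test, seed,
                             inlier_fraction = 0.5, ood_train_mix = NULL) {
  stopifnot(inherits(schema, "osr_schema"))
  for (nm in c("n_labeled_per_class", "n_unlabeled", "n_ood", "n_val", "n_test")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      abort(sprintf("`%s` must be a single nonnegative count.", nm))
    }
  }
  if (missing(seed)) abort("`seed` is required for reproducible generation.")
  mix <- schema$outlier_mix
  ood_mix <- ood_train_mix %||% mix
  motifs <- motif_table(schema$K)
  parts <- list(
    labeled_train = with_seed(derive_seed(seed, 1), {
      generate_split(schema, motifs, "tr", schema$K * n_labeled_per_class, 0, mix)
    }),
    unlabeled = with_seed(derive_seed(seed, 2), {
      n_in <- round(n_unlabeled * inlier_fraction)
      generate_split(schema, motifs, "un", n_in, n_unlabeled - n_in, mix)
    }),
    validation = with_seed(derive_seed(seed, 3), {
      n_in <- round(n_val * inlier_fraction)
      generate_split(schema, motifs, "va", n_in, n_val - n_in, mix)
    }),
    test = with_seed(derive_seed(seed, 4), {
      n_in <- round(n_test * inlier_fraction)
      generate_split(schema, motifs, "te", n_in, n_test - n_in, mix)
    }),
    ood_train = with_seed(derive_seed(seed, 5), {
      generate_split(schema, motifs, "ood", 0, n_ood, ood_mix)
    })
  )
  tbl <- dplyr::bind_rows(parts, .id = "split")
  tbl <- tbl[, c("sample_id", "split", "label", "outlier_type", "pixels")]
  new_bundle(tbl, schema)
}

#' Generate a Gaussian-cluster feature dataset (fast non-image path)
#'
#' A vector-space analogue of [generate_dataset()] that bypasses image
#' rendering: `K` unit-variance Gaussian clusters whose means are mutually
#' orthogonal with norm `separation` (so mean spacing is proportional to
#' `separation`), plus outliers drawn on a shell well outside the cluster
#' region. Feeds the same losses and trainers; used for fast unit tests.
#'
#' @param K Number of known classes (>= 2).
#' @param dim Feature dimension (>= 1).
#' @param n_per_class Labeled training vectors per class.
#' @param n_outliers Size of `ood_train`.
#' @param separation Distance scale between cluster means (> 0).
#' @param seed Integer seed.
#' @param n_unlabeled,n_val,n_test Optional mixed-split sizes (default 0).
#' @param inlier_fraction Inlier proportion of the mixed splits.
#' @return An `osr_bundle` with a `features` list-column instead of `pixels`.
#' @export
generate_feature_dataset <- function(K, dim, n_per_class, n_outliers, separation,
                                     seed, n_unlabeled = 0, n_val = 0, n_test = 0,
                                     inlier_fraction = 0.5) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) abort("`K` must be an integer >= 2.")
  if (!is.numeric(dim) || dim < 1) abort("`dim` must be >= 1.")
  if (!is.numeric(separation) || separation <= 0) abort("`separation` must be > 0.")
  for (nm in c("n_per_class", "n_outliers", "n_unlabeled", "n_val", "n_test")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 0) abort(sprintf("`%s` must be a nonnegative count.", nm))
  }
  dim <- as.integer(dim)
  schema <- structure(
    list(K = K, class_names = sprintf("class%02d", seq_len(K)), dim = dim,
         separation = separation, type = "feature",
         outlier_mix = c(irrelevant = 0, normal = 0, unknown_disease = 1)),
    class = "osr_schema"
  )
  with_seed(seed, {
    means <- matrix(rnorm(dim * K), dim, K)
    if (dim >= K) {
      means <- qr.Q(qr(means))[, seq_len(K), drop = FALSE] * separation
    } else {
      means <- apply(means, 2, function(m) m / sqrt(sum(m^2))) * separation
      means <- matrix(means, dim, K)
    }
    draw_inliers <- function(n, prefix) {
      labels <- rep(seq_len(K) - 1L, length.out = n)
      feats <- lapply(labels, function(l) means[, l + 1L] + rnorm(dim))
      tibble(sample_id = sprintf("%s-%04d", prefix, seq_len(n)),
             label = labels, outlier_type = "none", features = feats)
    }
    draw_outliers <- function(n, prefix) {
      feats <- lapply(seq_len(n), function(i) {
        dir <- rnorm(dim)
        dir <- dir / sqrt(sum(dir^2))
        dir * separation * runif(1, 2.0, 2.8) + 0.5 * rnorm(dim)
      })
      tibble(sample_id = sprintf("%s-%04d", prefix, seq_len(n)),
             label = rep(label_unknown(), n), outlier_type = "unknown_disease",
             features = feats)
    }
    mixed_split <- function(n, prefix) {
      n_in <- round(n * inlier_fraction)
      out <- dplyr::bind_rows(draw_inliers(n_in, prefix),
                              draw_outliers(n - n_in, paste0(prefix, "o")))
      if (nrow(out)) out[sample.int(nrow(out)), ] else out
    }
    parts <- list(
      labeled_train = draw_inliers(K * n_per_class, "tr"),
      unlabeled = mixed_split(n_unlabeled, "un"),
      validation = mixed_split(n_val, "va"),
      test = mixed_split(n_test, "te"),
      ood_train = draw_outliers(n_outliers, "ood")
    )
    tbl <- dplyr::bind_rows(parts, .id = "split")
    new_bundle(tbl[, c("sample_id", "split", "label", "outlier_type", "features")],
               schema)
  })
}
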
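test_that("schema validation rejects bad inputs naming the field", {
  expect_error(dataset_schema(K = 1), "K")
  expect_error(dataset_schema(K = 4, outlier_mix = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(
    generate_dataset(tiny_schema(), n_labeled_per_class = -1, n_unlabeled = 0,
                     n_ood = 0, n_val = 0, n_test = 0, seed = 1),
    "n_labeled_per_class"
  )
  expect_error(
    generate_dataset(tiny_schema(), 1, 1, 1, 1, 1),
    "seed"
  )
})

test_that("labeled count bookkeeping holds (K classes x n per class)", {
  sc <- dataset_schema(K = 8, image_size = 16)
  b <- generate_dataset(sc, n_labeled_per_class = 10, n_unlabeled = 0,
                        n_ood = 0, n_val = 0, n_test = 0, seed = 1)
  lab <- bundle_split(b, "labeled_train")
  expect_equal(nrow(lab), 80L)
  expect_true(all(lab$label %in% 0:7))
  expect_equal(as.integer(table(lab$label)), rep(10L, 8))
})

test_that("identical seed reproduces pixels and manifest byte-identically", {
  b1 <- tiny_image_bundle(seed = 7)
  b2 <- tiny_image_bundle(seed = 7)
  expect_identical(b1$sample_id, b2$sample_id)
  expect_identical(b1$label, b2$label)
  expect_identical(b1$pixels, b2$pixels)
  f1 <- tempfile(); f2 <- tempfile()
  saveRDS(b1$pixels, f1, compress = FALSE)
  saveRDS(b2$pixels, f2, compress = FALSE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  b3 <- tiny_image_bundle(seed = 8)
  expect_false(identical(b1$pixels, b3$pixels))
})

test_that("outlier mix allocation is exact by largest remainders", {
  sc <- dataset_schema(K = 3, image_size = 16)
  b <- generate_dataset(sc, n_labeled_per_class = 0, n_unlabeled = 0,
                        n_ood = 90, n_val = 0, n_test = 0, seed = 2)
  tally <- table(bundle_split(b, "ood_train")$outlier_type)
  expect_equal(as.integer(tally[c("irrelevant", "normal", "unknown_disease")]),
               c(30L, 30L, 30L))
})

test_that("pixels are finite, in [0,1], and labels match outlier types", {
  b <- tiny_image_bundle()
  for (px in b$pixels) {
    expect_true(all(is.finite(px)))
    expect_true(all(px >= 0 & px <= 1))
    expect_equal(dim(px), c(16L, 16L, 3L))
  }
  expect_true(all((b$label == label_unknown()) == (b$outlier_type != "none")))
})

test_that("sample ids are unique and splits disjoint", {
  b <- tiny_image_bundle()
  expect_equal(anyDuplicated(b$sample_id), 0L)
  ids <- split(b$sample_id, b$split)
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    expect_length(intersect(ids[[i]], ids[[j]]), 0)
  }
})

test_that("unknown-disease motif parameters are disjoint from known motifs", {
  for (K in c(2, 4, 8)) {
    motifs <- opensetr:::motif_table(K)
    unk <- motifs[motifs$motif == "unknown_disease", ]
    known <- motifs[motifs$motif != "unknown_disease", ]
    expect_true(all(abs(known$hue - unk$hue) > 0.05))
    expect_false(any(known$hue == unk$hue & known$eccentricity == unk$eccentricity &
                       known$spots == unk$spots))
  }
})

test_that("feature generator rejects bad preconditions", {
  expect_error(generate_feature_dataset(3, 6, 5, 5, separation = 0, seed = 1),
               "separation")
  expect_error(generate_feature_dataset(3, 0, 5, 5, separation = 1, seed = 1),
               "dim")
})

test_that("feature generator: counts and nearest-centroid recovery", {
  b <- generate_feature_dataset(3, 6, 5, 0, separation = 10, seed = 1)
  expect_equal(nrow(bundle_split(b, "labeled_train")), 15L)
  # held-out sample, nearest-centroid oracle
  big <- generate_feature_dataset(3, 6, 100, 0, separation = 10, seed = 5,
                                  n_test = 300, inlier_fraction = 1)
  lab <- bundle_split(big, "labeled_train")
  te <- bundle_split(big, "test")
  X <- do.call(rbind, lab$features)
  cent <- sapply(0:2, function(k) colMeans(X[lab$label == k, , drop = FALSE]))
  pred <- apply(do.call(rbind, te$features), 1,
                function(x) which.min(colSums((cent - x)^2)) - 1)
  expect_gte(mean(pred == te$label), 0.99)
})

test_that("manifest round-trips bundles losslessly", {
  b <- tiny_image_bundle(seed = 3)
  dir <- file.path(tempdir(), "osr-manifest-test")
  unlink(dir, recursive = TRUE)
  write_manifest(b, dir)
  expect_error(write_manifest(b, dir), "overwrite")
  b2 <- read_manifest(dir)
  expect_equal(b2$sample_id, b$sample_id)
  expect_equal(b2$label, b$label)
  expect_equal(b2$outlier_type, b$outlier_type)
  for (i in seq_len(nrow(b))) expect_equal(b2$pixels[[i]], b$pixels[[i]])
  sc2 <- bundle_schema(b2)
  expect_equal(sc2$K, bundle_schema(b)$K)
  unlink(dir, recursive = TRUE)
})

test_that("manifests cover every sample and tolerate empty bundles", {
  sc <- dataset_schema(K = 2, image_size = 8)
  b <- generate_dataset(sc, n_labeled_per_class = 2, n_unlabeled = 3,
                        n_ood = 2, n_val = 2, n_test = 2, seed = 1)
  expect_equal(nrow(b), 13L)
  dir <- file.path(tempdir(), "osr-manifest-13")
  unlink(dir, recursive = TRUE)
  write_manifest(b, dir)
  rows <- sum(vapply(
    c("labeled_train", "unlabeled", "validation", "test", "ood_train"),
    function(sp) nrow(read.csv(file.path(dir, paste0(sp, ".csv")))), numeric(1)
  ))
  expect_equal(rows, 13)
  unlink(dir, recursive = TRUE)
  empty <- generate_dataset(sc, 0, 0, 0, 0, 0, seed = 1)
  dir2 <- file.path(tempdir(), "osr-manifest-empty")
  unlink(dir2, recursive = TRUE)
  write_manifest(empty, dir2)
  man <- read.csv(file.path(dir2, "labeled_train.csv"))
  expect_equal(nrow(man), 0L)
  expect_equal(names(man),
               c("sample_id", "relative_path", "label", "outlier_type"))
  unlink(dir2, recursive = TRUE)
})

test_that("feature bundles round-trip through the manifest too", {
  b <- tiny_feature_bundle(seed = 9)
  dir <- file.path(tempdir(), "osr-manifest-feat")
  unlink(dir, recursive = TRUE)
  write_manifest(b, dir)
  b2 <- read_manifest(dir)
  expect_equal(b2$sample_id, b$sample_id)
  for (i in seq_len(nrow(b))) {
    expect_equal(b2$features[[i]], b$features[[i]], tolerance = 1e-12)
  }
  unlink(dir, recursive = TRUE)
})
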
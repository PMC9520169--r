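#' Create a weak or strong augmentation policy
#'
#' The weak policy is geometric only: a rotation drawn uniformly from
#' \{0, 90, 180, 270\} degrees (4 catalogue entries; the identity is included
#' so the unaugmented view is covered). The strong policy is the 4 x 3 x 3
#' grid of rotation \{0, 90, 180, 270\} x brightness factor \{0.6, 1.0, 1.4\}
#' x saturation shift \{-0.3, 0, +0.3\} — 36 alternatives, matching the
#' convention of drawing one of 36 color/brightness/rotation combinations.
#' The grid is a documented convention; supply `catalogue` to override it.
#'
#' Policies are stateful samplers: repeated [draw_augmentation()] calls on a
#' policy built with the same seed replay the same index sequence.
#'
#' @param kind `"weak"` or `"strong"`.
#' @param seed Integer seed driving the policy's draw sequence.
#' @param catalogue Optional replacement tibble with columns `rotation`,
#'   `brightness`, `saturation`.
#' @return An `osr_policy` object.
#' @export
#' @examples
#' pol <- augmentation_policy("strong", seed = 7)
#' nrow(pol$catalogue)
augmentation_policy <- function(kind = c("weak", "strong"), seed = 0L,
                                catalogue = NULL) {
  kind <- match.arg(kind)
  if (is.null(catalogue)) {
    catalogue <- if (kind == "weak") {
      tibble(rotation = c(0L, 90L, 180L, 270L), brightness = 1, saturation = 0)
    } else {
      g <- expand.grid(rotation = c(0L, 90L, 180L, 270L),
                       brightness = c(0.6, 1.0, 1.4),
                       saturation = c(-0.3, 0, 0.3))
      as_tibble(g)
    }
  }
  state <- new.env(parent = emptyenv())
  state$counter <- 0L
  structure(
    list(kind = kind, catalogue = as_tibble(catalogue),
         rng_seed = as.integer(seed), state = state),
    class = "osr_policy"
  )
}

#' Draw the next catalogue index from a policy's seeded stream
#' @param policy An `osr_policy`.
#' @return A 0-based catalogue index.
#' @export
draw_augmentation <- function(policy) {
  stopifnot(inherits(policy, "osr_policy"))
  policy$state$counter <- policy$state$counter + 1L
  with_seed(derive_seed(policy$rng_seed, policy$state$counter),
            sample.int(nrow(policy$catalogue), 1L)) - 1L
}

# Rotate an H x W (or H x W x 3) image 90 degrees counter-clockwise `k` times.
rotate_image <- function(px, k) {
  k <- as.integer(k) %% 4L
  if (k == 0L) return(px)
  rot1 <- function(m) t(m)[ncol(m):1, , drop = FALSE]
  if (length(dim(px)) == 2L) {
    for (i in seq_len(k)) px <- rot1(px)
    return(px)
  }
  chans <- lapply(seq_len(dim(px)[3]), function(c) {
    m <- px[, , c]
    for (i in seq_len(k)) m <- rot1(m)
    m
  })
  out <- array(0, dim = c(dim(chans[[1]]), length(chans)))
  for (c in seq_along(chans)) out[, , c] <- chans[[c]]
  out
}

apply_transform <- function(px, rotation, brightness, saturation) {
  px <- rotate_image(px, rotation / 90)
  if (brightness != 1) px <- px * brightness
  if (saturation != 0) {
    gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
    f <- 1 + saturation
    for (c in 1:3) px[, , c] <- gray + f * (px[, , c] - gray)
  }
  pmax(pmin(px, 1), 0)
}

aug_pixels <- function(sample) if (is.array(sample)) sample else sample$pixels[[1]]

aug_rewrap <- function(sample, px) {
  if (is.array(sample)) return(px)
  sample$pixels[[1]] <- px
  sample
}

#' Weakly augment a sample (rotation only)
#'
#' Applies a rotation from \{0, 90, 180, 270\} degrees — either
#' `catalogue[index + 1]` or the policy's next seeded draw. Labels and outlier
#' types are untouched; rotation permutes pixels, so intensities are
#' preserved exactly. Non-square inputs have their dimensions swapped by
#' 90/270-degree rotations.
#'
#' @param sample A pixel array or a one-row bundle tibble.
#' @param policy A weak `osr_policy`.
#' @param index Optional 0-based catalogue index.
#' @return Same type as `sample`.
#' @export
weak_augment <- function(sample, policy, index = NULL) {
  stopifnot(inherits(policy, "osr_policy"))
  if (policy$kind != "weak") abort("`policy` must be a weak policy.")
  idx <- index %||% draw_augmentation(policy)
  if (idx < 0 || idx >= nrow(policy$catalogue)) abort("`index` out of range.")
  tr <- policy$catalogue[idx + 1L, ]
  aug_rewrap(sample, rotate_image(aug_pixels(sample), tr$rotation / 90))
}

#' Strongly augment a sample (rotation x brightness x saturation)
#'
#' Applies the composed transform `catalogue[index + 1]` (or a seeded draw):
#' rotation, then multiplicative brightness, then a saturation shift
#' implemented as scaling the distance from the per-pixel gray level; output
#' is clipped to `[0, 1]`.
#'
#' @inheritParams weak_augment
#' @param policy A strong `osr_policy`.
#' @return Same type as `sample`.
#' @export
strong_augment <- function(sample, policy, index = NULL) {
  stopifnot(inherits(policy, "osr_policy"))
  if (policy$kind != "strong") abort("`policy` must be a strong policy.")
  idx <- index %||% draw_augmentation(policy)
  if (idx < 0 || idx >= nrow(policy$catalogue)) abort("`index` out of range.")
  tr <- policy$catalogue[idx + 1L, ]
  aug_rewrap(sample,
             apply_transform(aug_pixels(sample), tr$rotation, tr$brightness,
                             tr$saturation))
}

#' Serialize an augmentation policy to YAML
#' @param policy An `osr_policy`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_policy <- function(policy, path) {
  yaml::write_yaml(
    list(kind = policy$kind, rng_seed = policy$rng_seed,
         catalogue = lapply(seq_len(nrow(policy$catalogue)), function(i) {
           as.list(policy$catalogue[i, ])
         })),
    path
  )
  invisible(path)
}

#' Read an augmentation policy from YAML
#' @param path File written by [write_policy()].
#' @return An `osr_policy`.
#' @export
read_policy <- function(path) {
  y <- yaml::read_yaml(path)
  augmentation_policy(y$kind, y$rng_seed,
                      catalogue = dplyr::bind_rows(lapply(y$catalogue, as_tibble)))
}
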
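#' Construct a trainable open-set network
#'
#' One shared backbone feeds either two softmax heads (`arch = "twohead"`) or
#' a closed-set softmax head plus `K` one-vs-all (OVA) binary heads
#' (`arch = "openmatch"`), and a projection head used by contrastive
#' regularization. The desk-scale default backbone is a fixed average-pooling
#' stem (images are pooled to a `pool x pool x 3` grid) followed by a
#' one-hidden-layer ReLU perceptron producing an `embed`-dimensional feature;
#' feature-vector datasets skip the stem. The backbone is a contract — any
#' drop-in replacement exposing the same forward/backward surface works — but
#' this small trainable default keeps end-to-end runs at seconds of CPU.
#'
#' @param schema The `osr_schema` of the data the network will consume.
#' @param arch `"twohead"` or `"openmatch"`.
#' @param hidden Hidden width of the backbone.
#' @param embed Embedding dimension of the backbone output.
#' @param proj_dim Output dimension of the (L2-normalized) projection head.
#' @param pool Pooling grid for image input (ignored for feature data).
#' @param seed Seed for random parameter initialization.
#' @return An `osr_network` object with elements `arch`, `K`, `params`, etc.
#' @export
osr_network <- function(schema, arch = c("twohead", "openmatch"), hidden = 48,
                        embed = 32, proj_dim = 16, pool = 8, seed = 1) {
  arch <- match.arg(arch)
  stopifnot(inherits(schema, "osr_schema"))
  K <- schema$K
  d_in <- if (identical(schema$type, "image")) 3L * pool^2 else schema$dim
  init <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  params <- with_seed(seed, {
    p <- list(
      W1 = init(d_in, hidden), b1 = numeric(hidden),
      W2 = init(hidden, embed), b2 = numeric(embed),
      Wp = init(embed, proj_dim), bp = numeric(proj_dim)
    )
    if (arch == "twohead") {
      p$Wh1 <- init(embed, K); p$bh1 <- numeric(K)
      p$Wh2 <- init(embed, K); p$bh2 <- numeric(K)
    } else {
      p$Wc <- init(embed, K); p$bc <- numeric(K)
      p$Wo <- init(embed, 2L * K); p$bo <- numeric(2L * K)
    }
    p
  })
  opt <- new.env(parent = emptyenv())
  opt$velocity <- list()
  structure(
    list(arch = arch, K = K, d_in = d_in, hidden = hidden, embed = embed,
         proj_dim = proj_dim, pool = as.integer(pool), schema = schema,
         params = params, opt = opt),
    class = "osr_network"
  )
}

#' @export
print.osr_network <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat("<osr_network> arch = ", x$arch, ", K = ", x$K,
      ", d_in = ", x$d_in, ", ", np, " parameters\n", sep = "")
  invisible(x)
}

# Block-mean pooling matrix mapping `size` pixels to `pool` cells.
pool_matrix <- function(size, pool) {
  f <- size / pool
  M <- matrix(0, size, pool)
  for (i in seq_len(size)) M[i, ceiling(i / f)] <- 1
  sweep(M, 2, colSums(M), "/")
}

# Stack samples (pixel arrays or feature vectors) into the n x d_in design
# matrix the backbone consumes.
design_matrix <- function(net, samples) {
  if ("features" %in% names(samples)) {
    X <- do.call(rbind, samples$features)
  } else {
    size <- dim(samples$pixels[[1]])[1]
    M <- pool_matrix(size, net$pool)
    X <- do.call(rbind, lapply(samples$pixels, function(px) {
      c(vapply(1:3, function(ch) crossprod(M, px[, , ch]) %*% M,
               matrix(0, net$pool, net$pool)))
    }))
    X <- (X - 0.45) / 0.25  # fixed affine rescale: intensities to roughly unit scale
  }
  if (!all(is.finite(X))) abort("Non-finite values in network input.")
  X
}

forward_backbone <- function(params, X) {
  A1 <- pmax(sweep(X %*% params$W1, 2, params$b1, "+"), 0)
  E <- sweep(A1 %*% params$W2, 2, params$b2, "+")
  list(E = E, X = X, A1 = A1)
}

backbone_backward <- function(params, cache, dE) {
  dA1 <- (dE %*% t(params$W2)) * (cache$A1 > 0)
  list(
    W1 = crossprod(cache$X, dA1), b1 = colSums(dA1),
    W2 = crossprod(cache$A1, dE), b2 = colSums(dE)
  )
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

head_softmax <- function(E, W, b) softmax_rows(sweep(E %*% W, 2, b, "+"))

# dL/dlogits given dL/dP for row-wise softmax.
softmax_backward <- function(P, dP) P * (dP - rowSums(dP * P))

# OVA heads: per class j a (t=0 inlier, t=1 outlier) logit pair, normalized
# pairwise, so p0 + p1 = 1 by construction. Returns the n x K inlier matrix.
head_ova <- function(E, W, b) {
  L <- sweep(E %*% W, 2, b, "+")
  K <- ncol(L) / 2L
  l0 <- L[, 2L * seq_len(K) - 1L, drop = FALSE]
  l1 <- L[, 2L * seq_len(K), drop = FALSE]
  1 / (1 + exp(l1 - l0))
}

# dL/dlogits (n x 2K) from dL/dp0 and dL/dp1 (each n x K).
ova_backward <- function(P0, g0, g1) {
  K <- ncol(P0)
  dl0 <- P0 * (1 - P0) * (g0 - g1)
  dL <- matrix(0, nrow(P0), 2L * K)
  dL[, 2L * seq_len(K) - 1L] <- dl0
  dL[, 2L * seq_len(K)] <- -dl0
  dL
}

forward_projection_raw <- function(params, E) {
  V <- sweep(E %*% params$Wp, 2, params$bp, "+")
  nrm <- sqrt(rowSums(V^2))
  nrm[nrm < 1e-12] <- 1e-12
  list(Z = V / nrm, V = V, nrm = nrm)
}

projection_backward <- function(proj, dZ) {
  (dZ - proj$Z * rowSums(dZ * proj$Z)) / proj$nrm
}

#' Forward pass of a two-head network
#'
#' Both softmax heads consume the same backbone embedding; each row of `p1`
#' and `p2` is a length-`K` probability vector.
#'
#' @param net An `osr_network` with `arch = "twohead"`.
#' @param data Bundle rows (tibble with `pixels` or `features`).
#' @return A list with matrices `p1`, `p2`, the embedding `embed`, and
#'   `sample_id`.
#' @export
forward_twohead <- function(net, data) {
  stopifnot(inherits(net, "osr_network"))
  if (net$arch != "twohead") abort("`net` is not a two-head network.")
  bb <- forward_backbone(net$params, design_matrix(net, data))
  if (!all(is.finite(bb$E))) {
    abort(sprintf("Non-finite embedding for %d row(s); check input scaling.",
                  sum(!is.finite(rowSums(bb$E)))))
  }
  list(p1 = head_softmax(bb$E, net$params$Wh1, net$params$bh1),
       p2 = head_softmax(bb$E, net$params$Wh2, net$params$bh2),
       embed = bb$E, sample_id = data$sample_id)
}

#' Forward pass of an OpenMatch network
#'
#' The closed-set softmax head and the `K` OVA heads consume the same
#' backbone embedding. `p_ova0[i, j]` is the probability that sample `i` is
#' an inlier with respect to class `j` (`p(t=0)`); the outlier probability is
#' `1 - p_ova0`.
#'
#' @param net An `osr_network` with `arch = "openmatch"`.
#' @param data Bundle rows.
#' @return A list with `p_closed` (n x K), `p_ova0` (n x K), `embed`,
#'   `sample_id`.
#' @export
forward_openmatch <- function(net, data) {
  stopifnot(inherits(net, "osr_network"))
  if (net$arch != "openmatch") abort("`net` is not an OpenMatch network.")
  bb <- forward_backbone(net$params, design_matrix(net, data))
  if (!all(is.finite(bb$E))) {
    abort(sprintf("Non-finite embedding for %d row(s); check input scaling.",
                  sum(!is.finite(rowSums(bb$E)))))
  }
  list(p_closed = head_softmax(bb$E, net$params$Wc, net$params$bc),
       p_ova0 = head_ova(bb$E, net$params$Wo, net$params$bo),
       embed = bb$E, sample_id = data$sample_id)
}

#' Save / load network checkpoints
#'
#' The parameter state goes to a single serialized file; a JSON sidecar
#' (`<path>.json`) records the architecture (K, dims, head layout) for
#' validation on load.
#'
#' @param net An `osr_network`.
#' @param path Checkpoint file path.
#' @return `path` (write) or an `osr_network` (read).
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  jsonlite::write_json(
    list(arch = net$arch, K = net$K, d_in = net$d_in, hidden = net$hidden,
         embed = net$embed, proj_dim = net$proj_dim, pool = net$pool),
    paste0(path, ".json"), auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!identical(meta$K, net$K) || !identical(meta$arch, net$arch)) {
      abort("Checkpoint sidecar does not match the serialized network.")
    }
  }
  net
}

# Plain SGD step over named parameter lists.
sgd_step <- function(params, grads, lr) {
  for (nm in names(grads)) {
    if (!is.null(grads[[nm]])) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  }
  params
}

grad_accumulate <- function(acc, g) {
  for (nm in names(g)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) g[[nm]] else acc[[nm]] + g[[nm]]
  }
  acc
}

# Cosine decay from lr0 to ~0 over `total` epochs.
cosine_lr <- function(lr0, epoch, total) {
  lr0 * 0.5 * (1 + cos(pi * (epoch - 1) / max(total, 1)))
}
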
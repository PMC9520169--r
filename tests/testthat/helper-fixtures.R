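# Small fixtures shared across test files; everything is generated in code.

tiny_schema <- function(K = 3, size = 16) dataset_schema(K = K, image_size = size)

tiny_image_bundle <- function(seed = 42, K = 3, size = 16) {
  generate_dataset(tiny_schema(K, size), n_labeled_per_class = 4,
                   n_unlabeled = 9, n_ood = 6, n_val = 8, n_test = 10,
                   seed = seed)
}

tiny_feature_bundle <- function(seed = 42, K = 3, dim = 6, sep = 6) {
  generate_feature_dataset(K, dim, n_per_class = 6, n_outliers = 10,
                           separation = sep, seed = seed, n_unlabeled = 20,
                           n_val = 16, n_test = 24)
}

# Random probability matrix with rows summing to 1.
random_prob <- function(n, K) {
  m <- matrix(stats::rexp(n * K), n, K)
  m / rowSums(m)
}

# Random OVA inlier-probability matrix (entries free in (0, 1)).
random_ova <- function(n, K) matrix(stats::runif(n * K, 0.05, 0.95), n, K)
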
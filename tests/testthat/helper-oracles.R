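# Independent oracles and small fixture builders used across the suite.

# textbook type-II DCT as an explicit double sum (orthonormal scaling);
# deliberately naive so it cannot share code with the matrix-product path
dct2_bruteforce <- function(x) {
  S <- nrow(x)
  a <- function(u) if (u == 0) sqrt(1 / S) else sqrt(2 / S)
  z <- matrix(0, S, S)
  for (u in 0:(S - 1)) {
    for (v in 0:(S - 1)) {
      acc <- 0
      for (m in 0:(S - 1)) {
        for (n in 0:(S - 1)) {
          acc <- acc + x[m + 1, n + 1] *
            cos((2 * m + 1) * u * pi / (2 * S)) *
            cos((2 * n + 1) * v * pi / (2 * S))
        }
      }
      z[u + 1, v + 1] <- a(u) * a(v) * acc
    }
  }
  z
}

random_rgb <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(h * w * 3, 0, 255), c(h, w, 3))
}

# the published top-24 combination for an 8x8 filter (11-7-6 split)
top24_entries <- list(
  Y = c(0, 1, 3, 4, 5, 8, 12, 16, 24, 32, 40),
  Cb = c(0, 2, 7, 8, 10, 17, 27),
  Cr = c(0, 1, 3, 7, 8, 16)
)

# small labeled feature table with deterministic separable clusters
toy_features <- function(n_classes = 6, per_class = 25, dim = 8, sep = 6, seed = 42) {
  generate_feature_clusters(synthetic_feature_spec(
    n_classes = n_classes, dim = dim, per_class = per_class,
    separation = sep, noise = "gaussian", sigma = 1, seed = seed
  ))
}
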
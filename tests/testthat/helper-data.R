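# Shared fixtures, generated in code and memoised for the test session.

.fixture_cache <- new.env(parent = emptyenv())

# Default-condition synthetic dataset (60 subjects x 8 tasks) and its
# feature matrix; expensive, so computed once per session.
default_feature_fixture <- function(seed = 42L) {
  key <- paste0("fm_", seed)
  if (is.null(.fixture_cache[[key]])) {
    ds <- generate_dataset(generator_config(seed = seed))
    .fixture_cache[[key]] <- c(extract_feature_matrix(ds),
                               list(n_trials = length(ds$trials),
                                    support = class_support(ds)))
  }
  .fixture_cache[[key]]
}

# Fit configuration used for the end-to-end checks: default architecture,
# candidate pairs capped so a layer-1 sweep stays cheap.
capped_fit_config <- function(seed = 7L, ...) {
  fit_config(seed = seed, max_candidate_pairs = 1500L, ...)
}

# Two well-separated Gaussian blobs in 2-D with a few nuisance dimensions:
# the smallest problem on which a fitted network should be near-perfect.
make_blob_data <- function(n_per_class = 30L, seed = 5L, p_noise = 0L) {
  set.seed(seed)
  n <- 2L * n_per_class
  x1 <- c(rnorm(n_per_class, -2, 0.3), rnorm(n_per_class, 2, 0.3))
  x2 <- c(rnorm(n_per_class, -2, 0.3), rnorm(n_per_class, 2, 0.3))
  X <- cbind(x1, x2)
  if (p_noise > 0L) X <- cbind(X, matrix(rnorm(n * p_noise), n, p_noise))
  list(features = X, labels = rep(1:2, each = n_per_class))
}

# Random valid confusion matrix with strictly positive cells (so reference
# implementations never hit a 0/0 convention difference).
random_confusion <- function(K) {
  matrix(stats::rpois(K * K, lambda = 4) + 1L, K, K)
}

# Tiny trial CSV writer for reader tests.
write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Brute-force selection oracle: fit every pair with stats::lm on the explicit
# quadratic formula, score by hand, and take the k best (ties lexicographic).
brute_force_layer <- function(X, Xv, y, yv, width) {
  p <- ncol(X)
  rows <- list()
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    df <- data.frame(y = y, x1 = X[, i], x2 = X[, j])
    fit <- stats::lm(y ~ x1 + x2 + I(x1^2) + I(x2^2) + I(x1 * x2), df)
    pred <- stats::predict(fit, data.frame(x1 = Xv[, i], x2 = Xv[, j]))
    rows[[length(rows) + 1]] <- data.frame(a = i, b = j,
                                           score = mean((pred - yv)^2))
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$score, res$a, res$b), ]
  utils::head(res, width)
}
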
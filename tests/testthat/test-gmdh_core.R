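test_that("neuron forward pass evaluates the quadratic polynomial exactly", {
  nr <- function(b) list(coef = b)
  expect_equal(neuron_forward(nr(c(1, 0, 0, 0, 0, 0)), 7, -3), 1)
  expect_equal(neuron_forward(nr(c(0, 1, 1, 0, 0, 0)), 2, 3), 5)
  expect_equal(neuron_forward(nr(c(0, 0, 0, 1, 1, 1)), 2, 3), 19)
  expect_error(neuron_forward(nr(c(1, 2)), 1, 1), "6 coefficients")
})

test_that("least squares recovers noiseless generating coefficients", {
  set.seed(21)
  for (rep in 1:10) {
    b <- rnorm(6)
    x1 <- rnorm(20); x2 <- rnorm(20)
    y <- neuron_forward(list(coef = b), x1, x2)
    expect_equal(fit_neuron(x1, x2, y), b, tolerance = 1e-8)
  }
  # the spec's worked example
  b <- c(0.5, -1, 2, 0, 1, 3)
  x1 <- runif(20, -2, 2); x2 <- runif(20, -2, 2)
  y <- neuron_forward(list(coef = b), x1, x2)
  expect_equal(fit_neuron(x1, x2, y), b, tolerance = 1e-8)
})

test_that("six general-position points are interpolated exactly", {
  set.seed(22)
  x1 <- rnorm(6); x2 <- rnorm(6); y <- rnorm(6)
  cf <- fit_neuron(x1, x2, y)
  expect_equal(neuron_forward(list(coef = cf), x1, x2), y, tolerance = 1e-6)
})

test_that("rank-deficient designs fall back to a fitting minimum-norm solution", {
  x1 <- rep(2, 10); x2 <- rep(-1, 10); y <- rep(3.5, 10)
  cf <- fit_neuron(x1, x2, y)
  expect_equal(neuron_forward(list(coef = cf), x1, x2), y, tolerance = 1e-10)
  # min-norm beats the basic solution in L2 norm for this degenerate system
  expect_lt(sum(cf^2), 3.5^2 + 1e-9)
})

test_that("neuron scores are validation MSE", {
  nr <- list(coef = c(0, 1, 0, 0, 0, 0))  # y = x1
  expect_equal(score_neuron(nr, c(1, 2), c(0, 0), c(1, 2)), 0)
  zero <- list(coef = rep(0, 6))
  expect_equal(score_neuron(zero, c(1, 2, 3), c(0, 0, 0), c(1, 1, 1)), 1)
  expect_gte(score_neuron(nr, rnorm(5), rnorm(5), rnorm(5)), 0)
  expect_error(score_neuron(nr, numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("layer building equals brute-force top-k selection", {
  set.seed(23)
  for (p in c(3L, 5L, 8L)) {
    X <- matrix(rnorm(40 * p), 40, p)
    Xv <- matrix(rnorm(15 * p), 15, p)
    y <- X[, 1] - 0.5 * X[, 2]^2 + rnorm(40, sd = 0.2)
    yv <- Xv[, 1] - 0.5 * Xv[, 2]^2 + rnorm(15, sd = 0.2)
    width <- min(4L, choose(p, 2))
    got <- build_layer(X, Xv, y, yv, width)
    want <- brute_force_layer(X, Xv, y, yv, width)
    expect_equal(vapply(got, `[[`, integer(1), "a"), want$a)
    expect_equal(vapply(got, `[[`, integer(1), "b"), want$b)
    expect_equal(vapply(got, `[[`, numeric(1), "score"), want$score,
                 tolerance = 1e-8)
  }
})

test_that("layer width is capped by the candidate count and ties are lexicographic", {
  set.seed(24)
  X <- matrix(rnorm(30 * 3), 30, 3)
  Xv <- matrix(rnorm(10 * 3), 10, 3)
  y <- rnorm(30); yv <- rnorm(10)
  layer <- build_layer(X, Xv, y, yv, width = 40)
  expect_length(layer, 3L)  # C(3,2)
  scores <- vapply(layer, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) >= 0))

  # duplicated column => pairs (1,2) and (1,3) give identical candidates
  X2 <- cbind(X[, 1], X[, 2], X[, 2])
  Xv2 <- cbind(Xv[, 1], Xv[, 2], Xv[, 2])
  layer2 <- build_layer(X2, Xv2, y, yv, width = 1)
  tied <- build_layer(X2, Xv2, y, yv, width = 3)
  s <- vapply(tied, `[[`, numeric(1), "score")
  dup <- which(abs(s - s[1]) < 1e-12)
  first <- tied[[1]]
  if (length(dup) > 1) expect_true(first$a == 1 && first$b == 2 ||
                                     first$a < tied[[dup[2]]]$a ||
                                     (first$a == tied[[dup[2]]]$a &&
                                        first$b < tied[[dup[2]]]$b))
  expect_error(build_layer(X[, 1, drop = FALSE], Xv[, 1, drop = FALSE],
                           y, yv, 2), "2 input columns")
})

test_that("a single-neuron network separates two blobs", {
  blobs <- make_blob_data(30, seed = 25)
  cfg <- fit_config(schedule = 1L, seed = 2)
  model <- fit_gmdh(blobs$features, blobs$labels, cfg)
  acc <- mean(predict(model, blobs$features) == blobs$labels)
  expect_gte(acc, 0.9)
  expect_length(model$networks[[1]]$layers, 1L)
  expect_length(model$networks[[1]]$layers[[1]], 1L)
})

test_that("degenerate training inputs are rejected", {
  blobs <- make_blob_data(30, seed = 26)
  expect_error(fit_gmdh(blobs$features, rep(1L, 60), fit_config(schedule = 1L)),
               "single class")
  expect_error(fit_gmdh(blobs$features[1:8, ], blobs$labels[1:8],
                        fit_config(schedule = 1L)), "12 training rows")
  expect_error(fit_gmdh(blobs$features[, 1, drop = FALSE], blobs$labels,
                        fit_config(schedule = 1L)), "2 feature columns")
  expect_error(fit_config(schedule = integer(0)), "schedule")
  expect_error(fit_config(internal_split_fraction = 1), "0, 1")
})

test_that("fitting is deterministic given config and seed", {
  blobs <- make_blob_data(20, seed = 27, p_noise = 3L)
  cfg <- fit_config(schedule = c(4L, 2L), seed = 9)
  m1 <- fit_gmdh(blobs$features, blobs$labels, cfg)
  m2 <- fit_gmdh(blobs$features, blobs$labels, cfg)
  expect_identical(m1, m2)
  expect_identical(predict(m1, blobs$features), predict(m2, blobs$features))
})

test_that("decode rules round half-up and clamp into the code range", {
  blobs <- make_blob_data(20, seed = 28)
  model <- fit_gmdh(blobs$features, blobs$labels, fit_config(schedule = 1L),
                    n_classes = 8L)
  # craft a model whose output neuron is the identity in x1 to probe decoding
  probe <- model
  probe$networks[[1]]$layers <- list(list(list(a = 1L, b = 2L,
                                               coef = c(0, 1, 0, 0, 0, 0),
                                               score = 0)))
  probe$standardizer <- list(center = c(0, 0), scale = c(1, 1))
  probe$n_features <- 2L
  feats <- cbind(c(8.7, 2.4, 2.5, -3, 0.2), 0)
  expect_equal(predict(probe, feats), c(8L, 2L, 3L, 1L, 1L))
})

test_that("structural validation catches inconsistent models", {
  blobs <- make_blob_data(20, seed = 29, p_noise = 2L)
  model <- fit_gmdh(blobs$features, blobs$labels,
                    fit_config(schedule = c(3L, 2L), seed = 1))
  expect_silent(validate_gmdh(model))
  broken <- model
  broken$networks[[1]]$layers[[2]][[1]]$a <- 99L
  expect_error(validate_gmdh(broken), "invalid input indices")
  wide <- model
  wide$schedule <- c(1L, 2L)
  expect_error(validate_gmdh(wide), "schedule cap")
})

test_that("models survive a JSON round trip with identical predictions", {
  blobs <- make_blob_data(20, seed = 30, p_noise = 2L)
  model <- fit_gmdh(blobs$features, blobs$labels,
                    fit_config(schedule = c(3L, 2L), seed = 4),
                    class_labels = c("left", "right"))
  path <- tempfile(fileext = ".json")
  save_gmdh(model, path)
  back <- load_gmdh(path)
  expect_identical(predict(back, blobs$features), predict(model, blobs$features))
  expect_equal(back$class_labels, c("left", "right"))

  doc <- jsonlite::read_json(path)
  expect_true(all(vapply(doc$networks[[1]]$layers[[1]],
                         function(nr) length(nr$coef) == 6L, logical(1))))

  writeLines(substr(paste(readLines(path), collapse = ""), 1, 50),
             path2 <- tempfile(fileext = ".json"))
  expect_error(load_gmdh(path2), "malformed|version")
  expect_error(load_gmdh(tempfile()), "not found")
})

test_that("one-vs-rest encoding trains one network per class and decodes by argmax", {
  set.seed(31)
  n <- 90
  labs <- rep(1:3, each = 30)
  X <- cbind(c(rnorm(30, -3), rnorm(30, 0), rnorm(30, 3)),
             rnorm(n), rnorm(n))
  X[, 2] <- X[, 1]^2 + rnorm(n, sd = 0.3)
  model <- fit_gmdh(X, labs, fit_config(schedule = c(3L, 2L), seed = 6,
                                        encoding_mode = "one_vs_rest"))
  expect_length(model$networks, 3L)
  acc <- mean(predict(model, X) == labs)
  expect_gte(acc, 0.9)
})

test_that("model parameter accounting matches the complexity profiler", {
  blobs <- make_blob_data(25, seed = 32, p_noise = 4L)
  model <- fit_gmdh(blobs$features, blobs$labels,
                    fit_config(schedule = c(5L, 3L, 2L), seed = 8))
  total <- sum(vapply(model$networks[[1]]$layers, length, integer(1)))
  prof <- profile_model(model)
  expect_equal(prof$trainable_parameters, 6L * total)
  expect_equal(prof$total_neurons, total)
})
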
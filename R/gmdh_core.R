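# Local RNG scope: seeds without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# One seed fans out to per-stage seeds by fixed offsets (kept within 32-bit).
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 99991 * as.numeric(stage)) %% 2147483647)
}

#' Decremental layer schedule
#'
#' Per-layer caps on the number of retained neurons. The default is the
#' eight-layer decremental architecture 40, 38, 27, 22, 16, 10, 8, 5: wide
#' early layers explore many feature interactions, shrinking widths distill
#' the salient ones and bound model complexity (166 neurons, 996 coefficients
#' in total).
#'
#' @return integer vector of layer widths.
#' @export
default_schedule <- function() c(40L, 38L, 27L, 22L, 16L, 10L, 8L, 5L)

#' Truncate or extend the default schedule to a target depth
#'
#' Depths up to 8 truncate the default schedule; deeper networks repeat the
#' final width (5) for the extra layers.
#'
#' @param depth number of hidden layers, >= 1.
#' @param schedule base schedule to truncate/extend.
#' @return integer vector of length `depth`.
#' @export
schedule_for_depth <- function(depth, schedule = default_schedule()) {
  depth <- as.integer(depth)
  if (depth < 1L) stop("depth must be >= 1")
  if (depth <= length(schedule)) schedule[seq_len(depth)]
  else c(schedule, rep(schedule[length(schedule)], depth - length(schedule)))
}

#' Training configuration for the GMDH network
#'
#' @param schedule layer-width schedule; see [default_schedule()].
#' @param internal_split_fraction fraction of the training rows held out as
#'   the internal validation set that drives neuron selection (the external
#'   criterion), strictly between 0 and 1.
#' @param max_candidate_pairs optional cap on the number of candidate input
#'   pairs fitted per layer; when the full pair count exceeds it, a seeded
#'   random subsample of pairs is used. `NULL` (default) fits all pairs.
#' @param seed integer seed controlling the internal split and any pair
#'   subsampling.
#' @param encoding_mode `"ordinal"` (default): one network regressing on the
#'   numeric class code, decoded by round-and-clamp. `"one_vs_rest"`: one
#'   network per class on a 0/1 target, decoded by argmax.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(schedule = default_schedule(),
                       internal_split_fraction = 0.25,
                       max_candidate_pairs = NULL,
                       seed = 1L,
                       encoding_mode = c("ordinal", "one_vs_rest")) {
  schedule <- as.integer(schedule)
  if (!length(schedule) || any(schedule < 1L))
    stop("schedule must be a non-empty vector of widths >= 1")
  if (!is.numeric(internal_split_fraction) ||
      internal_split_fraction <= 0 || internal_split_fraction >= 1)
    stop("internal_split_fraction must be in (0, 1)")
  if (!is.null(max_candidate_pairs)) {
    max_candidate_pairs <- as.integer(max_candidate_pairs)
    if (max_candidate_pairs < 1L) stop("max_candidate_pairs must be >= 1")
  }
  structure(list(schedule = schedule,
                 internal_split_fraction = internal_split_fraction,
                 max_candidate_pairs = max_candidate_pairs,
                 seed = as.integer(seed),
                 encoding_mode = match.arg(encoding_mode)),
            class = "fit_config")
}

#' Evaluate one quadratic polynomial neuron
#'
#' Computes `b0 + b1 x1 + b2 x2 + b3 x1^2 + b4 x2^2 + b5 x1 x2`, the
#' two-input second-order (Ivakhnenko) polynomial that every unit in the
#' network realizes.
#'
#' @param neuron a neuron (list with 6-element `coef`); see [fit_neuron()].
#' @param x1,x2 numeric vectors (recycled as usual).
#' @return numeric vector of outputs.
#' @export
neuron_forward <- function(neuron, x1, x2) {
  b <- neuron$coef
  if (length(b) != 6L) stop("a polynomial neuron has exactly 6 coefficients")
  b[1] + b[2] * x1 + b[3] * x2 + b[4] * x1^2 + b[5] * x2^2 + b[6] * x1 * x2
}

quad_design <- function(x1, x2) cbind(1, x1, x2, x1^2, x2^2, x1 * x2)

#' Fit one neuron's coefficients by least squares
#'
#' Ordinary least squares of `target` on the design
#' `[1, x1, x2, x1^2, x2^2, x1*x2]`. Rank-deficient designs fall back to the
#' minimum-norm solution (SVD pseudoinverse), so the fit never fails.
#'
#' @param x1,x2 input columns.
#' @param target response column, same length.
#' @return numeric vector `(b0..b5)`.
#' @export
fit_neuron <- function(x1, x2, target) {
  n <- length(target)
  if (length(x1) != n || length(x2) != n)
    stop("x1, x2 and target must have the same length")
  if (n < 1L) stop("empty training columns")
  D <- quad_design(x1, x2)
  fit <- .lm.fit(D, target)
  if (fit$rank < 6L) {
    s <- svd(D)
    keep <- s$d > max(s$d) * 1e-12
    cf <- s$v[, keep, drop = FALSE] %*%
      ((crossprod(s$u[, keep, drop = FALSE], target)) / s$d[keep])
    return(as.numeric(cf))
  }
  as.numeric(fit$coefficients)
}

#' External criterion of one neuron
#'
#' Mean squared error of the neuron's output against the target on the
#' internal validation rows — the classical GMDH regularity criterion used to
#' rank and retain candidates.
#'
#' @param neuron a fitted neuron.
#' @param x1_val,x2_val,target_val validation columns (non-empty).
#' @return nonnegative scalar.
#' @export
score_neuron <- function(neuron, x1_val, x2_val, target_val) {
  if (!length(target_val)) stop("empty validation set")
  mean((neuron_forward(neuron, x1_val, x2_val) - target_val)^2)
}

candidate_pairs <- function(p, max_candidate_pairs = NULL, seed = NULL) {
  pairs <- utils::combn(p, 2L)
  m <- ncol(pairs)
  if (!is.null(max_candidate_pairs) && m > max_candidate_pairs) {
    idx <- with_seed(seed, sort(sample.int(m, max_candidate_pairs)))
    pairs <- pairs[, idx, drop = FALSE]
  }
  pairs
}

#' Build one hidden layer
#'
#' Fits one candidate neuron per unordered pair of input columns (or a seeded
#' subsample of pairs when their count exceeds `max_candidate_pairs`), scores
#' every candidate on the validation rows, and retains the
#' `min(width, n_candidates)` best by ascending criterion. Ties are broken by
#' the lexicographic order of the input-index pair, and the returned list is
#' sorted by ascending score.
#'
#' @param prev_outputs training matrix (rows x >= 2 columns): standardized
#'   features for layer 1, the previous layer's outputs otherwise.
#' @param prev_outputs_val validation matrix with the same columns.
#' @param target,target_val numeric response on the two row sets.
#' @param width maximum number of neurons to retain.
#' @param max_candidate_pairs optional candidate cap; see [fit_config()].
#' @param seed seed for pair subsampling.
#' @return list of neurons: each a list with `a`, `b` (input column indices,
#'   `a < b`), `coef` (6 values), `score`.
#' @export
build_layer <- function(prev_outputs, prev_outputs_val, target, target_val,
                        width, max_candidate_pairs = NULL, seed = NULL) {
  p <- ncol(prev_outputs)
  if (is.null(p) || p < 2L) stop("need at least 2 input columns to pair")
  pairs <- candidate_pairs(p, max_candidate_pairs, seed)
  m <- ncol(pairs)
  Xsq <- prev_outputs^2
  Vsq <- prev_outputs_val^2
  cand <- vector("list", m)
  scores <- numeric(m)
  for (k in seq_len(m)) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    cf <- fit_neuron_fast(prev_outputs[, i], prev_outputs[, j],
                          Xsq[, i], Xsq[, j], target)
    pred <- cf[1] + cf[2] * prev_outputs_val[, i] + cf[3] * prev_outputs_val[, j] +
      cf[4] * Vsq[, i] + cf[5] * Vsq[, j] +
      cf[6] * prev_outputs_val[, i] * prev_outputs_val[, j]
    scores[k] <- mean((pred - target_val)^2)
    cand[[k]] <- list(a = i, b = j, coef = cf, score = NA_real_)
  }
  ord <- order(scores, pairs[1L, ], pairs[2L, ])
  keep <- ord[seq_len(min(width, m))]
  lapply(keep, function(k) {
    nr <- cand[[k]]; nr$score <- scores[k]; nr
  })
}

# Same contract as fit_neuron but takes precomputed squares (hot loop).
fit_neuron_fast <- function(x1, x2, x1sq, x2sq, target) {
  D <- cbind(1, x1, x2, x1sq, x2sq, x1 * x2)
  fit <- .lm.fit(D, target)
  if (fit$rank < 6L) {
    s <- svd(D)
    keep <- s$d > max(s$d) * 1e-12
    return(as.numeric(s$v[, keep, drop = FALSE] %*%
      ((crossprod(s$u[, keep, drop = FALSE], target)) / s$d[keep])))
  }
  as.numeric(fit$coefficients)
}

layer_forward <- function(layer, X) {
  out <- matrix(0, nrow(X), length(layer))
  for (j in seq_along(layer)) {
    nr <- layer[[j]]
    out[, j] <- neuron_forward(nr, X[, nr$a], X[, nr$b])
  }
  out
}

gmdh_layers_forward <- function(layers, Xstd) {
  cur <- Xstd
  for (layer in layers) cur <- layer_forward(layer, cur)
  cur
}

build_network <- function(Xfit, Xval, tfit, tval, schedule,
                          max_candidate_pairs, seed) {
  layers <- vector("list", length(schedule))
  realized <- 0L
  cur_fit <- Xfit
  cur_val <- Xval
  for (l in seq_along(schedule)) {
    if (ncol(cur_fit) < 2L) {
      message("stopping at depth ", realized,
              ": previous layer left fewer than 2 outputs to pair")
      break
    }
    layer <- build_layer(cur_fit, cur_val, tfit, tval, schedule[l],
                         max_candidate_pairs, derive_seed(seed, l))
    layers[[l]] <- layer
    realized <- l
    cur_fit <- layer_forward(layer, cur_fit)
    cur_val <- layer_forward(layer, cur_val)
  }
  layers <- layers[seq_len(realized)]
  # layers are score-sorted, so the best final-layer neuron sits first; it is
  # selected as the single output, not refitted.
  list(layers = layers, output_selector = 1L,
       selection_scores = lapply(layers, function(ly)
         vapply(ly, function(nr) nr$score, numeric(1))))
}

#' Fit the self-organizing GMDH network
#'
#' Training proceeds in the classical inductive fashion: (1) features are
#' z-scored with location/scale estimated from the training rows only;
#' (2) the training rows are split by a seeded shuffle into a fit part and an
#' internal validation part (the external criterion set); (3) class labels
#' are encoded per `encoding_mode`; (4) hidden layers are grown one at a
#' time — every unordered pair of the previous layer's outputs (layer 1: the
#' standardized features) proposes one quadratic neuron fitted by least
#' squares on the fit rows, and each layer retains the schedule's width of
#' candidates with the lowest validation MSE; (5) the best neuron of the last
#' layer is selected as the single output. Layer `l` consumes only layer
#' `l - 1` outputs (no passthrough of raw features).
#'
#' @param features numeric matrix, rows = trials (>= 12), columns = features
#'   (>= 2).
#' @param labels integer class codes `1..K`, one per row; at least 2 distinct
#'   classes.
#' @param config a [fit_config()].
#' @param n_classes total number of classes `K`; defaults to `max(labels)`.
#' @param class_labels optional character vector of length `n_classes` mapping
#'   codes back to task names; stored with the model.
#' @return An object of class `gmdh_model`.
#' @export
fit_gmdh <- function(features, labels, config = fit_config(),
                     n_classes = max(labels), class_labels = NULL) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  n <- nrow(features)
  if (n < 12L) stop("need at least 12 training rows")
  if (ncol(features) < 2L) stop("need at least 2 feature columns")
  if (length(labels) != n) stop("one label per feature row required")
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class")
  K <- as.integer(n_classes)
  if (any(labels < 1L | labels > K)) stop("labels must be codes in 1..", K)
  stopifnot(inherits(config, "fit_config"))

  center <- colMeans(features)
  scale <- apply(features, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Xstd <- sweep(sweep(features, 2L, center), 2L, scale, "/")

  n_val <- max(1L, round(config$internal_split_fraction * n))
  if (n_val >= n) n_val <- n - 1L
  perm <- with_seed(derive_seed(config$seed, 0L), sample.int(n))
  val_idx <- sort(perm[seq_len(n_val)])
  fit_idx <- sort(perm[-seq_len(n_val)])

  Xfit <- Xstd[fit_idx, , drop = FALSE]
  Xval <- Xstd[val_idx, , drop = FALSE]

  if (config$encoding_mode == "ordinal") {
    tfit <- as.numeric(labels[fit_idx])
    tval <- as.numeric(labels[val_idx])
    net <- build_network(Xfit, Xval, tfit, tval, config$schedule,
                         config$max_candidate_pairs, config$seed)
    networks <- list(net)
  } else {
    networks <- lapply(seq_len(K), function(k) {
      build_network(Xfit, Xval,
                    as.numeric(labels[fit_idx] == k),
                    as.numeric(labels[val_idx] == k),
                    config$schedule, config$max_candidate_pairs,
                    derive_seed(config$seed, 1000L + k))
    })
  }

  if (!is.null(class_labels) && length(class_labels) != K)
    stop("class_labels must have length n_classes")
  model <- structure(list(version = "1",
                          encoding_mode = config$encoding_mode,
                          n_classes = K,
                          class_labels = class_labels,
                          n_features = ncol(features),
                          feature_names = colnames(features),
                          schedule = config$schedule,
                          standardizer = list(center = as.numeric(center),
                                              scale = as.numeric(scale)),
                          networks = networks),
                     class = "gmdh_model")
  validate_gmdh(model)
  model
}

#' Structural validation of a fitted model
#'
#' Checks that every layer respects its schedule cap, that every neuron has
#' six coefficients and valid input indices for the preceding layer's width,
#' and that the output selector indexes into the last layer.
#'
#' @param model a `gmdh_model`.
#' @return `model`, invisibly; errors on violation.
#' @export
validate_gmdh <- function(model) {
  stopifnot(inherits(model, "gmdh_model"))
  for (net in model$networks) {
    prev_width <- model$n_features
    for (l in seq_along(net$layers)) {
      layer <- net$layers[[l]]
      if (length(layer) < 1L || length(layer) > model$schedule[l])
        stop("layer ", l, " width ", length(layer),
             " violates schedule cap ", model$schedule[l])
      for (nr in layer) {
        if (length(nr$coef) != 6L) stop("neuron without 6 coefficients in layer ", l)
        if (nr$a == nr$b || nr$a < 1L || nr$b < 1L ||
            nr$a > prev_width || nr$b > prev_width)
          stop("invalid input indices (", nr$a, ",", nr$b,
               ") for layer ", l, " of width ", prev_width)
      }
      prev_width <- length(layer)
    }
    if (net$output_selector < 1L ||
        net$output_selector > length(net$layers[[length(net$layers)]]))
      stop("output selector out of range for the last layer")
  }
  invisible(model)
}

#' @export
print.gmdh_model <- function(x, ...) {
  w <- vapply(x$networks[[1]]$layers, length, integer(1))
  cat(sprintf("<gmdh_model> %s encoding, %d classes, %d features\n",
              x$encoding_mode, x$n_classes, x$n_features))
  cat("  realized layer widths:", paste(w, collapse = "-"), "\n")
  if (length(x$networks) > 1L)
    cat("  networks:", length(x$networks), "(one per class)\n")
  invisible(x)
}

model_raw_output <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stop("feature width ", ncol(features), " does not match training width ",
         model$n_features)
  Xstd <- sweep(sweep(features, 2L, model$standardizer$center), 2L,
                model$standardizer$scale, "/")
  vapply(model$networks, function(net) {
    gmdh_layers_forward(net$layers, Xstd)[, net$output_selector]
  }, numeric(nrow(features)))
}

#' Predict class codes
#'
#' Forward pass through the stored layers using the training-time
#' standardizer. Ordinal models decode the single continuous output by
#' rounding half-up to the nearest integer and clamping to `[1, K]`;
#' one-vs-rest models take the argmax over the per-class networks (ties to
#' the lowest code). Deterministic. Non-finite outputs — possible when a
#' badly overfit deep network overflows double precision — decode to the
#' nearest clamp boundary (`+Inf` to `K`, `-Inf` to 1) and `NaN` to class 1,
#' so prediction is total.
#'
#' @param object a `gmdh_model`.
#' @param features numeric matrix with the training feature width.
#' @param ... unused.
#' @return integer vector of class codes.
#' @export
predict.gmdh_model <- function(object, features, ...) {
  out <- model_raw_output(object, features)
  if (object$encoding_mode == "ordinal") {
    code <- floor(out[, 1L] + 0.5)
    code[is.nan(code)] <- 1
    as.integer(pmin(pmax(code, 1), object$n_classes))
  } else {
    out[!is.finite(out)] <- -Inf
    as.integer(apply(out, 1L, function(r)
      if (all(r == -Inf)) 1L else which.max(r)))
  }
}

# -- serialization ------------------------------------------------------------

#' Save / load a fitted model as JSON
#'
#' The document stores the schedule, every neuron's input indices,
#' coefficients and selection score, the standardizer, the label encoding and
#' a format version. Numbers are written at full precision, so
#' `load_gmdh(save_gmdh(m, p))` predicts identically to `m`.
#'
#' @param model a `gmdh_model`.
#' @param path JSON file path.
#' @return `path` invisibly (`save_gmdh`); a `gmdh_model` (`load_gmdh`).
#' @export
save_gmdh <- function(model, path) {
  validate_gmdh(model)
  doc <- list(version = model$version,
              encoding_mode = model$encoding_mode,
              n_classes = model$n_classes,
              class_labels = model$class_labels,
              n_features = model$n_features,
              feature_names = model$feature_names,
              schedule = model$schedule,
              standardizer = model$standardizer,
              networks = lapply(model$networks, function(net) {
                list(output_selector = net$output_selector,
                     layers = lapply(net$layers, function(layer)
                       lapply(layer, function(nr)
                         list(a = nr$a, b = nr$b, coef = nr$coef,
                              score = nr$score))))
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_gmdh
#' @export
load_gmdh <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed model file: ",
                                           conditionMessage(e)))
  if (is.null(doc$version)) stop("model file has no version field")
  if (!identical(as.character(doc$version), "1"))
    stop("unsupported model format version: ", doc$version)
  networks <- lapply(doc$networks, function(net) {
    list(output_selector = as.integer(net$output_selector),
         layers = lapply(net$layers, function(layer)
           lapply(layer, function(nr) {
             cf <- as.numeric(unlist(nr$coef))
             if (length(cf) != 6L) stop("neuron without 6 coefficients in model file")
             list(a = as.integer(nr$a), b = as.integer(nr$b),
                  coef = cf, score = as.numeric(nr$score))
           })))
  })
  model <- structure(list(version = "1",
                          encoding_mode = doc$encoding_mode,
                          n_classes = as.integer(doc$n_classes),
                          class_labels = if (is.null(doc$class_labels)) NULL
                                         else as.character(unlist(doc$class_labels)),
                          n_features = as.integer(doc$n_features),
                          feature_names = if (is.null(doc$feature_names)) NULL
                                          else as.character(unlist(doc$feature_names)),
                          schedule = as.integer(unlist(doc$schedule)),
                          standardizer = list(
                            center = as.numeric(unlist(doc$standardizer$center)),
                            scale = as.numeric(unlist(doc$standardizer$scale))),
                          networks = networks),
                     class = "gmdh_model")
  validate_gmdh(model)
  model
}
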
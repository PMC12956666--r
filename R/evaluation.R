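#' Confusion matrix
#'
#' @param y_true,y_pred integer class codes in `1..K`, equal length.
#' @param K number of classes.
#' @param class_names optional row/column names (vocabulary order).
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, K, class_names = NULL) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) && (any(y_true < 1L | y_true > K) ||
                         any(y_pred < 1L | y_pred > K)))
    stop("class codes must lie in 1..", K)
  cm <- matrix(0L, K, K)
  for (n in seq_along(y_true))
    cm[y_true[n], y_pred[n]] <- cm[y_true[n], y_pred[n]] + 1L
  if (!is.null(class_names)) dimnames(cm) <- list(true = class_names,
                                                  predicted = class_names)
  cm
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)`, with expected
#' agreement `p_e` computed from the row and column marginals.
#'
#' @param cm square count matrix (rows = true, columns = predicted).
#' @return kappa in `[-1, 1]`; errors when `p_e = 1` (all mass concentrated
#'   in a single row and column), where kappa is undefined.
#' @export
#' @examples
#' cohen_kappa(matrix(c(20, 10, 5, 15), 2))  # 0.4
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (1 - pe < .Machine$double.eps)
    stop("kappa undefined: expected agreement equals 1")
  (po - pe) / (1 - pe)
}

#' Per-class precision/recall/F1 with macro and weighted aggregates
#'
#' `precision_k = cm[k,k] / colsum_k`, `recall_k = cm[k,k] / rowsum_k`, F1 is
#' their harmonic mean. Any metric whose denominator is zero is set to 0 (not
#' NaN) so the aggregates stay defined on degenerate predictions. Macro
#' aggregates are unweighted class means; weighted aggregates are
#' support-weighted (hence weighted recall equals accuracy).
#'
#' @param cm square count matrix.
#' @return list with `per_class` (data.frame: class, precision, recall, f1,
#'   support) and scalars `macro_precision`, `macro_recall`, `macro_f1`,
#'   `weighted_precision`, `weighted_recall`, `weighted_f1`.
#' @export
per_class_prf <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  K <- nrow(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  tp <- diag(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  w <- support / total
  list(per_class = data.frame(class = if (!is.null(rownames(cm))) rownames(cm)
                                       else as.character(seq_len(K)),
                              precision = as.numeric(precision),
                              recall = as.numeric(recall),
                              f1 = as.numeric(f1),
                              support = as.integer(support),
                              stringsAsFactors = FALSE),
       macro_precision = mean(precision),
       macro_recall = mean(recall),
       macro_f1 = mean(f1),
       weighted_precision = sum(w * precision),
       weighted_recall = sum(w * recall),
       weighted_f1 = sum(w * f1))
}

#' Full multiclass evaluation report
#'
#' @param y_true,y_pred integer class codes.
#' @param K class count.
#' @param class_names optional class names.
#' @return An object of class `evaluation_report`: confusion matrix, accuracy,
#'   Cohen's kappa, per-class precision/recall/F1/support, and macro/weighted
#'   aggregates.
#' @export
evaluation_report <- function(y_true, y_pred, K, class_names = NULL) {
  cm <- confusion_matrix(y_true, y_pred, K, class_names)
  prf <- per_class_prf(cm)
  kappa <- tryCatch(cohen_kappa(cm), error = function(e) NA_real_)
  structure(c(list(confusion = cm,
                   accuracy = sum(diag(cm)) / sum(cm),
                   kappa = kappa),
              prf),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  accuracy: %.2f%%   Cohen's kappa: %s\n",
              100 * x$accuracy, format(round(x$kappa, digits))))
  cat(sprintf("  macro  P/R/F1: %.4f / %.4f / %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  cat(sprintf("  weighted F1  : %.4f\n", x$weighted_f1))
  cat("  per class:\n")
  pc <- x$per_class
  pc[c("precision", "recall", "f1")] <-
    lapply(pc[c("precision", "recall", "f1")], round, digits)
  print(pc, row.names = FALSE)
  invisible(x)
}

# Plain-list view used for JSON reports.
report_as_list <- function(report) {
  list(accuracy = report$accuracy,
       kappa = report$kappa,
       macro_precision = report$macro_precision,
       macro_recall = report$macro_recall,
       macro_f1 = report$macro_f1,
       weighted_precision = report$weighted_precision,
       weighted_recall = report$weighted_recall,
       weighted_f1 = report$weighted_f1,
       per_class = report$per_class,
       confusion = unname(apply(report$confusion, 1L, as.integer,
                                simplify = FALSE)))
}

#' Train/test split
#'
#' Seeded random partition of `1..n` into train and test index sets. With
#' `stratify = TRUE` (default) the split is drawn within each class so class
#' proportions carry over to rounding; the unstratified variant draws one
#' simple random sample. 480 balanced rows at `test_fraction = 0.30` give the
#' canonical 336/144 partition either way.
#'
#' @param labels integer class codes (length n).
#' @param test_fraction fraction of rows assigned to the test set, in (0, 1).
#' @param seed integer seed.
#' @param stratify draw the split within classes?
#' @return list with sorted integer vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
train_test_split <- function(labels, test_fraction = 0.30, seed = 1L,
                             stratify = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  labels <- as.integer(labels)
  n <- length(labels)
  if (stratify) {
    counts <- table(labels)
    if (any(counts < 2L)) stop("stratified split needs >= 2 rows per class")
    test <- with_seed(seed, {
      unlist(lapply(sort(unique(labels)), function(k) {
        idx <- which(labels == k)
        sample(idx, round(test_fraction * length(idx)))
      }), use.names = FALSE)
    })
  } else {
    test <- with_seed(seed, sample.int(n, round(test_fraction * n)))
  }
  test <- sort(test)
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Stratified k-fold indices
#'
#' @param labels integer class codes.
#' @param k fold count; every class support must be >= k.
#' @param seed integer seed.
#' @return list of `k` sorted test-index vectors: pairwise disjoint, jointly
#'   exhaustive, class-balanced to rounding.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  counts <- table(labels)
  if (any(counts < k))
    stop("every class needs support >= k = ", k, " for stratified folding")
  assignment <- integer(length(labels))
  with_seed(seed, {
    for (cls in sort(unique(labels))) {
      idx <- sample(which(labels == cls))
      assignment[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) sort(which(assignment == f)))
}

#' Stratified k-fold cross-validation of the GMDH pipeline
#'
#' One model fit per fold; every sample is tested exactly once. Feature
#' standardization is refitted inside each fold (it is part of [fit_gmdh()]),
#' so no information leaks from the held-out fold.
#'
#' @param features trials x features matrix.
#' @param labels integer class codes.
#' @param config a [fit_config()].
#' @param k fold count (default 5).
#' @param seed seed for the folding.
#' @return list with `fold_accuracy` (length k), `mean_accuracy`,
#'   `sd_accuracy`, and `folds` (the test-index sets).
#' @export
cross_validate <- function(features, labels, config = fit_config(), k = 5L,
                           seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  K <- max(labels)
  folds <- stratified_folds(labels, k, seed)
  acc <- vapply(seq_len(k), function(f) {
    test <- folds[[f]]
    train <- setdiff(seq_len(length(labels)), test)
    model <- fit_gmdh(features[train, , drop = FALSE], labels[train],
                      config, n_classes = K)
    mean(predict(model, features[test, , drop = FALSE]) == labels[test])
  }, numeric(1))
  list(fold_accuracy = acc, mean_accuracy = mean(acc),
       sd_accuracy = stats::sd(acc), folds = folds)
}

#' Depth ablation
#'
#' Fits one network per requested depth on a fixed stratified train split and
#' reports held-out accuracy. Depths up to 8 truncate the default decremental
#' schedule; deeper networks repeat the final width (5) for the extra layers
#' (see [schedule_for_depth()]).
#'
#' @param features trials x features matrix.
#' @param labels integer class codes.
#' @param depths integer vector of hidden-layer counts (non-empty).
#' @param config base [fit_config()] whose schedule is replaced per depth.
#' @param test_fraction,seed split parameters shared by all depths.
#' @return data.frame with columns `depth` and `accuracy`.
#' @export
depth_ablation <- function(features, labels, depths = 1:12,
                           config = fit_config(), test_fraction = 0.30,
                           seed = 1L) {
  if (!length(depths)) stop("empty depth list")
  features <- as.matrix(features)
  labels <- as.integer(labels)
  K <- max(labels)
  split <- train_test_split(labels, test_fraction, seed)
  acc <- vapply(as.integer(depths), function(d) {
    cfg <- config
    cfg$schedule <- schedule_for_depth(d, default_schedule())
    model <- fit_gmdh(features[split$train, , drop = FALSE],
                      labels[split$train], cfg, n_classes = K)
    mean(predict(model, features[split$test, , drop = FALSE]) ==
           labels[split$test])
  }, numeric(1))
  data.frame(depth = as.integer(depths), accuracy = acc)
}

#' Feature-subset ablation
#'
#' Masks the feature columns to one group — `"frequency"` (band powers +
#' dominant frequency), `"time"` (mean, standard deviation, median,
#' peak-to-peak amplitude) or `"all"` — then fits and evaluates on a fixed
#' stratified train split shared across groups.
#'
#' @param features trials x features matrix laid out by [extract_features()].
#' @param labels integer class codes.
#' @param groups character vector of group names.
#' @param config a [fit_config()].
#' @param n_channels,bands layout parameters of the feature matrix.
#' @param test_fraction,seed split parameters shared by all groups.
#' @return data.frame with columns `group`, `n_columns`, `accuracy`.
#' @export
feature_subset_ablation <- function(features, labels,
                                    groups = c("frequency", "time", "all"),
                                    config = fit_config(), n_channels = 16,
                                    bands = default_bands(),
                                    test_fraction = 0.30, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.integer(labels)
  K <- max(labels)
  split <- train_test_split(labels, test_fraction, seed)
  res <- lapply(groups, function(g) {
    cols <- feature_group_columns(g, n_channels, bands)
    if (max(cols) > ncol(features))
      stop("group layout exceeds feature matrix width; check n_channels/bands")
    sub <- features[, cols, drop = FALSE]
    model <- fit_gmdh(sub[split$train, , drop = FALSE], labels[split$train],
                      config, n_classes = K)
    acc <- mean(predict(model, sub[split$test, , drop = FALSE]) ==
                  labels[split$test])
    data.frame(group = g, n_columns = length(cols), accuracy = acc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
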
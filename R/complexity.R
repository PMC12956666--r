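#' Neuron count of a layer schedule
#'
#' @param schedule integer vector of layer widths (possibly empty).
#' @return total number of neurons (sum of widths).
#' @export
#' @examples
#' count_neurons(default_schedule())  # 166
count_neurons <- function(schedule) {
  if (!length(schedule)) return(0L)
  schedule <- as.integer(schedule)
  if (any(schedule < 1L)) stop("layer widths must be >= 1")
  sum(schedule)
}

#' Trainable parameter count of a layer schedule
#'
#' Every neuron is a two-input quadratic polynomial with six coefficients, so
#' the count is `6 * count_neurons(schedule)`; the default eight-layer
#' schedule has 996 trainable parameters.
#'
#' @inheritParams count_neurons
#' @return parameter count.
#' @export
count_parameters <- function(schedule) 6L * count_neurons(schedule)

#' Arithmetic operations per forward pass
#'
#' A quadratic neuron `b0 + b1 x1 + b2 x2 + b3 x1^2 + b4 x2^2 + b5 x1 x2`
#' costs 8 multiplications (x1^2, x2^2, x1*x2 and the five coefficient
#' products) and 5 additions, so per-sample cost is `(8, 5)` times the neuron
#' count. Feature standardization and the round/clamp decode are excluded:
#' the accounting covers the polynomial network only.
#'
#' @inheritParams count_neurons
#' @return list with `multiplications`, `additions`, `total`.
#' @export
#' @examples
#' count_operations(default_schedule())  # 1328 mult, 830 add, 2158 total
count_operations <- function(schedule) {
  n <- count_neurons(schedule)
  list(multiplications = 8L * n, additions = 5L * n, total = 13L * n)
}

#' Complexity profile of a fitted model
#'
#' Counts are computed from the realized layer widths of the fitted network
#' (which can fall below the nominal schedule on tiny inputs), and are
#' invariant to coefficient values. The selected output neuron is a member of
#' the last layer and is not counted separately. One-vs-rest models sum over
#' the per-class networks.
#'
#' @param model a `gmdh_model`.
#' @return An object of class `complexity_report`: list with `total_neurons`,
#'   `trainable_parameters`, `multiplications`, `additions`,
#'   `total_operations`, and `realized_schedule`.
#' @export
profile_model <- function(model) {
  stopifnot(inherits(model, "gmdh_model"))
  widths <- unlist(lapply(model$networks, function(net)
    vapply(net$layers, length, integer(1))))
  n <- count_neurons(widths)
  ops <- count_operations(widths)
  structure(list(total_neurons = n,
                 trainable_parameters = count_parameters(widths),
                 multiplications = ops$multiplications,
                 additions = ops$additions,
                 total_operations = ops$total,
                 realized_schedule = as.integer(
                   vapply(model$networks[[1]]$layers, length, integer(1)))),
            class = "complexity_report")
}

#' Complexity profile of a bare schedule
#'
#' @inheritParams count_neurons
#' @return A `complexity_report` (see [profile_model()]).
#' @export
profile_schedule <- function(schedule) {
  n <- count_neurons(schedule)
  ops <- count_operations(schedule)
  structure(list(total_neurons = n,
                 trainable_parameters = count_parameters(schedule),
                 multiplications = ops$multiplications,
                 additions = ops$additions,
                 total_operations = ops$total,
                 realized_schedule = as.integer(schedule)),
            class = "complexity_report")
}

#' @export
print.complexity_report <- function(x, ...) {
  cat("<complexity_report>\n")
  cat("  layer widths        :", paste(x$realized_schedule, collapse = "-"), "\n")
  cat("  neurons             :", x$total_neurons, "\n")
  cat("  trainable parameters:", x$trainable_parameters, "\n")
  cat(sprintf("  ops per sample      : %d mult + %d add = %d\n",
              x$multiplications, x$additions, x$total_operations))
  invisible(x)
}
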
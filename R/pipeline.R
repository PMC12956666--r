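#' Default run configuration
#'
#' Nested configuration binding all pipeline stages, with the package defaults
#' for every key. A single top-level `seed` fans out to per-stage seeds by
#' fixed offsets, so one knob controls generation, splitting, fitting and
#' folding with no hidden coupling between stages.
#'
#' Sections and keys:
#' * `seed` — integer master seed.
#' * `generator` — `enabled`, `n_subjects`, `fs`, `duration`, `n_channels`,
#'   `noise_sd`, `subject_amp_sd`, `apply_bandpass`.
#' * `features` — `bands`: `"default"` (five canonical bands),
#'   `"mu_beta"`, or a list of `(name, f_low, f_high)` triples.
#' * `model` — `schedule`, `internal_split_fraction`, `max_candidate_pairs`,
#'   `encoding_mode`.
#' * `evaluation` — `test_fraction`, `stratify`, `k`.
#' * `io` — `input_dir` (manifest directory; used when the generator is
#'   disabled), `out_dir`.
#'
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    seed = 1L,
    generator = list(enabled = TRUE, n_subjects = 60L, fs = 125,
                     duration = 4, n_channels = 16L, noise_sd = 2.5,
                     subject_amp_sd = 0.1, apply_bandpass = TRUE),
    features = list(bands = "default"),
    model = list(schedule = default_schedule(),
                 internal_split_fraction = 0.25,
                 max_candidate_pairs = NULL,
                 encoding_mode = "ordinal"),
    evaluation = list(test_fraction = 0.30, stratify = TRUE, k = 5L),
    io = list(input_dir = NULL, out_dir = "gmdheeg_run")
  ), class = "run_config")
}

# Recursive merge of user keys over defaults; unknown keys are an error.
merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(ifelse(nzchar(path), paste0(path, "."), ""), unknown,
                collapse = ", "))
  for (key in names(user)) {
    full <- if (nzchar(path)) paste(path, key, sep = ".") else key
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load a run configuration from YAML
#'
#' Keys absent from the file keep their defaults; keys not in
#' [default_run_config()] are rejected.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a `run_config`.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  structure(merge_config(unclass(cfg), user), class = "run_config")
}

resolve_bands <- function(bands_cfg) {
  if (is.character(bands_cfg) && length(bands_cfg) == 1L) {
    return(switch(bands_cfg,
                  default = default_bands(),
                  mu_beta = mu_beta_bands(),
                  stop("unknown band set: ", bands_cfg)))
  }
  if (is.list(bands_cfg))
    return(lapply(bands_cfg, function(b)
      band_definition(b$name, b$f_low, b$f_high)))
  stop("features.bands must be 'default', 'mu_beta', or a list of triples")
}

config_to_fit_config <- function(config, seed) {
  fit_config(schedule = config$model$schedule,
             internal_split_fraction = config$model$internal_split_fraction,
             max_candidate_pairs = config$model$max_candidate_pairs,
             seed = seed,
             encoding_mode = config$model$encoding_mode)
}

config_to_generator <- function(config) {
  g <- config$generator
  generator_config(n_subjects = g$n_subjects, fs = g$fs,
                   duration = g$duration, n_channels = g$n_channels,
                   noise_sd = g$noise_sd, subject_amp_sd = g$subject_amp_sd,
                   apply_bandpass = g$apply_bandpass,
                   seed = derive_seed(config$seed, 11L))
}

write_confusion_csv <- function(cm, path) {
  df <- as.data.frame.matrix(cm)
  df <- cbind(true = rownames(cm), df)
  utils::write.csv(df, path, row.names = FALSE)
}

#' Run the full decoding pipeline
#'
#' Executes generate (or load) -> extract features -> stratified 70/30 split
#' -> fit GMDH -> predict -> evaluate, writing every artifact under the run
#' directory: `resolved_config.yaml`, `features.csv`, `model.json`,
#' `report.json` (train + test metrics), `report.txt`,
#' `confusion_train.csv`, `confusion_test.csv`. Re-running with the same
#' config reproduces all numeric outputs byte-for-byte.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [load_run_config()]).
#' @param out_dir run directory; defaults to `config$io$out_dir`.
#' @param quiet suppress progress messages?
#' @return invisibly, a list with `report_train`, `report_test`, `model`,
#'   `split`, and `out_dir`.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = config$io$out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message("[gmdheeg] ", ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config$io$out_dir <- out_dir
  yaml::write_yaml(unclass(config), file.path(out_dir, "resolved_config.yaml"))
  say("seed = ", config$seed, "; resolved config written")

  if (isTRUE(config$generator$enabled)) {
    say("generating synthetic dataset")
    dataset <- generate_dataset(config_to_generator(config))
  } else {
    if (is.null(config$io$input_dir))
      stop("generator disabled and io.input_dir not set")
    manifest <- file.path(config$io$input_dir, "manifest.csv")
    say("loading dataset from ", manifest)
    dataset <- read_manifest(manifest)
  }

  bands <- resolve_bands(config$features$bands)
  say("extracting ", length(bands) + 5L, " features x ",
      ncol(dataset$trials[[1]]$samples), " channels from ",
      length(dataset$trials), " trials")
  fm <- extract_feature_matrix(dataset, bands)
  write_feature_table(fm$features, fm$label_names,
                      file.path(out_dir, "features.csv"))

  split <- train_test_split(fm$labels, config$evaluation$test_fraction,
                            seed = derive_seed(config$seed, 12L),
                            stratify = config$evaluation$stratify)
  say("split: ", length(split$train), " train / ", length(split$test), " test")

  fit_cfg <- config_to_fit_config(config, derive_seed(config$seed, 13L))
  model <- fit_gmdh(fm$features[split$train, , drop = FALSE],
                    fm$labels[split$train], fit_cfg,
                    n_classes = length(fm$vocabulary),
                    class_labels = unclass(fm$vocabulary))
  save_gmdh(model, file.path(out_dir, "model.json"))
  say("fitted model: realized widths ",
      paste(vapply(model$networks[[1]]$layers, length, integer(1)),
            collapse = "-"))

  K <- length(fm$vocabulary)
  pred_train <- predict(model, fm$features[split$train, , drop = FALSE])
  pred_test <- predict(model, fm$features[split$test, , drop = FALSE])
  rep_train <- evaluation_report(fm$labels[split$train], pred_train, K,
                                 unclass(fm$vocabulary))
  rep_test <- evaluation_report(fm$labels[split$test], pred_test, K,
                                unclass(fm$vocabulary))
  say(sprintf("train accuracy %.2f%%, test accuracy %.2f%%",
              100 * rep_train$accuracy, 100 * rep_test$accuracy))

  jsonlite::write_json(list(train = report_as_list(rep_train),
                            test = report_as_list(rep_test)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(utils::capture.output(print(rep_train)),
           "", utils::capture.output(print(rep_test)))
  writeLines(txt, file.path(out_dir, "report.txt"))
  write_confusion_csv(rep_train$confusion,
                      file.path(out_dir, "confusion_train.csv"))
  write_confusion_csv(rep_test$confusion,
                      file.path(out_dir, "confusion_test.csv"))

  invisible(list(report_train = rep_train, report_test = rep_test,
                 model = model, split = split, out_dir = out_dir))
}
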
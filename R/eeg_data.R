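#' Motor-task vocabulary
#'
#' Ordered set of task class labels with contiguous 1-based integer codes.
#' The default is the eight-task executed-movement vocabulary used throughout
#' the package: baseline with eyes open (BEO), closing of the left/right hand
#' (CLH, CRH), dorsal and plantar flexion of the left and right foot
#' (DLF, PLF, DRF, PRF), and inter-task rest (Rest).
#'
#' @param labels character vector of unique class labels, in code order.
#' @return An object of class `task_vocabulary`: a character vector whose
#'   positions are the integer class codes.
#' @export
#' @examples
#' vocab <- task_vocabulary()
#' vocab_code(vocab, "CLH")   # 2
#' vocab_label(vocab, 8)      # "Rest"
task_vocabulary <- function(labels = c("BEO", "CLH", "CRH", "DLF",
                                       "PLF", "DRF", "PRF", "Rest")) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("vocabulary must contain at least one label")
  if (anyDuplicated(labels)) stop("vocabulary labels must be unique")
  structure(labels, class = "task_vocabulary")
}

#' @rdname task_vocabulary
#' @param vocabulary a `task_vocabulary`.
#' @param label class label(s) to encode.
#' @export
vocab_code <- function(vocabulary, label) {
  code <- match(as.character(label), unclass(vocabulary))
  if (anyNA(code)) {
    bad <- unique(as.character(label)[is.na(code)])
    stop("unknown task label(s): ", paste(bad, collapse = ", "))
  }
  code
}

#' @rdname task_vocabulary
#' @param code integer class code(s) to decode.
#' @export
vocab_label <- function(vocabulary, code) {
  code <- as.integer(code)
  if (any(code < 1L | code > length(vocabulary)))
    stop("class code out of range 1..", length(vocabulary))
  unclass(vocabulary)[code]
}

#' Single epoched EEG trial
#'
#' One epoched multichannel recording with its task label: the unit of
#' classification. Samples are stored rows = time points, columns = channels.
#'
#' @param samples numeric matrix, time points x channels.
#' @param sampling_rate sampling frequency in Hz (> 0), default 125.
#' @param channel_names optional character vector of electrode labels; default
#'   `"ch1".."chC"`.
#' @param label task class label (string) or NA.
#' @param subject_id opaque subject identifier.
#' @return An object of class `eeg_trial`.
#' @export
eeg_trial <- function(samples, sampling_rate = 125, channel_names = NULL,
                      label = NA_character_, subject_id = NA_character_) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (nrow(samples) < 2L) stop("a trial needs at least 2 time points")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) stop("sampling_rate must be a positive scalar (Hz)")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(ncol(samples)))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != ncol(samples))
    stop("channel_names length (", length(channel_names),
         ") does not match channel count (", ncol(samples), ")")
  colnames(samples) <- channel_names
  structure(list(samples = samples,
                 sampling_rate = as.numeric(sampling_rate),
                 channel_names = channel_names,
                 label = as.character(label),
                 subject_id = as.character(subject_id)),
            class = "eeg_trial")
}

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial> %d time points x %d channels @ %g Hz, label=%s, subject=%s\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              x$label, x$subject_id))
  invisible(x)
}

#' Collection of EEG trials sharing one recording geometry
#'
#' @param trials list of [eeg_trial()] objects; all must share sampling rate
#'   and channel count, and every label must be in `vocabulary`.
#' @param vocabulary a [task_vocabulary()].
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(trials, vocabulary = task_vocabulary()) {
  if (!length(trials)) stop("dataset must contain at least one trial")
  if (!all(vapply(trials, inherits, logical(1), "eeg_trial")))
    stop("all elements must be eeg_trial objects")
  fs <- unique(vapply(trials, function(t) t$sampling_rate, numeric(1)))
  if (length(fs) != 1L)
    stop("inconsistent sampling rates across trials: ",
         paste(fs, collapse = ", "))
  nch <- unique(vapply(trials, function(t) ncol(t$samples), integer(1)))
  if (length(nch) != 1L)
    stop("inconsistent channel counts across trials: ",
         paste(nch, collapse = ", "))
  vocab_code(vocabulary, vapply(trials, function(t) t$label, character(1)))
  structure(list(trials = trials, vocabulary = vocabulary),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %d trials, %d channels @ %g Hz, %d classes\n",
              length(x$trials), ncol(x$trials[[1]]$samples),
              x$trials[[1]]$sampling_rate, length(x$vocabulary)))
  print(class_support(x))
  invisible(x)
}

#' Per-class trial counts of a dataset
#'
#' @param dataset a `trial_dataset`.
#' @return named integer vector of supports, in vocabulary order.
#' @export
class_support <- function(dataset) {
  labs <- vapply(dataset$trials, function(t) t$label, character(1))
  counts <- table(factor(labs, levels = unclass(dataset$vocabulary)))
  stats::setNames(as.integer(counts), names(counts))
}

#' Dataset labels as integer codes
#'
#' @param dataset a `trial_dataset`.
#' @return integer vector of 1-based class codes, one per trial.
#' @export
dataset_labels <- function(dataset) {
  vocab_code(dataset$vocabulary,
             vapply(dataset$trials, function(t) t$label, character(1)))
}

# -- per-trial CSV -----------------------------------------------------------

#' Read one trial from a numeric CSV matrix
#'
#' The file layout is fixed: rows = time points, columns = channels, with an
#' optional header row of channel names. The transpose is rejected rather than
#' auto-detected. Ragged rows and non-numeric cells are errors.
#'
#' @param path path to the CSV file.
#' @param sampling_rate sampling frequency in Hz.
#' @param label task class label for the trial.
#' @param subject_id subject identifier.
#' @return An [eeg_trial()].
#' @export
read_trial_csv <- function(path, sampling_rate = 125,
                           label = NA_character_, subject_id = NA_character_) {
  if (!file.exists(path)) stop("trial file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty trial file: ", path)
  cells <- strsplit(lines, ",", fixed = TRUE)
  lens <- lengths(cells)
  if (length(unique(lens)) != 1L)
    stop("ragged rows in ", path, ": row lengths ",
         paste(unique(lens), collapse = ", "))
  first <- suppressWarnings(as.numeric(cells[[1]]))
  has_header <- anyNA(first)
  channel_names <- NULL
  if (has_header) {
    channel_names <- trimws(cells[[1]])
    cells <- cells[-1L]
    if (!length(cells)) stop("trial file has a header but no data: ", path)
  }
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(cells, use.names = FALSE)),
           nrow = length(cells), byrow = TRUE))
  if (anyNA(mat)) stop("non-numeric cell(s) in ", path)
  if (nrow(mat) < 2L) stop("trial in ", path, " has fewer than 2 time points")
  eeg_trial(mat, sampling_rate = sampling_rate, channel_names = channel_names,
            label = label, subject_id = subject_id)
}

#' Write one trial to CSV (rows = time, columns = channels)
#'
#' @param trial an [eeg_trial()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "eeg_trial"))
  header <- paste(trial$channel_names, collapse = ",")
  body <- apply(trial$samples, 1L,
                function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

# -- manifest ----------------------------------------------------------------

#' Read a dataset manifest
#'
#' The manifest is a CSV with columns `file`, `subject_id`, `label`; `file`
#' paths are resolved relative to the manifest's directory. Every referenced
#' trial is loaded and dataset-level invariants (shared sampling rate and
#' channel count, labels within the vocabulary) are checked. Users of the
#' original public recordings can point rows at their local per-trial CSV
#' exports; the package defines this manifest convention itself.
#'
#' @param path manifest CSV path.
#' @param vocabulary a [task_vocabulary()].
#' @param sampling_rate sampling frequency (Hz) applied to all trials.
#' @return A [trial_dataset()].
#' @export
read_manifest <- function(path, vocabulary = task_vocabulary(),
                          sampling_rate = 125) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "subject_id", "label")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(man$file))
    stop("duplicate file entries in manifest: ",
         paste(unique(man$file[duplicated(man$file)]), collapse = ", "))
  vocab_code(vocabulary, man$label)  # unknown labels error here
  base <- dirname(path)
  trials <- lapply(seq_len(nrow(man)), function(i) {
    f <- man$file[i]
    if (!grepl("^(/|[A-Za-z]:)", f)) f <- file.path(base, f)
    read_trial_csv(f, sampling_rate = sampling_rate,
                   label = man$label[i], subject_id = as.character(man$subject_id[i]))
  })
  trial_dataset(trials, vocabulary)
}

#' Write a dataset to per-trial CSVs plus a manifest
#'
#' @param dataset a [trial_dataset()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vapply(seq_along(dataset$trials), function(i) {
    t <- dataset$trials[[i]]
    fname <- sprintf("trial_%04d_%s_%s.csv", i, t$subject_id, t$label)
    write_trial_csv(t, file.path(dir, fname))
    paste(fname, t$subject_id, t$label, sep = ",")
  }, character(1))
  manifest <- file.path(dir, "manifest.csv")
  writeLines(c("file,subject_id,label", rows), manifest)
  invisible(manifest)
}

# -- feature table -----------------------------------------------------------

#' Write a feature table to CSV
#'
#' One row per trial: the named feature columns followed by a final `label`
#' column. Values are written with 17 significant digits so the table
#' round-trips doubles exactly.
#'
#' @param features numeric matrix (trials x features) or list of equal-length
#'   numeric vectors; column names are taken from the matrix/vectors.
#' @param labels one class label (string) per row.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, labels, path) {
  if (is.list(features) && !is.data.frame(features)) {
    lens <- lengths(features)
    if (length(unique(lens)) > 1L)
      stop("feature vectors have unequal lengths")
    nms <- names(features[[1]])
    features <- do.call(rbind, features)
    if (!is.null(nms)) colnames(features) <- nms
  }
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    stop("got ", nrow(features), " feature rows but ", length(labels), " labels")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  header <- paste(c(colnames(features), "label"), collapse = ",")
  body <- vapply(seq_len(nrow(features)), function(i) {
    paste(c(sprintf("%.17g", features[i, ]), as.character(labels[i])),
          collapse = ",")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return list with `features` (numeric matrix, named columns) and `labels`
#'   (character vector).
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"label" %in% names(df)) stop("feature table has no 'label' column")
  labels <- as.character(df$label)
  df$label <- NULL
  features <- as.matrix(df)
  if (!is.numeric(features)) stop("non-numeric feature columns in ", path)
  list(features = features, labels = labels)
}
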
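#' Frequency band definition
#'
#' @param name band name.
#' @param f_low,f_high band limits in Hz, `0 <= f_low < f_high`.
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(name, f_low, f_high) {
  if (!is.numeric(f_low) || !is.numeric(f_high) || f_low < 0 || f_low >= f_high)
    stop("band limits must satisfy 0 <= f_low < f_high")
  structure(list(name = as.character(name), f_low = as.numeric(f_low),
                 f_high = as.numeric(f_high)), class = "band_definition")
}

#' Canonical EEG frequency bands
#'
#' The five classical bands: delta (0.5-4 Hz), theta (4-8 Hz), alpha
#' (8-13 Hz), beta (13-30 Hz), gamma (30-50 Hz). A bin falling exactly on a
#' shared boundary (e.g. 4 Hz) is counted in both adjacent bands, because the
#' band-power sum is inclusive at both limits; see [band_power()].
#'
#' @return list of [band_definition()] objects, in the order above.
#' @export
default_bands <- function() {
  list(band_definition("delta", 0.5, 4),
       band_definition("theta", 4, 8),
       band_definition("alpha", 8, 13),
       band_definition("beta", 13, 30),
       band_definition("gamma", 30, 50))
}

#' Sensorimotor rhythm bands
#'
#' The two-band variant restricted to the rhythms modulated by movement:
#' mu (7.5-12.5 Hz) and beta (16-31 Hz). Selectable anywhere a band list is
#' accepted, e.g. for data recorded with a 7-31 Hz passband.
#'
#' @return list of two [band_definition()] objects.
#' @export
mu_beta_bands <- function() {
  list(band_definition("mu", 7.5, 12.5),
       band_definition("beta", 16, 31))
}

#' One-sided power spectrum of a signal
#'
#' Unnormalized forward DFT of the full epoch (rectangular window, no
#' zero-padding or detrending), reduced to the one-sided bins
#' `f_k = k * fs / N`, `k = 0..floor(N/2)`, with power `|X(f_k)|^2`. The epoch
#' length sets the frequency resolution `fs / N`.
#'
#' @param x numeric vector, length >= 2.
#' @param fs sampling frequency in Hz (> 0).
#' @return An object of class `eeg_spectrum`: list with `frequencies` (Hz) and
#'   `power` (nonnegative, same length).
#' @export
#' @examples
#' sp <- compute_spectrum(sin(2 * pi * 10 * (0:124) / 125), fs = 125)
#' dominant_frequency(sp)  # 10
compute_spectrum <- function(x, fs) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 samples for a spectrum")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a positive scalar (Hz)")
  n <- length(x)
  X <- stats::fft(x)
  k <- 0:(n %/% 2L)
  structure(list(frequencies = k * fs / n,
                 power = Mod(X[k + 1L])^2),
            class = "eeg_spectrum")
}

#' Band power
#'
#' Sum of spectral power over the bins whose center frequency lies inside the
#' band, inclusive at both limits: `P_b = sum_{f_low <= f_k <= f_high}
#' |X(f_k)|^2`. Returns 0 when no bin falls inside the band.
#'
#' @param spectrum an [compute_spectrum()] result.
#' @param band a [band_definition()].
#' @return nonnegative scalar.
#' @export
band_power <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "eeg_spectrum"), inherits(band, "band_definition"))
  sel <- spectrum$frequencies >= band$f_low & spectrum$frequencies <= band$f_high
  sum(spectrum$power[sel])
}

#' Dominant frequency
#'
#' Bin-center frequency of maximal power over the positive-frequency bins.
#' The DC bin is excluded (a nonzero mean would otherwise dominate; the
#' feature is meant to capture rhythmic activity). Ties are broken toward the
#' lowest frequency. A spectrum with no positive-frequency power (e.g. a
#' constant signal) has no dominant frequency and raises an error.
#'
#' @param spectrum an [compute_spectrum()] result.
#' @return dominant frequency in Hz, in `(0, fs/2]`.
#' @export
dominant_frequency <- function(spectrum) {
  stopifnot(inherits(spectrum, "eeg_spectrum"))
  pos <- spectrum$frequencies > 0
  pw <- spectrum$power[pos]
  if (!length(pw) || all(pw == 0))
    stop("dominant frequency undefined: no positive-frequency power")
  spectrum$frequencies[pos][which.max(pw)]  # which.max takes the first maximum
}

#' Amplitude statistics
#'
#' Four time-domain summaries of one channel. `mean_amplitude` and
#' `std_amplitude` operate on the absolute signal `|x[n]|` (mean of `|x|`;
#' population standard deviation of `|x|`, i.e. divide by N). The median is
#' taken over the raw signed samples, and the peak-to-peak amplitude is
#' `max(x) - min(x)` of the raw samples — note the deliberate asymmetry: the
#' first two are rectified statistics, the last two are not.
#'
#' @param x numeric vector, length >= 1.
#' @return scalar.
#' @name amplitude_statistics
NULL

#' @rdname amplitude_statistics
#' @export
mean_amplitude <- function(x) {
  if (!length(x)) stop("empty signal")
  mean(abs(as.numeric(x)))
}

#' @rdname amplitude_statistics
#' @export
std_amplitude <- function(x) {
  if (!length(x)) stop("empty signal")
  a <- abs(as.numeric(x))
  sqrt(mean((a - mean(a))^2))
}

#' @rdname amplitude_statistics
#' @export
median_amplitude <- function(x) {
  if (!length(x)) stop("empty signal")
  stats::median(as.numeric(x))
}

#' @rdname amplitude_statistics
#' @export
ptp_amplitude <- function(x) {
  if (!length(x)) stop("empty signal")
  x <- as.numeric(x)
  max(x) - min(x)
}

#' Names of the per-electrode features
#'
#' @param bands list of [band_definition()]s.
#' @return character vector, length `length(bands) + 5`.
#' @export
feature_names <- function(bands = default_bands()) {
  c(paste0("power_", vapply(bands, function(b) b$name, character(1))),
    "dominant_freq", "mean_amp", "std_amp", "median_amp", "ptp_amp")
}

#' Extract the per-trial feature vector
#'
#' For every electrode, in channel order: the band powers in the given band
#' order, then dominant frequency, mean amplitude, standard deviation of
#' amplitude, median amplitude, and peak-to-peak amplitude. With the five
#' [default_bands()] and 16 channels this yields the canonical 160-element
#' descriptor (10 features x 16 electrodes). Elements are named
#' `"{electrode}_{feature}"`.
#'
#' @param trial an [eeg_trial()].
#' @param bands non-empty list of [band_definition()]s.
#' @return named numeric vector of length `n_channels * (length(bands) + 5)`.
#' @export
extract_features <- function(trial, bands = default_bands()) {
  stopifnot(inherits(trial, "eeg_trial"))
  if (!length(bands)) stop("need at least one frequency band")
  per_channel <- lapply(seq_along(trial$channel_names), function(ci) {
    x <- trial$samples[, ci]
    sp <- compute_spectrum(x, trial$sampling_rate)
    fdom <- tryCatch(dominant_frequency(sp), error = function(e)
      stop("channel ", trial$channel_names[ci], ": ", conditionMessage(e),
           call. = FALSE))
    c(vapply(bands, function(b) band_power(sp, b), numeric(1)),
      fdom, mean_amplitude(x), std_amplitude(x),
      median_amplitude(x), ptp_amplitude(x))
  })
  v <- unlist(per_channel, use.names = FALSE)
  names(v) <- as.vector(t(outer(trial$channel_names, feature_names(bands),
                                paste, sep = "_")))
  v
}

#' Feature matrix for a whole dataset
#'
#' @param dataset a [trial_dataset()].
#' @param bands band list passed to [extract_features()].
#' @return list with `features` (trials x features matrix, named columns),
#'   `labels` (integer class codes), `label_names` (character),
#'   `subjects` (character), and `vocabulary`.
#' @export
extract_feature_matrix <- function(dataset, bands = default_bands()) {
  stopifnot(inherits(dataset, "trial_dataset"))
  feats <- t(vapply(dataset$trials, extract_features,
                    numeric((length(bands) + 5L) * ncol(dataset$trials[[1]]$samples)),
                    bands = bands))
  list(features = feats,
       labels = dataset_labels(dataset),
       label_names = vapply(dataset$trials, function(t) t$label, character(1)),
       subjects = vapply(dataset$trials, function(t) t$subject_id, character(1)),
       vocabulary = dataset$vocabulary)
}

#' Column indices of a feature-subset group
#'
#' Maps the layout of [extract_features()] onto the two ablation groups:
#' `"frequency"` keeps the band powers and the dominant frequency
#' (`length(bands) + 1` columns per electrode), `"time"` keeps the four
#' amplitude statistics, `"all"` keeps everything.
#'
#' @param group one of `"frequency"`, `"time"`, `"all"`.
#' @param n_channels channel count of the layout.
#' @param bands band list of the layout.
#' @return integer vector of column indices.
#' @export
feature_group_columns <- function(group, n_channels = 16,
                                  bands = default_bands()) {
  nb <- length(bands)
  per <- nb + 5L
  offsets <- switch(group,
    frequency = seq_len(nb + 1L),
    time      = (nb + 2L):per,
    all       = seq_len(per),
    stop("unknown feature group: ", group))
  as.vector(outer(offsets, (seq_len(n_channels) - 1L) * per, `+`))
}
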
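#' @importFrom stats approx fft rnorm runif rbinom quantile sd setNames
#' @importFrom utils head tail read.csv write.csv read.delim write.table
NULL

# canonical factor levels used across the package
AGE_GROUPS <- c("preschool", "school", "adolescent")
LOCATIONS  <- c("trachea", "right_anterior",
                "right_posterior_inferior", "left_posterior_inferior")
COLLECTORS <- c("physician", "parent")

#' Construct an audio recording
#'
#' Container for one mono auscultation recording: waveform, sampling rate
#' and study metadata (age group, auscultation location, collector,
#' human-supplied quality flag).
#'
#' @param samples Numeric vector of finite amplitudes.
#' @param sample_rate_hz Positive sampling rate in Hz.
#' @param recording_id Opaque identifier string.
#' @param age_group One of `"preschool"` (0-5 y), `"school"` (6-9 y),
#'   `"adolescent"` (10-17 y), or `NA`.
#' @param location One of the four auscultation sites (`"trachea"`,
#'   `"right_anterior"`, `"right_posterior_inferior"`,
#'   `"left_posterior_inferior"`), or `NA`.
#' @param collector `"physician"`, `"parent"`, or `NA`.
#' @param quality Logical quality flag (or `NA` until assessed).
#' @param patient_id Optional patient pseudo-identifier.
#' @return Object of class `audio_recording`.
#' @export
audio_recording <- function(samples, sample_rate_hz, recording_id = "rec",
                            age_group = NA_character_, location = NA_character_,
                            collector = NA_character_, quality = NA,
                            patient_id = NA_character_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("empty audio: a recording must contain samples")
  if (!all(is.finite(samples))) stop("non-finite sample values")
  if (!(is.numeric(sample_rate_hz) && sample_rate_hz > 0))
    stop("sample_rate_hz must be a positive number")
  if (!is.na(age_group)) age_group <- match.arg(age_group, AGE_GROUPS)
  if (!is.na(location))  location  <- match.arg(location, LOCATIONS)
  if (!is.na(collector)) collector <- match.arg(collector, COLLECTORS)
  structure(
    list(recording_id = recording_id, samples = samples,
         sample_rate_hz = as.integer(sample_rate_hz),
         duration_s = length(samples) / sample_rate_hz,
         age_group = age_group, location = location, collector = collector,
         quality = quality, patient_id = patient_id),
    class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %s: %.2f s @ %d Hz (%d samples)\n",
              x$recording_id, x$duration_s, x$sample_rate_hz, length(x$samples)))
  cat(sprintf("  age_group=%s location=%s collector=%s quality=%s\n",
              x$age_group, x$location, x$collector, x$quality))
  invisible(x)
}

#' Preprocessing configuration
#'
#' Defaults follow computerized respiratory-sound practice: wheeze
#' fundamentals sit roughly in 100-1000 Hz, so audio is resampled to
#' 4 kHz, band-pass filtered to 100-1800 Hz, and peak-normalized.
#'
#' Two zero-phase filter implementations are offered. `"fft"` (default)
#' is an ideal spectral band-pass: exactly zero phase, infinitely steep,
#' and idempotent, so re-preprocessing an already-preprocessed signal is
#' a no-op; its cost is mild time-domain ringing at the clip boundaries.
#' `"iir"` is a 4th-order Butterworth run forward-backward
#' (`filtfilt`), the classical choice, whose shallow skirts make
#' repeated application slightly lossy.
#'
#' @param target_rate_hz Target sampling rate (Hz).
#' @param band_hz Length-2 band edges in Hz; upper edge must stay below
#'   the Nyquist frequency of the target rate.
#' @param filter_type `"fft"` or `"iir"`.
#' @param filter_order Butterworth design order (IIR only).
#' @return List of class `preprocess_config`.
#' @export
preprocess_config <- function(target_rate_hz = 4000, band_hz = c(100, 1800),
                              filter_type = c("fft", "iir"),
                              filter_order = 4) {
  filter_type <- match.arg(filter_type)
  stopifnot(length(band_hz) == 2, band_hz[1] > 0, band_hz[2] > band_hz[1])
  if (band_hz[2] >= target_rate_hz / 2)
    stop("band upper edge (", band_hz[2], " Hz) must be below the Nyquist ",
         "frequency of the target rate (", target_rate_hz / 2, " Hz)")
  structure(list(target_rate_hz = target_rate_hz, band_hz = band_hz,
                 filter_type = filter_type, filter_order = filter_order),
            class = "preprocess_config")
}

# zero-phase band-pass; the fft path zeroes all bins outside the band
apply_bandpass <- function(x, fs, band_hz, filter_type = "fft",
                           filter_order = 4) {
  if (filter_type == "fft") {
    n <- length(x)
    X <- fft(x)
    f <- (seq_len(n) - 1) * fs / n
    f <- pmin(f, fs - f)                       # two-sided frequency axis
    X[f < band_hz[1] | f > band_hz[2]] <- 0
    Re(fft(X, inverse = TRUE)) / n
  } else {
    bf <- signal::butter(filter_order %/% 2, band_hz / (fs / 2), type = "pass")
    signal::filtfilt(bf, x)
  }
}

resample_to <- function(x, from_hz, to_hz) {
  if (from_hz == to_hz) return(x)
  r <- to_hz / from_hz
  # rational approximation of the rate ratio for polyphase resampling
  fr <- .rat(r)
  signal::resample(x, p = fr$p, q = fr$q)
}

.rat <- function(r, max_den = 1000L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(as.integer(p), q) }
    if (err < 1e-12) break
  }
  list(p = best[1], q = best[2])
}

#' Preprocess a recording
#'
#' Resamples to the target rate, applies a zero-phase Butterworth
#' band-pass, and peak-normalizes so that `max(|x|) == 1`. An all-zero
#' input passes through unchanged (no division by zero).
#'
#' @param rec [audio_recording].
#' @param cfg [preprocess_config()].
#' @return Preprocessed `audio_recording` at `cfg$target_rate_hz`.
#' @export
preprocess <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "audio_recording"), inherits(cfg, "preprocess_config"))
  x <- resample_to(rec$samples, rec$sample_rate_hz, cfg$target_rate_hz)
  x <- apply_bandpass(x, cfg$target_rate_hz, cfg$band_hz,
                      cfg$filter_type, cfg$filter_order)
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  out <- rec
  out$samples <- x
  out$sample_rate_hz <- as.integer(cfg$target_rate_hz)
  out$duration_s <- length(x) / cfg$target_rate_hz
  out
}

#' Segment a recording into fixed-length analysis windows
#'
#' Tiles the recording with non-overlapping windows of `window_s` seconds;
#' the final window is zero-padded at the tail so all windows share one
#' sample count. Concatenating the windows and truncating the pad
#' reconstructs the input exactly.
#'
#' @param rec [audio_recording].
#' @param window_s Window length in seconds (default 10, the analysis
#'   window used throughout the package).
#' @return List of `analysis_window` objects, each with fields
#'   `parent_id`, `window_index` (0-based), `offset_s`, `samples`, `pad_s`.
#' @export
segment_windows <- function(rec, window_s = 10) {
  stopifnot(inherits(rec, "audio_recording"), window_s > 0)
  fs <- rec$sample_rate_hz
  wlen <- round(window_s * fs)
  n <- length(rec$samples)
  n_win <- ceiling(n / wlen)
  lapply(seq_len(n_win) - 1L, function(i) {
    a <- i * wlen + 1L
    b <- min((i + 1L) * wlen, n)
    x <- rec$samples[a:b]
    pad <- wlen - length(x)
    if (pad > 0) x <- c(x, numeric(pad))
    structure(list(parent_id = rec$recording_id, window_index = i,
                   offset_s = i * wlen / fs, samples = x,
                   sample_rate_hz = fs, window_s = window_s,
                   pad_s = pad / fs),
              class = "analysis_window")
  })
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window> %s[%d] offset=%.1fs pad=%.2fs (%d samples @ %d Hz)\n",
              x$parent_id, x$window_index, x$offset_s, x$pad_s,
              length(x$samples), x$sample_rate_hz))
  invisible(x)
}
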
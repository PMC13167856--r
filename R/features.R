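#' Feature extraction configuration
#'
#' Framing and filterbank parameters for all three representations.
#' Defaults: 64 ms frames, 32 ms hop, 64 mel bands spanning 50-2000 Hz —
#' at 4 kHz audio this gives about 311 frames per 10-s window, a
#' tractable sequence length for the recurrent detector stage.
#'
#' @param frame_s Analysis frame length, seconds.
#' @param hop_s Frame hop, seconds.
#' @param n_mels Number of mel bands.
#' @param fmin_hz,fmax_hz Filterbank frequency range.
#' @param dynamic_range_db Log-mel dynamic range; values are floored at
#'   `reference - dynamic_range_db`.
#' @param db_reference `"window_max"` (per-window maximum, the standard
#'   log-mel convention) or `"unit"` (absolute full-scale reference, so
#'   amplitude scaling shifts the log-mel by a constant).
#' @param n_mfcc Number of MFCCs in the handcrafted vector.
#' @param rolloff_quantile Spectral roll-off quantile.
#' @param sobel_orientation Default Sobel orientation used by
#'   [feature_bundle()]: `"frequency"` responds to horizontal (tonal)
#'   ridges, `"time"` to onsets, `"magnitude"` to both.
#' @return List of class `feature_config`.
#' @export
feature_config <- function(frame_s = 0.064, hop_s = 0.032, n_mels = 64,
                           fmin_hz = 50, fmax_hz = 2000,
                           dynamic_range_db = 80,
                           db_reference = c("window_max", "unit"),
                           n_mfcc = 13, rolloff_quantile = 0.85,
                           sobel_orientation = c("frequency", "time", "magnitude")) {
  db_reference <- match.arg(db_reference)
  sobel_orientation <- match.arg(sobel_orientation)
  structure(as.list(environment()), class = "feature_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank on FFT bin frequencies; rows = bins, cols = bands
mel_filterbank <- function(n_fft, sample_rate_hz, n_mels, fmin_hz, fmax_hz) {
  n_bins <- n_fft %/% 2 + 1
  bin_hz <- (seq_len(n_bins) - 1) * sample_rate_hz / n_fft
  pts <- mel_to_hz(seq(hz_to_mel(fmin_hz), hz_to_mel(fmax_hz),
                       length.out = n_mels + 2))
  fb <- matrix(0, n_bins, n_mels)
  for (j in seq_len(n_mels)) {
    lo <- pts[j]; c0 <- pts[j + 1]; hi <- pts[j + 2]
    up <- (bin_hz - lo) / (c0 - lo)
    down <- (hi - bin_hz) / (hi - c0)
    fb[, j] <- pmax(0, pmin(up, down))
  }
  attr(fb, "center_freqs_hz") <- pts[2:(n_mels + 1)]
  fb
}

# short-time power spectrum: returns n_frames x n_bins matrix plus framing info
stft_power <- function(samples, sample_rate_hz, frame_s, hop_s) {
  flen <- round(frame_s * sample_rate_hz)
  hop <- round(hop_s * sample_rate_hz)
  n <- length(samples)
  if (n < flen) stop("frame length (", flen, " samples) exceeds input (", n, ")")
  n_frames <- (n - flen) %/% hop + 1L
  idx <- outer(seq_len(flen), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(samples[idx], nrow = flen)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1))  # Hann
  spec <- stats::mvfft(frames * w)
  n_bins <- flen %/% 2 + 1
  p <- t(Mod(spec[seq_len(n_bins), , drop = FALSE])^2)
  list(power = p, n_frames = n_frames, frame_len = flen, hop = hop,
       frame_starts_s = (seq_len(n_frames) - 1L) * hop / sample_rate_hz,
       bin_hz = (seq_len(n_bins) - 1) * sample_rate_hz / flen)
}

#' Compute a log-mel spectrogram
#'
#' STFT power, mel filterbank, then log compression to dB with a floor at
#' `reference - dynamic_range_db`. Digital silence maps entirely to the
#' floor (no `-Inf`).
#'
#' @param window An `analysis_window` (from [segment_windows()]), an
#'   [audio_recording], or a numeric vector (then `sample_rate_hz` is
#'   required).
#' @param cfg [feature_config()].
#' @param sample_rate_hz Required when `window` is a bare vector.
#' @return Object of class `mel_spectrogram`: list with `values`
#'   (n_frames x n_mels, dB), `frame_times_s` (frame centers),
#'   `frame_starts_s`, `frame_hop_s`, `frame_len_s`,
#'   `mel_center_freqs_hz`.
#' @export
mel_spectrogram <- function(window, cfg = feature_config(),
                            sample_rate_hz = NULL) {
  x <- if (inherits(window, c("analysis_window", "audio_recording")))
    window$samples else as.numeric(window)
  fs <- if (inherits(window, c("analysis_window", "audio_recording")))
    window$sample_rate_hz else sample_rate_hz
  if (is.null(fs)) stop("sample_rate_hz required for a bare vector")

  sp <- stft_power(x, fs, cfg$frame_s, cfg$hop_s)
  fb <- mel_filterbank(sp$frame_len, fs, cfg$n_mels, cfg$fmin_hz, cfg$fmax_hz)
  melpow <- sp$power %*% fb
  ref <- if (cfg$db_reference == "window_max") max(melpow) else 1
  floor_lin <- 10^(-cfg$dynamic_range_db / 10)
  v <- if (ref <= 0) matrix(-cfg$dynamic_range_db, nrow(melpow), ncol(melpow))
       else 10 * log10(pmax(melpow / ref, floor_lin))
  structure(list(values = v,
                 frame_times_s = sp$frame_starts_s + cfg$frame_s / 2,
                 frame_starts_s = sp$frame_starts_s,
                 frame_hop_s = sp$hop / fs,
                 frame_len_s = sp$frame_len / fs,
                 mel_center_freqs_hz = attr(fb, "center_freqs_hz")),
            class = "mel_spectrogram")
}

#' @export
print.mel_spectrogram <- function(x, ...) {
  cat(sprintf("<mel_spectrogram> %d frames x %d bands, hop %.0f ms, %.0f-%.0f Hz\n",
              nrow(x$values), ncol(x$values), x$frame_hop_s * 1000,
              min(x$mel_center_freqs_hz), max(x$mel_center_freqs_hz)))
  invisible(x)
}

#' Sobel-filter a (mel) spectrogram
#'
#' 3x3 Sobel gradient with replicate-edge padding, applied to the log-mel
#' values so that the edge response reflects dB contrast. A tonal wheeze
#' appears as a horizontal ridge; the `"frequency"` orientation
#' (gradient across mel bands) responds on the ridge's flanks with
#' opposite signs, `"time"` responds to onsets/offsets, and
#' `"magnitude"` is the Euclidean norm of both.
#'
#' @param mel A `mel_spectrogram` or a plain matrix (time x frequency),
#'   at least 3x3.
#' @param orientation `"frequency"`, `"time"`, or `"magnitude"`.
#' @return Matrix of the same shape as the input values.
#' @export
sobel_filter <- function(mel, orientation = c("frequency", "time", "magnitude")) {
  orientation <- match.arg(orientation)
  m <- if (inherits(mel, "mel_spectrogram")) mel$values else as.matrix(mel)
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3 || nc < 3) stop("input must be at least 3x3 for the Sobel kernel")
  # replicate padding
  P <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  sub <- function(di, dj) P[di + seq_len(nr), dj + seq_len(nc)]
  # smoothed central differences (correlation with the standard kernels)
  g_time <- (sub(2, 0) + 2 * sub(2, 1) + sub(2, 2)) -
            (sub(0, 0) + 2 * sub(0, 1) + sub(0, 2))
  g_freq <- (sub(0, 2) + 2 * sub(1, 2) + sub(2, 2)) -
            (sub(0, 0) + 2 * sub(1, 0) + sub(2, 0))
  switch(orientation,
         time = g_time,
         frequency = g_freq,
         magnitude = sqrt(g_time^2 + g_freq^2))
}

#' Per-frame handcrafted audio features
#'
#' Classical spectral descriptors per analysis frame: spectral centroid,
#' bandwidth, roll-off, flatness, zero-crossing rate, RMS energy, and
#' MFCCs (DCT-II of the log-mel energies). Silent frames map to zero by
#' convention (flatness and centroid are undefined there).
#'
#' @inheritParams mel_spectrogram
#' @return Matrix n_frames x (6 + n_mfcc) with named columns.
#' @export
handcrafted_features <- function(window, cfg = feature_config(),
                                 sample_rate_hz = NULL) {
  x <- if (inherits(window, c("analysis_window", "audio_recording")))
    window$samples else as.numeric(window)
  fs <- if (inherits(window, c("analysis_window", "audio_recording")))
    window$sample_rate_hz else sample_rate_hz
  if (is.null(fs)) stop("sample_rate_hz required for a bare vector")

  sp <- stft_power(x, fs, cfg$frame_s, cfg$hop_s)
  p <- sp$power
  f <- sp$bin_hz
  tot <- rowSums(p)
  live <- tot > 0

  centroid <- bandwidth <- rolloff <- flatness <- numeric(sp$n_frames)
  if (any(live)) {
    pl <- p[live, , drop = FALSE]
    tl <- tot[live]
    centroid[live] <- as.vector(pl %*% f) / tl
    dev2 <- sweep(outer(rep(1, nrow(pl)), f), 1, centroid[live])^2
    bandwidth[live] <- sqrt(rowSums(pl * dev2) / tl)
    cum <- t(apply(pl, 1, cumsum))
    rolloff[live] <- f[max.col(cum >= cfg$rolloff_quantile * tl,
                               ties.method = "first")]
    flatness[live] <- exp(rowMeans(log(pl + 1e-12))) / rowMeans(pl + 1e-12)
  }

  # frame-wise ZCR and RMS on the time-domain frames
  idx <- outer(seq_len(sp$frame_len), (seq_len(sp$n_frames) - 1L) * sp$hop, `+`)
  frames <- matrix(x[idx], nrow = sp$frame_len)
  zcr <- colMeans(abs(diff(sign(frames))) > 0)
  rms <- sqrt(colMeans(frames^2))

  fb <- mel_filterbank(sp$frame_len, fs, cfg$n_mels, cfg$fmin_hz, cfg$fmax_hz)
  logmel <- log(p %*% fb + 1e-10)
  # DCT-II over mel bands, first n_mfcc coefficients
  k <- seq_len(cfg$n_mfcc)
  dct <- sqrt(2 / cfg$n_mels) *
    cos(outer(seq_len(cfg$n_mels) - 0.5, k - 1) * pi / cfg$n_mels)
  mfcc <- logmel %*% dct

  out <- cbind(centroid = centroid, bandwidth = bandwidth, rolloff = rolloff,
               flatness = flatness, zcr = zcr, rms = rms, mfcc)
  colnames(out) <- c("centroid", "bandwidth", "rolloff", "flatness",
                     "zcr", "rms", paste0("mfcc", k))
  out
}

#' Assemble the detector's input representations for one window
#'
#' @inheritParams mel_spectrogram
#' @return List of class `feature_bundle`: `mel` (a `mel_spectrogram`),
#'   `sobel_mel` (same shape), `handcrafted` (n_frames x p matrix), and
#'   framing metadata.
#' @export
feature_bundle <- function(window, cfg = feature_config(),
                           sample_rate_hz = NULL) {
  mel <- mel_spectrogram(window, cfg, sample_rate_hz)
  hc <- handcrafted_features(window, cfg, sample_rate_hz)
  stopifnot(nrow(hc) == nrow(mel$values))
  structure(list(mel = mel,
                 sobel_mel = sobel_filter(mel, cfg$sobel_orientation),
                 handcrafted = hc,
                 frame_times_s = mel$frame_times_s,
                 frame_starts_s = mel$frame_starts_s,
                 frame_hop_s = mel$frame_hop_s,
                 frame_len_s = mel$frame_len_s),
            class = "feature_bundle")
}
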
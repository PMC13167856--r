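#' Read a WAV file
#'
#' Reads a RIFF/WAVE file (16-bit PCM or 32-bit IEEE float) and returns an
#' [audio_recording]. Multi-channel audio is averaged to mono, matching how
#' smartphone auscultation recordings are treated downstream.
#'
#' @param path Path to a `.wav` file.
#' @return An object of class `audio_recording` with unset metadata fields
#'   (attach them from a cohort metadata table).
#' @seealso [write_wav()], [audio_recording()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little"),
        bits         = readBin(con, "integer", 1, 2, signed = FALSE, endian = "little")
      )
      extra <- size - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        n <- size %/% 2L
        samples <- readBin(con, "integer", n, 2, signed = TRUE, endian = "little") / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        n <- size %/% 4L
        samples <- readBin(con, "numeric", n, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding: format ", fmt$audio_format,
             ", ", fmt$bits, " bits (only PCM16 and float32 are supported)")
      }
      if (size %% 2L == 1L) readBin(con, "raw", 1)  # pad byte
    } else {
      # skip unknown chunk (word-aligned)
      readBin(con, "raw", size + (size %% 2L))
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk in ", path)
  if (length(samples) == 0) stop("empty audio in ", path)

  nc <- max(1L, fmt$n_channels)
  if (nc > 1L) {
    usable <- (length(samples) %/% nc) * nc
    samples <- rowMeans(matrix(samples[seq_len(usable)], ncol = nc, byrow = TRUE))
  }
  audio_recording(samples, fmt$sample_rate,
                  recording_id = sub("\\.wav$", "", basename(path), ignore.case = TRUE))
}

#' Write a WAV file
#'
#' @param rec An [audio_recording] or a numeric vector.
#' @param path Output path.
#' @param sample_rate_hz Sampling rate; taken from `rec` when it is an
#'   `audio_recording`.
#' @param bits 16 (PCM, default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, sample_rate_hz = NULL, bits = 16L) {
  if (inherits(rec, "audio_recording")) {
    samples <- rec$samples
    sample_rate_hz <- rec$sample_rate_hz
  } else {
    samples <- as.numeric(rec)
    if (is.null(sample_rate_hz)) stop("sample_rate_hz required for a bare vector")
  }
  stopifnot(bits %in% c(16L, 32L), length(samples) > 0)

  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  fmt_code <- if (bits == 16L) 1L else 3L

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                       # mono
  writeBin(as.integer(sample_rate_hz), con, 4, endian = "little")
  writeBin(as.integer(sample_rate_hz * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 16L) {
    q <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
    writeBin(q, con, 2, endian = "little")
  } else {
    writeBin(as.numeric(samples), con, 4, endian = "little")
  }
  invisible(path)
}
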
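#' Sampled single-channel signal
#'
#' Light container for a uniformly sampled, single-channel waveform, the raw
#' phonocardiogram \eqn{x(t)}.  All transform, segmentation and feature
#' functions in the package consume this class.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units), all finite,
#'   length at least 2.
#' @param fs Sampling rate in Hz (scalar, > 0).
#' @return An object of class `time_signal`: a list with elements `samples`
#'   and `fs`.
#' @examples
#' x <- time_signal(sin(2 * pi * 10 * seq(0, 1, by = 1 / 200)), fs = 200)
#' x
#' @export
time_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (length(samples) < 2L)
    stop("signal must contain at least 2 samples", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("signal contains non-finite samples", call. = FALSE)
  structure(list(samples = samples, fs = as.numeric(fs)),
            class = "time_signal")
}

#' @export
print.time_signal <- function(x, ...) {
  cat(sprintf("<time_signal> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.time_signal <- function(x) length(x$samples)

#' Duration of a time_signal in seconds
#' @param x A `time_signal`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(x) {
  stopifnot(inherits(x, "time_signal"))
  length(x$samples) / x$fs
}

#' Extract a time slice of a signal
#'
#' Cuts `[from, to]` (seconds) out of a signal, clamped to the recording.
#' Used to cut detected or annotated heart-sound segments, optionally with a
#' symmetric context pad, before feature extraction.
#'
#' @param x A `time_signal`.
#' @param from,to Slice bounds in seconds, `from < to`.
#' @param pad Extra context in seconds added on both sides (default 0).
#' @return A `time_signal` holding the slice.
#' @export
signal_slice <- function(x, from, to, pad = 0) {
  stopifnot(inherits(x, "time_signal"), from < to, pad >= 0)
  i0 <- max(1L, 1L + floor((from - pad) * x$fs))
  i1 <- min(length(x$samples), 1L + ceiling((to + pad) * x$fs))
  time_signal(x$samples[i0:i1], x$fs)
}

#' Anti-aliased integer-factor decimation
#'
#' Low-pass filters and downsamples a signal so that its rate does not exceed
#' `target_fs`.  Heart sounds carry essentially no energy above ~200 Hz, so
#' clinical PCG recordings (often 44.1/48 kHz) are decimated to a modest
#' internal rate before the S-transform.  The decimation factor is the
#' largest integer `q` with `fs / q >= target_fs`; an FIR anti-alias filter
#' (via [signal::decimate()]) precedes subsampling.
#'
#' @param x A `time_signal`.
#' @param target_fs Maximum output sampling rate in Hz.
#' @return A `time_signal` at rate `fs / q` (unchanged when `fs <= target_fs`).
#' @export
decimate_signal <- function(x, target_fs = 2000) {
  stopifnot(inherits(x, "time_signal"), target_fs > 0)
  q <- floor(x$fs / target_fs)
  if (q < 2L) return(x)
  y <- signal::decimate(x$samples, q, ftype = "fir")
  time_signal(y, x$fs / q)
}

# ---- WAV I/O -----------------------------------------------------------
# Minimal RIFF/WAVE reader and writer: mono, PCM 16/24-bit or IEEE float32.
# No WAV package ships with the supported R stack, and the format subset
# needed here is small, so it is read and written directly.

#' Read a mono WAV file
#'
#' Supports PCM 16-bit, PCM 24-bit and IEEE float (32-bit) encodings.
#' Stereo or multichannel files are rejected: phonocardiograms are
#' single-channel and silently mixing channels would corrupt amplitudes.
#'
#' @param path Path to a `.wav` file.
#' @return A [time_signal()] with amplitudes scaled to `[-1, 1]` for PCM.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE))
      extra <- sz - 16L
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + (sz %% 2L)))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV: missing fmt or data chunk", call. = FALSE)
  if (fmt$n_channels != 1L)
    stop("only mono WAV files are supported (got ", fmt$n_channels,
         " channels)", call. = FALSE)

  if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "numeric", length(data_raw) %/% 4L, size = 4,
                 endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    v <- readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2,
                 signed = TRUE, endian = "little")
    x <- v / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    n <- length(data_raw) %/% 3L
    b <- matrix(as.integer(data_raw), nrow = 3L)[, seq_len(n), drop = FALSE]
    v <- b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else {
    stop("unsupported WAV encoding: format ", fmt$audio_format, ", ",
         fmt$bits, " bits", call. = FALSE)
  }
  time_signal(x, fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param x A [time_signal()]; amplitudes are clipped to `[-1, 1]` for PCM.
#' @param path Output path.
#' @param bits Bit depth: 16 (PCM, default) or 32 (IEEE float, lossless for
#'   double-precision signals up to float32 resolution).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bits = 16) {
  stopifnot(inherits(x, "time_signal"), bits %in% c(16, 32))
  n <- length(x$samples)
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per <- bits / 8
  data_size <- n * bytes_per
  fmt_code <- if (bits == 32) 3L else 1L

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(round(x$fs)), con, size = 4, endian = "little")
  writeBin(as.integer(round(x$fs) * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 32) {
    writeBin(x$samples, con, size = 4, endian = "little")
  } else {
    v <- pmin(pmax(x$samples, -1), 32767 / 32768)
    writeBin(as.integer(round(v * 32768)), con, size = 2, endian = "little")
  }
  invisible(path)
}
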
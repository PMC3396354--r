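#' Construct a mono audio signal
#'
#' The basic container passed between all pipeline stages: a vector of
#' dimensionless amplitude samples plus the sampling rate. Heart-sound
#' analysis here needs at least 2 kHz sampling so that the 500 Hz analysis
#' ceiling is resolvable (Nyquist).
#'
#' @param samples numeric vector of finite amplitudes, length >= 1.
#' @param sample_rate sampling rate in Hz, >= 2000.
#' @return an object of class `audio_signal` with elements `samples` and
#'   `sample_rate`.
#' @examples
#' s <- audio_signal(sin(2 * pi * 100 * (0:7999) / 8000), 8000)
#' duration(s)
#' @export
audio_signal <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop_config("'samples' must be a non-empty numeric vector")
  if (any(!is.finite(samples)))
    stop_config("all samples must be finite")
  check_scalar_num(sample_rate, "sample_rate", lower = 2000)
  structure(
    list(samples = as.numeric(samples), sample_rate = as.integer(sample_rate)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %d Hz (%.3f s)>\n",
              length(x$samples), x$sample_rate, duration(x)))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param s an `audio_signal`.
#' @return duration in seconds.
#' @export
duration <- function(s) {
  stopifnot(inherits(s, "audio_signal"))
  length(s$samples) / s$sample_rate
}

#' Read a WAV file as a mono audio signal
#'
#' Reads RIFF/WAVE files containing 8/16/24/32-bit integer PCM or 32/64-bit
#' IEEE float samples. Stereo (or multi-channel) input is mixed down to mono
#' by the per-frame channel mean; integer PCM is rescaled to \[-1, 1\].
#'
#' @param path path to an existing WAV file.
#' @return an [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path))
    stop_config("WAV file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    stop_config("not a RIFF/WAVE file: %s", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    stop_config("not a RIFF/WAVE file: %s", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      u16 <- function(off) sum(as.integer(fmt_raw[off + 1:2]) * c(1, 256))
      u32 <- function(off) sum(as.integer(fmt_raw[off + 1:4]) * 256^(0:3))
      fmt <- list(format = u16(0), channels = u16(2),
                  sample_rate = u32(4), bits = u16(14))
      # WAVE_FORMAT_EXTENSIBLE: actual format code in the sub-format GUID
      if (fmt$format == 65534L && size >= 26L) fmt$format <- u16(24)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      seek(con, size + size %% 2, origin = "current")
      next
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop_config("corrupt WAV (missing fmt/data chunk): %s", path)
  if (length(data_raw) == 0L)
    stop_config("zero-length audio in %s", path)

  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes
  x <- if (fmt$format == 1L) {
    if (fmt$bits == 8L) {
      (as.numeric(readBin(data_raw, "integer", n_total, size = 1,
                          signed = FALSE)) - 128) / 128
    } else if (fmt$bits == 16L) {
      readBin(data_raw, "integer", n_total, size = 2, signed = TRUE,
              endian = "little") / 32768
    } else if (fmt$bits == 24L) {
      m <- matrix(as.integer(data_raw[seq_len(n_total * 3L)]), nrow = 3)
      v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
      ifelse(v >= 8388608, v - 16777216, v) / 8388608
    } else if (fmt$bits == 32L) {
      readBin(data_raw, "integer", n_total, size = 4, endian = "little") / 2147483648
    } else stop_config("unsupported PCM bit depth %d in %s", fmt$bits, path)
  } else if (fmt$format == 3L) {
    readBin(data_raw, "double", n_total, size = bytes, endian = "little")
  } else {
    stop_config("unsupported WAV format code %d in %s", fmt$format, path)
  }

  if (fmt$channels > 1L) {
    n_frames <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(n_frames * fmt$channels)],
                         nrow = fmt$channels))
  }
  audio_signal(x, fmt$sample_rate)
}

#' Write a mono audio signal to a WAV file
#'
#' @param s an [audio_signal()].
#' @param path output path.
#' @param bit_depth `"pcm16"` (default) or `"float32"`.
#' @return invisibly, the number of sample frames written.
#' @export
write_wav <- function(s, path, bit_depth = c("pcm16", "float32")) {
  stopifnot(inherits(s, "audio_signal"))
  bit_depth <- match.arg(bit_depth)
  x <- s$samples
  n <- length(x)
  if (bit_depth == "pcm16") {
    fmt_code <- 1L; bits <- 16L
    pcm <- as.integer(pmax(-32768, pmin(32767, round_half_away(x * 32768))))
    data_bytes <- n * 2L
  } else {
    fmt_code <- 3L; bits <- 32L
    data_bytes <- n * 4L
  }
  con <- file(path, "wb")
  on.exit(close(con))
  block <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(s$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(s$sample_rate * block), con, size = 4, endian = "little")
  writeBin(block, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (bit_depth == "pcm16") writeBin(pcm, con, size = 2, endian = "little")
  else writeBin(x, con, size = 4, endian = "little")
  invisible(n)
}
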
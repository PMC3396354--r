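#' Pitch-analysis configuration
#'
#' @param window_ms analysis window duration w in milliseconds (default 250;
#'   the sweeps also use 100 and 500). One pitch is transcribed per window.
#' @param f_min lower bound of the dominant-frequency search band in Hz
#'   (default 1; excludes the DC bin).
#' @param f_max upper bound of the search band in Hz (default 500). Heart
#'   sounds carry no useful content above this, and the restriction keeps
#'   the computation small.
#' @param ref_freq frequency of pitch number 60 in Hz (261.6, middle C).
#' @param silence_epsilon RMS level (relative to full scale) below which a
#'   window is transcribed as a rest (default 1e-6).
#' @return a `pitch_config` list.
#' @export
pitch_config <- function(window_ms = 250, f_min = 1, f_max = 500,
                         ref_freq = 261.6, silence_epsilon = 1e-6) {
  check_scalar_num(window_ms, "window_ms", lower = 1e-9)
  check_scalar_num(f_min, "f_min", lower = 1e-12)
  check_scalar_num(f_max, "f_max")
  if (f_max <= f_min) stop_config("f_max must exceed f_min")
  check_scalar_num(ref_freq, "ref_freq", lower = 1e-12)
  check_scalar_num(silence_epsilon, "silence_epsilon", lower = 0)
  structure(list(window_ms = window_ms, f_min = f_min, f_max = f_max,
                 ref_freq = ref_freq, silence_epsilon = silence_epsilon),
            class = "pitch_config")
}

#' One analysis window of samples
#'
#' @param index 0-based window ordinal.
#' @param samples amplitude vector of the window.
#' @param duration_ms window duration in milliseconds.
#' @return a `window_frame` list.
#' @export
window_frame <- function(index, samples, duration_ms) {
  stopifnot(index >= 0, length(samples) >= 1)
  structure(list(index = as.integer(index), samples = as.numeric(samples),
                 duration_ms = duration_ms),
            class = "window_frame")
}

#' Split a signal into consecutive analysis windows
#'
#' Non-overlapping frames of `round(window_ms / 1000 * sample_rate)` samples;
#' a trailing partial window is discarded. A signal shorter than one window
#' yields an empty list (with a message), not an error.
#'
#' @param s an [audio_signal()].
#' @param cfg a [pitch_config()].
#' @return list of [window_frame()] objects with consecutive indices from 0.
#' @export
segment_windows <- function(s, cfg = pitch_config()) {
  stopifnot(inherits(s, "audio_signal"), inherits(cfg, "pitch_config"))
  n <- as.integer(round(cfg$window_ms / 1000 * s$sample_rate))
  n_win <- length(s$samples) %/% n
  if (n_win == 0L) {
    message(sprintf("signal shorter than one %g ms window; no frames", cfg$window_ms))
    return(list())
  }
  lapply(seq_len(n_win) - 1L, function(i) {
    window_frame(i, s$samples[(i * n + 1L):((i + 1L) * n)], cfg$window_ms)
  })
}

#' Frequency spectrum of one window
#'
#' Plain (untapered) discrete Fourier transform of the window,
#' `X_k = sum_j x_j exp(-i 2 pi k j / N)`, computed by FFT. No taper is
#' applied; the band restriction and amplitude gating stand in for leakage
#' control.
#'
#' @param frame a [window_frame()], or a bare numeric vector.
#' @param sample_rate sampling rate in Hz; required when `frame` is a bare
#'   vector, otherwise derived from the frame duration.
#' @return a `pcg_spectrum`: complex `coefficients` of length N and the
#'   bin width `bin_hz = sample_rate / N`.
#' @export
frame_spectrum <- function(frame, sample_rate = NULL) {
  if (inherits(frame, "window_frame")) {
    x <- frame$samples
    if (is.null(sample_rate))
      sample_rate <- length(x) / (frame$duration_ms / 1000)
  } else {
    x <- as.numeric(frame)
    if (is.null(sample_rate))
      stop_config("sample_rate required for a bare sample vector")
  }
  if (length(x) < 1L) stop_config("empty frame")
  structure(list(coefficients = stats::fft(x),
                 bin_hz = sample_rate / length(x),
                 n = length(x)),
            class = "pcg_spectrum")
}

#' Dominant frequency of a spectrum
#'
#' Returns `bin_hz * argmax_k |X_k|` over bins whose frequency lies in
#' `[f_min, f_max]`. Ties break toward the lower frequency (heart-sound
#' fundamentals sit below their harmonics). If the window's RMS (via
#' Parseval) is below `silence_epsilon` the window is a rest and `NA` is
#' returned.
#'
#' @param sp a `pcg_spectrum` from [frame_spectrum()].
#' @param cfg a [pitch_config()].
#' @return dominant frequency in Hz, or `NA_real_` for a silent window.
#' @export
dominant_frequency <- function(sp, cfg = pitch_config()) {
  stopifnot(inherits(sp, "pcg_spectrum"), inherits(cfg, "pitch_config"))
  k_lo <- as.integer(ceiling(cfg$f_min / sp$bin_hz))
  k_hi <- as.integer(floor(min(cfg$f_max, (sp$n / 2) * sp$bin_hz) / sp$bin_hz))
  if (k_hi < k_lo)
    stop_config("f_max (%g Hz) below the first usable bin (%g Hz)",
                cfg$f_max, k_lo * sp$bin_hz)
  rms <- sqrt(sum(Mod(sp$coefficients)^2)) / sp$n
  if (rms < cfg$silence_epsilon) return(NA_real_)
  k <- k_lo:k_hi
  mags <- Mod(sp$coefficients[k + 1L])
  k[which.max(mags)] * sp$bin_hz
}

#' Quantize a frequency to the nearest pitch number
#'
#' `N(p) = round(40 * log10(f / 261.6) + 60)`, clamped to \[1, 127\]. Pitch
#' 60 is middle C (261.6 Hz); doubling the frequency adds one octave
#' (about 12, since 40*log10(2) = 12.04). Rounding is half-away-from-zero.
#' Pitch 0 is reserved for rests and never returned here.
#'
#' @param f_hz frequency (or vector of frequencies) in Hz, > 0.
#' @param ref_freq frequency of pitch 60 (default 261.6 Hz).
#' @return integer pitch number(s) in \[1, 127\].
#' @export
pitch_number <- function(f_hz, ref_freq = 261.6) {
  if (any(!is.finite(f_hz)) || any(f_hz <= 0))
    stop_config("pitch_number requires finite positive frequencies")
  p <- round_half_away(40 * log10(f_hz / ref_freq) + 60)
  as.integer(pmin(127, pmax(1, p)))
}

#' Integer frequencies where the octave law deviates
#'
#' The mapping of [pitch_number()] adds 12.04 (not exactly 12) per octave,
#' so frequencies whose unrounded pitch value has fractional part in
#' \[0.5 - (40*log10(2) - 12), 0.5) round up at `2f` but not at `f`,
#' giving a difference of 13. This helper returns the frequencies in
#' `f_hz` for which `pitch_number(2f) - pitch_number(f) != 12`.
#'
#' @param f_hz vector of frequencies to check (default the 20-250 Hz
#'   heart-sound band at 1 Hz steps).
#' @return the deviating frequencies (possibly empty), with the observed
#'   differences as the `"diff"` attribute.
#' @export
octave_law_exceptions <- function(f_hz = 20:250) {
  d <- pitch_number(2 * f_hz) - pitch_number(f_hz)
  out <- f_hz[d != 12L]
  attr(out, "diff") <- d[d != 12L]
  out
}
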
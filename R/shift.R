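#' Frequency-shifting configuration
#'
#' Low-frequency windows are lifted into the reliably quantizable range by
#' remapping their spectrum upward by a fixed number of semitones and
#' re-estimating the pitch from the shifted spectrum.
#'
#' @param shift_semitones the shift size f_sh in semitones, integer >= 0
#'   (default 14; the sweeps also use 8, 20 and 26). One semitone is a
#'   frequency ratio of 2^(1/12); 0 disables lifting (estimates below the
#'   trigger then stay unresolved).
#' @param trigger_hz the shift is applied while the estimate is below this
#'   frequency (default 100 Hz).
#' @param very_low_hz when the original estimate is below this (default
#'   50 Hz) the shift is applied at least twice.
#' @param max_applications safety cap on shift applications per window
#'   (default 4).
#' @return a `shift_config` list.
#' @export
shift_config <- function(shift_semitones = 14, trigger_hz = 100,
                         very_low_hz = 50, max_applications = 4) {
  check_scalar_num(shift_semitones, "shift_semitones", lower = 0)
  check_scalar_num(trigger_hz, "trigger_hz", lower = 1e-9)
  check_scalar_num(very_low_hz, "very_low_hz", lower = 1e-9)
  if (very_low_hz >= trigger_hz)
    stop_config("very_low_hz must be below trigger_hz")
  check_scalar_num(max_applications, "max_applications", lower = 2)
  structure(list(shift_semitones = as.integer(shift_semitones),
                 trigger_hz = trigger_hz, very_low_hz = very_low_hz,
                 max_applications = as.integer(max_applications)),
            class = "shift_config")
}

#' Shift a spectrum upward by a number of semitones
#'
#' Every positive-frequency bin k is relocated to
#' `k' = round(k * 2^(semitones/12))`; colliding destinations accumulate
#' (complex sum), destinations at or beyond Nyquist are discarded, and the
#' DC bin stays in place. Conjugate symmetry is restored afterwards so the
#' inverse transform of the result is real. A shift of 0 semitones is the
#' identity.
#'
#' @param sp a `pcg_spectrum` from [frame_spectrum()].
#' @param semitones integer shift >= 0.
#' @return the shifted `pcg_spectrum` (same length and bin width).
#' @export
shift_spectrum <- function(sp, semitones) {
  stopifnot(inherits(sp, "pcg_spectrum"))
  check_scalar_num(semitones, "semitones", lower = 0)
  if (semitones == 0) return(sp)
  x <- sp$coefficients
  n <- sp$n
  half <- n %/% 2L                       # Nyquist index for even n
  factor <- 2^(semitones / 12)
  y <- complex(length.out = n)
  y[1L] <- x[1L]
  k_src <- seq_len(max(0L, as.integer(ceiling(n / 2)) - 1L))
  k_dst <- as.integer(round_half_away(k_src * factor))
  keep <- k_dst * sp$bin_hz < (n / 2) * sp$bin_hz   # strictly below Nyquist
  for (i in which(keep)) {
    y[k_dst[i] + 1L] <- y[k_dst[i] + 1L] + x[k_src[i] + 1L]
  }
  mirror <- seq_len(max(0L, as.integer(ceiling(n / 2)) - 1L))
  y[n - mirror + 1L] <- Conj(y[mirror + 1L])
  structure(list(coefficients = y, bin_hz = sp$bin_hz, n = n),
            class = "pcg_spectrum")
}

#' Reconstruct a time-domain frame from a spectrum
#'
#' Inverse FFT; the imaginary residue (zero up to rounding for
#' conjugate-symmetric input) is dropped so the result is a real frame.
#'
#' @param sp a `pcg_spectrum`.
#' @param index window ordinal carried on the reconstructed frame
#'   (default 0).
#' @return a [window_frame()] of the same length.
#' @export
inverse_spectrum <- function(sp, index = 0L) {
  stopifnot(inherits(sp, "pcg_spectrum"))
  x <- Re(stats::fft(sp$coefficients, inverse = TRUE)) / sp$n
  window_frame(index, x, 1000 / sp$bin_hz)   # duration = N / fs = 1 / bin_hz
}

#' Estimate a window's pitch, lifting low frequencies
#'
#' The per-window decision procedure: estimate the dominant frequency; if
#' the window is silent, emit a rest (pitch 0). While the estimate is below
#' `trigger_hz` (and at least twice when the original estimate was below
#' `very_low_hz`), shift the spectrum up by `shift_semitones`, inverse-FFT,
#' and re-estimate, up to `max_applications` times. The final estimate is
#' quantized with [pitch_number()].
#'
#' @param frame a preprocessed [window_frame()].
#' @param pitch_cfg a [pitch_config()].
#' @param shift_cfg a [shift_config()].
#' @param sample_rate sampling rate in Hz (needed to map bins to Hz when
#'   the frame's duration alone is ambiguous); defaults to the rate implied
#'   by the frame length and duration.
#' @return a `pitch_event` list: `window_index`, `freq_hz` (`NA` for a
#'   rest), `shift_count`, `pitch` (0 for a rest) and `unresolved` (`TRUE`
#'   when the estimate stayed below the trigger after `max_applications`).
#' @export
apply_shift_policy <- function(frame, pitch_cfg = pitch_config(),
                               shift_cfg = shift_config(),
                               sample_rate = NULL) {
  stopifnot(inherits(frame, "window_frame"))
  sp <- frame_spectrum(frame, sample_rate)
  f0 <- dominant_frequency(sp, pitch_cfg)
  if (is.na(f0)) {
    return(structure(list(window_index = frame$index, freq_hz = NA_real_,
                          shift_count = 0L, pitch = 0L, unresolved = FALSE),
                     class = "pitch_event"))
  }
  f <- f0
  n_applied <- 0L
  n_min <- if (f0 < shift_cfg$very_low_hz) 2L else 0L
  while ((n_applied < n_min || f < shift_cfg$trigger_hz) &&
         n_applied < shift_cfg$max_applications) {
    sp <- shift_spectrum(sp, shift_cfg$shift_semitones)
    frame2 <- inverse_spectrum(sp, frame$index)
    sp <- frame_spectrum(frame2, sample_rate)
    f_new <- dominant_frequency(sp, pitch_cfg)
    n_applied <- n_applied + 1L
    if (is.na(f_new)) break           # all energy pushed out of band
    f <- f_new
  }
  structure(list(window_index = frame$index, freq_hz = f,
                 shift_count = n_applied, pitch = pitch_number(f),
                 unresolved = f < shift_cfg$trigger_hz),
            class = "pitch_event")
}
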
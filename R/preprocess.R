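#' Preprocessing configuration
#'
#' Parameters of the de-noising stage applied before pitch analysis: a
#' low-pass filter that removes content above the heart-sound band, and a
#' relative amplitude gate that zeroes samples below a fraction of the
#' record's maximum amplitude.
#'
#' @param f_pass passband edge in Hz (default 250). Heart-sound energy sits
#'   almost entirely below this frequency.
#' @param f_stop stopband edge in Hz (default 400), attenuated by at least
#'   40 dB.
#' @param threshold_ratio gate threshold T as a fraction of the record
#'   maximum amplitude A_max, in \[0, 1\] (default 0.6). Samples with
#'   `|x| < T * A_max` are zeroed.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(f_pass = 250, f_stop = 400, threshold_ratio = 0.6) {
  check_scalar_num(f_pass, "f_pass", lower = 1e-9)
  check_scalar_num(f_stop, "f_stop")
  if (f_stop <= f_pass)
    stop_config("f_stop (%g) must exceed f_pass (%g)", f_stop, f_pass)
  check_scalar_num(threshold_ratio, "threshold_ratio", lower = 0, upper = 1)
  structure(list(f_pass = f_pass, f_stop = f_stop,
                 threshold_ratio = threshold_ratio),
            class = "preprocess_config")
}

# Chebyshev type-II low-pass meeting (f_pass, f_stop, 0.5 dB, 40 dB) per pass.
# The order comes from the standard closed form; rounded up to an even order.
design_lowpass <- function(cfg, sample_rate, rp = 0.5, rs = 40) {
  nyq <- sample_rate / 2
  if (cfg$f_stop >= nyq)
    stop_config("f_stop (%g Hz) must be below Nyquist (%g Hz)", cfg$f_stop, nyq)
  sel <- sqrt((10^(rs / 10) - 1) / (10^(rp / 10) - 1))
  n <- ceiling(acosh(sel) / acosh(cfg$f_stop / cfg$f_pass))
  if (n %% 2 == 1) n <- n + 1
  signal::cheby2(n, Rp = rs, W = cfg$f_stop / nyq, type = "low")
}

#' Low-pass filter a heart-sound record
#'
#' Applies the preprocessing low-pass (passband edge `f_pass`, >= 40 dB
#' attenuation at `f_stop`). In batch mode the filter runs forward-backward
#' (zero phase), which protects pulse timing; the causal variant is a single
#' forward pass, used by the streaming path.
#'
#' @param s an [audio_signal()].
#' @param cfg a [preprocess_config()].
#' @param causal if `TRUE`, single forward (causal) pass instead of
#'   zero-phase forward-backward filtering.
#' @return the filtered [audio_signal()], same length as the input.
#' @export
lowpass_filter <- function(s, cfg = preprocess_config(), causal = FALSE) {
  stopifnot(inherits(s, "audio_signal"), inherits(cfg, "preprocess_config"))
  flt <- design_lowpass(cfg, s$sample_rate)
  y <- if (causal) as.numeric(signal::filter(flt, s$samples))
       else signal::filtfilt(flt, s$samples)
  audio_signal(y, s$sample_rate)
}

#' Amplitude reconstruction (relative-threshold gating)
#'
#' Passes samples whose magnitude reaches `threshold_ratio * A_max` and
#' zeroes the rest, where `A_max` is the maximum absolute amplitude of the
#' record. This eliminates low-magnitude background noise and weak harmonics
#' so that dominant-frequency estimation sees only the high-energy pulses.
#' An all-zero signal passes through unchanged.
#'
#' @param s an [audio_signal()].
#' @param cfg a [preprocess_config()]; only `threshold_ratio` is used.
#' @param a_max optional explicit reference maximum; defaults to
#'   `max(abs(samples))` of the record. The streaming path passes a rolling
#'   maximum here.
#' @return the gated [audio_signal()].
#' @export
amplitude_reconstruct <- function(s, cfg = preprocess_config(), a_max = NULL) {
  stopifnot(inherits(s, "audio_signal"), inherits(cfg, "preprocess_config"))
  if (is.null(a_max)) a_max <- max(abs(s$samples))
  if (a_max == 0 || cfg$threshold_ratio == 0) return(s)
  x <- s$samples
  x[abs(x) < cfg$threshold_ratio * a_max] <- 0
  audio_signal(x, s$sample_rate)
}
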
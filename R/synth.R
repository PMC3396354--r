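#' Synthetic phonocardiogram specification
#'
#' Describes a labelled synthetic heart-sound record. Eight diagnostic
#' categories are emulated: A1 normal (S1 and S2 pulses), A2 split second
#' sound (S2 as two coherent sub-bursts), A3 ejection sound and A4 clicks
#' (a short 200 Hz click after S1), A5 gallop rhythm (an extra ~40 Hz pulse
#' in early diastole), A6 systolic / A7 diastolic / A8 continuous murmurs
#' (band-limited noise with a tonal core filling the respective phase).
#' Pulse fundamentals must lie in the 20-150 Hz heart-sound band and pulses
#' last about 100 ms.
#'
#' @param category one of `"A1"` ... `"A8"`.
#' @param heart_rate_bpm beats per minute (default 70).
#' @param s1_freq_hz,s2_freq_hz pulse fundamentals in Hz (defaults 120, 80).
#' @param pulse_ms pulse duration in ms (default 100).
#' @param systole_ms S1-to-S2 onset interval in ms (default 300).
#' @param noise_level additive white-noise RMS relative to the pulse peak,
#'   in \[0, 1) (default 0.05).
#' @param murmur_band murmur frequency band `c(lo, hi)` in Hz (default
#'   120-200); the murmur's tonal core sits at the band centre.
#' @param duration_s record length in seconds (default 10).
#' @param sample_rate sampling rate in Hz (default 8000).
#' @param seed RNG seed; all randomness (cycle jitter, murmur noise,
#'   background noise) derives from it.
#' @return a `pcg_spec` list.
#' @export
pcg_spec <- function(category = "A1", heart_rate_bpm = 70,
                     s1_freq_hz = 120, s2_freq_hz = 80, pulse_ms = 100,
                     systole_ms = 300, noise_level = 0.05,
                     murmur_band = c(120, 200), duration_s = 10,
                     sample_rate = 8000, seed = 1) {
  if (!category %in% paste0("A", 1:8))
    stop_config("category must be one of A1..A8, got '%s'", category)
  check_scalar_num(heart_rate_bpm, "heart_rate_bpm", lower = 20, upper = 250)
  check_scalar_num(s1_freq_hz, "s1_freq_hz", lower = 20, upper = 150)
  check_scalar_num(s2_freq_hz, "s2_freq_hz", lower = 20, upper = 150)
  check_scalar_num(pulse_ms, "pulse_ms", lower = 50, upper = 150)
  check_scalar_num(systole_ms, "systole_ms", lower = 100)
  check_scalar_num(noise_level, "noise_level", lower = 0, upper = 1 - 1e-9)
  stopifnot(length(murmur_band) == 2, murmur_band[1] < murmur_band[2])
  check_scalar_num(duration_s, "duration_s", lower = 0.5)
  check_scalar_num(sample_rate, "sample_rate", lower = 2000)
  structure(list(category = category, heart_rate_bpm = heart_rate_bpm,
                 s1_freq_hz = s1_freq_hz, s2_freq_hz = s2_freq_hz,
                 pulse_ms = pulse_ms, systole_ms = systole_ms,
                 noise_level = noise_level, murmur_band = murmur_band,
                 duration_s = duration_s, sample_rate = sample_rate,
                 seed = seed),
            class = "pcg_spec")
}

# Relative source amplitudes (fractions of the S1 peak, which defines
# A_max = 1): S2 slightly weaker than S1, clicks sharp and loud, gallop
# (S3) weaker again, murmurs well below the pulses.
.pcg_amp <- list(s1 = 1.0, s2 = 0.85, click = 0.9, gallop = 0.75,
                 murmur = 0.35)
# Click at 280 Hz: within the filter passband yet clear of the S1/S2
# harmonic stack (160, 240, 360 Hz), and on the bin grid of all three
# window sizes at 8 kHz. Gallop (S3) at 40 Hz, slightly longer than the
# valve pulses: at ~1.5+ carrier cycles of gated support its peak bin is
# stable.
.pcg_click_hz <- 280
.pcg_click_ms <- 30
.pcg_gallop_hz <- 40
.pcg_gallop_ms <- 120
.pcg_murmur_tone_frac <- 0.7   # tonal core amplitude as fraction of murmur peak
.pcg_murmur_noise_frac <- 0.08 # in-band noise sd as fraction of murmur peak

# Duration (ms) of the part of a raised-cosine pulse that survives gating
# at absolute threshold `thr` when the pulse peak is `amp`.
supra_span_ms <- function(amp, thr, dur_ms) {
  if (thr <= 0) return(dur_ms)
  th <- thr / amp
  if (th >= 1) return(0)
  dur_ms * (1 - acos(1 - 2 * th) / pi)
}

# Schedule all tonal events and murmur segments for one record, with pulse
# onsets snapped to the analysis-window grid so that each pulse's
# supra-threshold core lies inside a single window (see the methods
# vignette for why this is what makes the per-window ground truth exact).
# Jitter on the cycle length (+-2%) still decorrelates cycles from the
# window grid at the window-count level.
schedule_pcg_events <- function(spec, window_ms) {
  w_s <- window_ms / 1000
  n_windows <- as.integer(floor(spec$duration_s / w_s + 1e-9))
  rows <- list()
  murmurs <- list()

  occupied_end <- rep(-1, n_windows)     # end time of last event per window

  place <- function(nominal_s, dur_s) {
    win <- as.integer(floor(nominal_s / w_s + 1e-9))
    if (win < 0L || win >= n_windows) return(NULL)
    win_start <- win * w_s
    hi <- win_start + w_s - dur_s
    onset <- if (occupied_end[win + 1L] < 0) win_start
             else min(max(nominal_s, occupied_end[win + 1L]), hi)
    if (onset > hi + 1e-12 || onset < occupied_end[win + 1L] - 1e-12)
      return(NULL)
    occupied_end[win + 1L] <<- onset + dur_s
    list(onset = onset, window = win)
  }

  add_pulse <- function(kind, nominal_s, dur_ms, freq, amp) {
    p <- place(nominal_s, dur_ms / 1000)
    if (is.null(p)) return(invisible(NULL))
    rows[[length(rows) + 1L]] <<- data.frame(
      kind = kind, onset_s = p$onset, dur_ms = dur_ms, freq_hz = freq,
      amp = amp, window = p$window)
    invisible(p)
  }

  cat <- spec$category
  base_cycle <- 60 / spec$heart_rate_bpm
  jitter <- stats::runif(ceiling(spec$duration_s / base_cycle * 1.1) + 2,
                         -0.02, 0.02)
  t_cyc <- 0
  ci <- 0L
  while (t_cyc < spec$duration_s) {
    ci <- ci + 1L
    s1 <- add_pulse("S1", t_cyc, spec$pulse_ms, spec$s1_freq_hz, .pcg_amp$s1)
    if (cat %in% c("A3", "A4") && !is.null(s1)) {
      # ejection click directly after S1. Because S1 snaps to its window
      # start, the S1+click geometry is fixed and its peak bin verified
      # stable; sharing S2's window instead would put the click's leakage
      # tail on the S2 fundamental at jitter-dependent offsets.
      add_pulse("click", s1$onset + spec$pulse_ms / 1000, .pcg_click_ms,
                .pcg_click_hz, .pcg_amp$click)
    }
    s2_nom <- t_cyc + spec$systole_ms / 1000
    if (cat == "A2") {
      sub1 <- add_pulse("S2a", s2_nom, 40, spec$s2_freq_hz, .pcg_amp$s2)
      if (!is.null(sub1)) {
        # 62.5 ms = 5 carrier periods of 80 Hz: the sub-bursts stay
        # phase-coherent so their combined spectral peak is on the carrier
        add_pulse("S2b", sub1$onset + 0.0625, 40, spec$s2_freq_hz,
                  .pcg_amp$s2)
      }
      s2 <- sub1
    } else {
      s2 <- add_pulse("S2", s2_nom, spec$pulse_ms, spec$s2_freq_hz,
                      .pcg_amp$s2)
    }
    if (cat == "A5" && !is.null(s2)) {
      # gallop in the window after S2's: its harmonics sit on the S2
      # fundamental (2 x 40 = 80 Hz) and would perturb a shared window
      add_pulse("gallop", (s2$window + 1L) * w_s, .pcg_gallop_ms,
                .pcg_gallop_hz, .pcg_amp$gallop)
    }
    cycle_len <- base_cycle * (1 + jitter[min(ci, length(jitter))])
    # murmur spans, ducked away from the pulses with 10 ms guards
    if (cat %in% c("A6", "A7", "A8") && !is.null(s1)) {
      s1_end <- s1$onset + spec$pulse_ms / 1000
      s2_on <- if (!is.null(s2)) s2$onset else t_cyc + cycle_len
      s2_end <- s2_on + spec$pulse_ms / 1000
      spans <- switch(cat,
        A6 = list(c(s1_end + 0.01, s2_on - 0.01)),
        A7 = list(c(s2_end + 0.01, t_cyc + cycle_len - 0.01)),
        A8 = list(c(s1_end + 0.01, s2_on - 0.01),
                  c(s2_end + 0.01, t_cyc + cycle_len - 0.01)))
      for (sp_i in spans) {
        if (sp_i[2] - sp_i[1] > 0.05 && sp_i[1] < spec$duration_s) {
          murmurs[[length(murmurs) + 1L]] <- data.frame(
            kind = "murmur", onset_s = sp_i[1],
            dur_ms = (min(sp_i[2], spec$duration_s) - sp_i[1]) * 1000,
            freq_hz = mean(spec$murmur_band), amp = .pcg_amp$murmur,
            window = NA_integer_)
        }
      }
    }
    t_cyc <- t_cyc + cycle_len
  }
  out <- do.call(rbind, c(rows, murmurs))
  attr(out, "n_windows") <- n_windows
  attr(out, "window_ms") <- window_ms
  out
}

# Band-limited unit-sd noise via FFT masking.
band_noise <- function(n, lo, hi, fs) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                    # fold to physical frequency
  sp[f < lo | f > hi] <- 0
  bn <- Re(stats::fft(sp, inverse = TRUE)) / n
  s <- stats::sd(bn)
  if (s > 0) bn / s else bn
}

render_pcg <- function(schedule, spec) {
  fs <- spec$sample_rate
  n <- as.integer(round(spec$duration_s * fs))
  x <- numeric(n)
  for (i in seq_len(nrow(schedule))) {
    ev <- schedule[i, ]
    nd <- as.integer(round(ev$dur_ms / 1000 * fs))
    i0 <- as.integer(round(ev$onset_s * fs))
    idx <- (i0 + 1L):min(i0 + nd, n)
    if (length(idx) < 2L || i0 >= n) next
    tt <- (seq_along(idx) - 1) / fs
    if (ev$kind == "murmur") {
      ramp_n <- min(as.integer(0.01 * fs), length(idx) %/% 2L)
      env <- rep(1, length(idx))
      if (ramp_n > 0) {
        r <- 0.5 * (1 - cos(pi * (seq_len(ramp_n) - 1) / ramp_n))
        env[seq_len(ramp_n)] <- r
        env[length(env) - ramp_n + seq_len(ramp_n)] <- rev(r)
      }
      tone <- .pcg_murmur_tone_frac * ev$amp * env * sin(2 * pi * ev$freq_hz * tt)
      bn <- band_noise(length(idx), spec$murmur_band[1], spec$murmur_band[2], fs)
      x[idx] <- x[idx] + tone + .pcg_murmur_noise_frac * ev$amp * env * bn
    } else {
      env <- 0.5 * (1 - cos(2 * pi * tt / (nd / fs)))
      x[idx] <- x[idx] + ev$amp * env * sin(2 * pi * ev$freq_hz * tt)
    }
  }
  if (spec$noise_level > 0) x <- x + stats::rnorm(n, 0, spec$noise_level)
  x
}

# Closed-form mirror of the shift policy in bin space: the analyzer's
# re-estimate after spectral remapping is exactly the remapped bin, so the
# expected lift must use k' = round(k * 2^(s/12)) per application, not the
# continuous frequency (the two can differ by one semitone at rounding
# boundaries).
expected_lift <- function(f, bin_hz, shift_cfg) {
  k <- round_half_away(f / bin_hz)
  n <- 0L
  n_min <- if (f < shift_cfg$very_low_hz) 2L else 0L
  while ((n < n_min || k * bin_hz < shift_cfg$trigger_hz) &&
         n < shift_cfg$max_applications) {
    k <- round_half_away(k * 2^(shift_cfg$shift_semitones / 12))
    n <- n + 1L
  }
  k * bin_hz
}

#' Per-window ground truth for a synthetic record
#'
#' Derives the expected pitch of every analysis window from the generator's
#' event schedule, independently of the analysis pipeline: a source counts
#' as active when its peak amplitude reaches the gate threshold (the
#' record's maximum amplitude is the S1 peak by construction); when several
#' sources share a window the expected dominant one maximizes amplitude
#' times gated duration (the FFT peak height is proportional to both). The
#' winner's fundamental is passed through the configured shift policy's
#' bin-space lift and quantized with [pitch_number()]; windows with no
#' active source are rests (pitch 0).
#'
#' @param record a `pcg_record` from [generate_pcg()], or a schedule as
#'   produced internally (with `n_windows`/`window_ms` attributes).
#' @param config the [transcription_config()] the truth should correspond
#'   to; threshold, window size and shift size all enter the truth.
#' @return a `pcg_truth` data frame with `window_index` and `pitch`;
#'   attributes carry the category and pulse onset times.
#' @export
ground_truth <- function(record, config = transcription_config()) {
  schedule <- if (inherits(record, "pcg_record")) record$schedule else record
  if (attr(schedule, "window_ms") != config$pitch$window_ms)
    stop_config("schedule was built for %g ms windows, config asks %g ms",
                attr(schedule, "window_ms"), config$pitch$window_ms)
  n_windows <- attr(schedule, "n_windows")
  w_s <- config$pitch$window_ms / 1000
  thr <- config$preprocess$threshold_ratio          # A_max = 1 by design
  fs <- if (inherits(record, "pcg_record")) record$spec$sample_rate else 8000
  bin_hz <- fs / round(w_s * fs)
  pulses <- schedule[schedule$kind != "murmur", , drop = FALSE]
  murmurs <- schedule[schedule$kind == "murmur", , drop = FALSE]
  pitch <- integer(n_windows)
  for (w in seq_len(n_windows) - 1L) {
    best_score <- 0
    best_f <- NA_real_
    pw <- pulses[pulses$window == w & pulses$amp >= thr, , drop = FALSE]
    for (i in seq_len(nrow(pw))) {
      sc <- pw$amp[i] * supra_span_ms(pw$amp[i], thr, pw$dur_ms[i])
      if (sc > best_score) { best_score <- sc; best_f <- pw$freq_hz[i] }
    }
    if (nrow(murmurs) > 0 && .pcg_amp$murmur >= thr) {
      lo <- w * w_s; hi <- lo + w_s
      ov <- pmin(murmurs$onset_s + murmurs$dur_ms / 1000, hi) -
            pmax(murmurs$onset_s, lo)
      ov_ms <- sum(pmax(ov, 0)) * 1000
      if (ov_ms > 0) {
        sc <- .pcg_murmur_tone_frac * .pcg_amp$murmur * ov_ms
        if (sc > best_score) { best_score <- sc; best_f <- murmurs$freq_hz[1] }
      }
    }
    pitch[w + 1L] <- if (is.na(best_f)) 0L
      else pitch_number(expected_lift(best_f, bin_hz, config$shift))
  }
  structure(
    data.frame(window_index = seq_len(n_windows) - 1L, pitch = pitch),
    class = c("pcg_truth", "data.frame"),
    category = attr(schedule, "category"),
    window_ms = config$pitch$window_ms,
    pulse_onsets = pulses$onset_s)
}

#' Generate a labelled synthetic phonocardiogram
#'
#' Renders a heart-sound record for the given specification and returns it
#' together with its per-window ground-truth pitches under the given
#' transcription configuration. Pulse onsets are aligned to the analysis
#' window grid (each pulse's gated core sits inside one window) so that
#' the expected pitch of every window has a closed form; cycle lengths
#' carry the spec's +-2% jitter. Deterministic given the spec's seed.
#'
#' @param spec a [pcg_spec()].
#' @param config a [transcription_config()]; enters the window grid used
#'   for event placement and the ground-truth labels.
#' @return a `pcg_record`: `signal` ([audio_signal()]), `truth`
#'   ([ground_truth()] result), `schedule` (event table), `spec`, `config`.
#' @examples
#' rec <- generate_pcg(pcg_spec("A1", noise_level = 0, seed = 7))
#' tr <- transcribe(rec$signal, rec$config)
#' accuracy(tr, rec$truth)
#' @export
generate_pcg <- function(spec, config = transcription_config()) {
  stopifnot(inherits(spec, "pcg_spec"), inherits(config, "transcription_config"))
  out <- with_local_seed(spec$seed, {
    schedule <- schedule_pcg_events(spec, config$pitch$window_ms)
    attr(schedule, "category") <- spec$category
    samples <- render_pcg(schedule, spec)
    list(schedule = schedule, samples = samples)
  })
  rec <- structure(list(signal = audio_signal(out$samples, spec$sample_rate),
                        truth = NULL, schedule = out$schedule, spec = spec,
                        config = config),
                   class = "pcg_record")
  rec$truth <- ground_truth(rec, config)
  rec
}

#' Fixed cohort of synthetic records for evaluation sweeps
#'
#' Replicated records across the eight diagnostic categories with a fixed
#' seed table, so every sweep is reproducible bit-exactly.
#'
#' @param categories category names (default all eight).
#' @param replicates records per category (default 3).
#' @param noise_level background noise level for every record (default the
#'   generator default, 0.05).
#' @param duration_s record duration (default 10 s).
#' @param seed base seed; record seeds are `seed + 0 ... seed + n - 1` in
#'   category-major order.
#' @return list of [pcg_spec()] objects.
#' @export
make_cohort <- function(categories = paste0("A", 1:8), replicates = 3,
                        noise_level = 0.05, duration_s = 10, seed = 2026) {
  specs <- list()
  k <- 0L
  for (cat in categories) {
    for (r in seq_len(replicates)) {
      specs[[length(specs) + 1L]] <- pcg_spec(
        category = cat, noise_level = noise_level, duration_s = duration_s,
        seed = seed + k)
      k <- k + 1L
    }
  }
  specs
}
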
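#' Transcription accuracy against ground truth
#'
#' The fraction of windows whose transcribed pitch equals the expected
#' pitch, as a percentage: `P_acc = 100 * n_t / N`, where `n_t` counts
#' exact per-window matches (rests included) and `N` is the total number
#' of windows.
#'
#' @param t a `transcript` from [transcribe()].
#' @param truth a `pcg_truth` from [ground_truth()], or any data frame
#'   with a `pitch` column of the same length.
#' @return an `accuracy_report` list: `correct`, `total`, `p_acc`.
#' @export
accuracy <- function(t, truth) {
  stopifnot(inherits(t, "transcript"))
  expected <- truth$pitch
  got <- t$events$pitch
  if (length(expected) != length(got))
    stop_config("window count mismatch: transcript %d vs truth %d",
                length(got), length(expected))
  if (length(got) == 0L) stop_config("empty transcript cannot be scored")
  correct <- sum(got == expected)
  structure(list(correct = correct, total = length(got),
                 p_acc = 100 * correct / length(got)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("P_acc = %.1f%% (%d / %d windows correct)\n",
              x$p_acc, x$correct, x$total))
  invisible(x)
}

config_with <- function(base, threshold = NULL, window_ms = NULL,
                        shift = NULL, mode = NULL) {
  pre <- base$preprocess; pit <- base$pitch; shf <- base$shift
  if (!is.null(threshold))
    pre <- preprocess_config(pre$f_pass, pre$f_stop, threshold)
  if (!is.null(window_ms))
    pit <- pitch_config(window_ms, pit$f_min, pit$f_max, pit$ref_freq,
                        pit$silence_epsilon)
  if (!is.null(shift))
    shf <- shift_config(shift, shf$trigger_hz, shf$very_low_hz,
                        shf$max_applications)
  transcription_config(pre, pit, shf,
                       mode = if (is.null(mode)) base$mode else mode)
}

sweep_result <- function(rows, parameter_name, seeds) {
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(p_acc ~ parameter + category + mode, df, mean)
  agg$n_records <- stats::aggregate(p_acc ~ parameter + category + mode, df,
                                    length)$p_acc
  agg <- agg[order(agg$parameter, agg$category, agg$mode), ]
  rownames(agg) <- NULL
  structure(agg, class = c("sweep_result", "data.frame"),
            parameter_name = parameter_name, seeds = seeds,
            per_record = df)
}

#' Threshold-level sweep on a synthetic cohort
#'
#' Transcribes every cohort record at each gate threshold and scores it
#' against the ground truth for that threshold (lowering the threshold can
#' make the sub-pulse murmur sources expected content rather than noise).
#' Raising the threshold eliminates low-magnitude noise and harmonics, so
#' accuracy should not decrease with T.
#'
#' @param cohort list of [pcg_spec()] objects (see [make_cohort()]).
#' @param thresholds gate thresholds to test (default 0.2, 0.4, 0.6).
#' @param modes processing modes (default batch and streaming).
#' @param base_config configuration holding all non-swept parameters.
#' @return a `sweep_result` data frame: `parameter` (threshold),
#'   `category`, `mode`, mean `p_acc`, `n_records`; the per-record grid is
#'   attached as the `"per_record"` attribute.
#' @export
sweep_threshold <- function(cohort, thresholds = c(0.2, 0.4, 0.6),
                            modes = c("batch", "streaming"),
                            base_config = transcription_config()) {
  rows <- list()
  for (spec in cohort) {
    rec <- generate_pcg(spec, base_config)
    for (th in thresholds) {
      cfg <- config_with(base_config, threshold = th)
      truth <- ground_truth(rec, cfg)
      for (mode in modes) {
        tr <- transcribe(rec$signal, config_with(cfg, mode = mode),
                         warn = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = th, category = spec$category, mode = mode,
          seed = spec$seed, p_acc = accuracy(tr, truth)$p_acc)
      }
    }
  }
  sweep_result(rows, "threshold",
               vapply(cohort, `[[`, numeric(1), "seed"))
}

#' Window-size sweep on a synthetic cohort
#'
#' Records are regenerated per window size (event placement follows the
#' analysis grid) and scored against that window size's truth. Large
#' windows merge pulses (several notes per window); small windows cut the
#' frequency resolution and multiply the transcript size.
#'
#' @param windows_ms window sizes in ms (default 100, 250, 500).
#' @inheritParams sweep_threshold
#' @return a `sweep_result` (parameter = window size in ms).
#' @export
sweep_window <- function(cohort, windows_ms = c(100, 250, 500),
                         modes = c("batch", "streaming"),
                         base_config = transcription_config()) {
  rows <- list()
  for (spec in cohort) {
    for (w in windows_ms) {
      cfg <- config_with(base_config, window_ms = w)
      rec <- generate_pcg(spec, cfg)
      for (mode in modes) {
        tr <- transcribe(rec$signal, config_with(cfg, mode = mode),
                         warn = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = w, category = spec$category, mode = mode,
          seed = spec$seed, p_acc = accuracy(tr, rec$truth)$p_acc)
      }
    }
  }
  sweep_result(rows, "window_ms",
               vapply(cohort, `[[`, numeric(1), "seed"))
}

#' Shift-size sweep on a synthetic cohort
#'
#' Ground truth is computed once under `base_config`'s shift size and held
#' fixed across the tested shift sizes, so the shift is a genuine accuracy
#' knob: too small a shift leaves low-frequency windows one semitone off
#' after lifting, too large a shift pushes content past the analysis
#' ceiling. A shift of 0 disables lifting entirely (the before-shifting
#' baseline).
#'
#' @param shifts shift sizes in semitones (default 8, 14, 20, 26).
#' @inheritParams sweep_threshold
#' @return a `sweep_result` (parameter = shift in semitones).
#' @export
sweep_shift <- function(cohort, shifts = c(8, 14, 20, 26),
                        modes = c("batch", "streaming"),
                        base_config = transcription_config()) {
  rows <- list()
  for (spec in cohort) {
    rec <- generate_pcg(spec, base_config)
    truth <- rec$truth                       # fixed at base_config's lift
    for (sh in shifts) {
      cfg <- config_with(base_config, shift = sh)
      for (mode in modes) {
        tr <- transcribe(rec$signal, config_with(cfg, mode = mode),
                         warn = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = sh, category = spec$category, mode = mode,
          seed = spec$seed, p_acc = accuracy(tr, truth)$p_acc)
      }
    }
  }
  sweep_result(rows, "shift_semitones",
               vapply(cohort, `[[`, numeric(1), "seed"))
}
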
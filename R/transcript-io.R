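#' Write a transcript as a raw byte stream
#'
#' The textual transcript format: exactly one unsigned byte per window, in
#' window order, no header. Each byte is the pitch number of its window
#' (0 = rest). Configuration and provenance go to a JSON sidecar file with
#' the same name plus `.json` (the stream itself stays exactly one byte per
#' window).
#'
#' @param t a `transcript` from [transcribe()].
#' @param path output path (conventionally `.hst`).
#' @param sidecar write the config sidecar (default `TRUE`).
#' @return invisibly, the number of bytes written (= number of windows).
#' @export
write_transcript_binary <- function(t, path, sidecar = TRUE) {
  stopifnot(inherits(t, "transcript"))
  p <- t$events$pitch
  if (length(p) > 0 && (any(p < 0) || any(p > 127)))
    stop_config("pitch outside [0, 127]; cannot serialize")
  writeBin(as.raw(p), path)
  if (sidecar) {
    cfg <- t$config
    jsonlite::write_json(
      list(window_ms = cfg$pitch$window_ms,
           threshold = cfg$preprocess$threshold_ratio,
           shift = cfg$shift$shift_semitones,
           mode = cfg$mode,
           source_id = t$source_id),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(length(p))
}

#' Read a raw byte-stream transcript
#'
#' Inverse of [write_transcript_binary()]: each byte becomes the pitch of
#' one window. Frequencies and shift counts are not stored in the stream,
#' so they are `NA` in the result. Bytes above 127 are outside the pitch
#' range and raise an error.
#'
#' @param path path to the byte stream.
#' @param config optional [transcription_config()] to attach; when `NULL`,
#'   the sidecar (if present) supplies window size, threshold and shift.
#' @return a `transcript` whose `events$pitch` reproduces the written
#'   sequence.
#' @export
read_transcript_binary <- function(path, config = NULL) {
  if (!file.exists(path)) stop_config("transcript file not found: %s", path)
  raw_bytes <- readBin(path, "raw", n = file.size(path))
  p <- as.integer(raw_bytes)
  if (any(p > 127))
    stop_config("byte value above 127 in %s: not a pitch stream", path)
  if (is.null(config)) {
    side <- paste0(path, ".json")
    config <- if (file.exists(side)) {
      meta <- jsonlite::read_json(side, simplifyVector = TRUE)
      transcription_config(
        preprocess = preprocess_config(threshold_ratio = meta$threshold),
        pitch = pitch_config(window_ms = meta$window_ms),
        shift = shift_config(shift_semitones = meta$shift),
        mode = if (identical(meta$mode, "streaming")) "streaming" else "batch")
    } else transcription_config()
  }
  df <- data.frame(window_index = seq_along(p) - 1L,
                   freq_hz = rep(NA_real_, length(p)),
                   shift_count = rep(NA_integer_, length(p)),
                   pitch = p,
                   unresolved = rep(FALSE, length(p)))
  new_transcript(df, config, basename(path))
}

#' Write a transcript as tab-separated text
#'
#' One line per window with a header: `window_index`, `freq_hz` (the
#' post-shift estimate), `shift_count`, `pitch`.
#'
#' @param t a `transcript`.
#' @param path output path.
#' @return invisibly, the number of data lines written.
#' @export
write_transcript_tsv <- function(t, path) {
  stopifnot(inherits(t, "transcript"))
  df <- t$events[, c("window_index", "freq_hz", "shift_count", "pitch")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(df))
}

# ---- Standard MIDI File (type 0) writer -----------------------------------

# variable-length quantity encoding
midi_vlq <- function(x) {
  x <- as.integer(x)
  out <- as.raw(bitwAnd(x, 127L))
  x <- bitwShiftR(x, 7L)
  while (x > 0L) {
    out <- c(as.raw(bitwOr(bitwAnd(x, 127L), 128L)), out)
    x <- bitwShiftR(x, 7L)
  }
  out
}

int_be <- function(x, size) {
  x <- as.integer(x)
  as.raw(rev(vapply(seq_len(size) - 1L,
                    function(i) bitwAnd(bitwShiftR(x, 8L * i), 255L),
                    integer(1))))
}

#' Write a transcript as a Standard MIDI File
#'
#' Type-0 file with a single track at a fixed 120 bpm, so a 250 ms window
#' maps to an eighth note; other window sizes scale proportionally. Each
#' non-rest window becomes one note-on/note-off pair with the window's
#' pitch number; rests advance time without a note.
#'
#' @param t a `transcript`.
#' @param path output path (conventionally `.mid`).
#' @param velocity note-on velocity, 1-127 (default 96).
#' @return invisibly, the number of notes written.
#' @export
write_midi <- function(t, path, velocity = 96L) {
  stopifnot(inherits(t, "transcript"))
  tpq <- 480L                                   # ticks per quarter note
  # 120 bpm -> quarter = 500 ms -> ticks per window
  w_ticks <- as.integer(round(tpq * t$config$pitch$window_ms / 500))
  p <- t$events$pitch
  track <- c(
    as.raw(c(0x00, 0xFF, 0x51, 0x03)), int_be(500000L, 3)  # tempo 120 bpm
  )
  gap <- 0L
  n_notes <- 0L
  for (pi in p) {
    if (pi == 0L) {
      gap <- gap + w_ticks
    } else {
      track <- c(track,
                 midi_vlq(gap), as.raw(c(0x90, pi, velocity)),
                 midi_vlq(w_ticks), as.raw(c(0x80, pi, 0x40)))
      gap <- 0L
      n_notes <- n_notes + 1L
    }
  }
  track <- c(track, midi_vlq(gap), as.raw(c(0xFF, 0x2F, 0x00)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("MThd", con, eos = NULL)
  writeBin(int_be(6L, 4), con)
  writeBin(c(int_be(0L, 2), int_be(1L, 2), int_be(tpq, 2)), con)
  writeChar("MTrk", con, eos = NULL)
  writeBin(int_be(length(track), 4), con)
  writeBin(track, con)
  invisible(n_notes)
}
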
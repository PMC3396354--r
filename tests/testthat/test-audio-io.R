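test_that("WAV write/read round-trips within PCM quantization", {
  s <- make_tone(100, fs = 8000, dur = 0.5, amp = 0.8)
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(s, f)
  r <- read_wav(f)
  expect_equal(r$sample_rate, 8000L)
  expect_equal(length(r$samples), length(s$samples))
  expect_lt(max(abs(r$samples - s$samples)), 1 / 32768 + 1e-12)

  write_wav(s, f, bit_depth = "float32")
  r32 <- read_wav(f)
  expect_lt(max(abs(r32$samples - s$samples)), 1e-6)
})

test_that("header arithmetic: 10 s at 8 kHz gives 80000 samples", {
  s <- audio_signal(numeric(80000), 8000)
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(s, f)
  r <- read_wav(f)
  expect_equal(length(r$samples), 80000L)
  expect_true(all(r$samples == 0))          # all-zero stays valid audio
})

test_that("stereo input mixes to mono by channel mean", {
  # hand-build a 2-channel PCM16 WAV with identical channels
  fs <- 8000L
  x <- as.integer(round(12000 * sin(2 * pi * 50 * (0:799) / fs)))
  inter <- as.vector(rbind(x, x))           # L R L R ...
  f <- withr::local_tempfile(fileext = ".wav")
  con <- file(f, "wb")
  data_bytes <- length(inter) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + data_bytes, con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  for (v in list(c(1L, 2L))) {              # PCM, 2 channels
    writeBin(v[1], con, size = 2, endian = "little")
    writeBin(v[2], con, size = 2, endian = "little")
  }
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * 4L, con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(inter, con, size = 2, endian = "little")
  close(con)
  r <- read_wav(f)
  expect_equal(length(r$samples), 800L)
  expect_equal(r$samples, x / 32768, tolerance = 1e-12)
})

test_that("unreadable or degenerate WAV input raises a format error", {
  f <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:10), f)
  expect_error(read_wav(f), "RIFF")
  expect_error(read_wav(file.path(tempdir(), "does-not-exist.wav")),
               "not found")
  expect_error(audio_signal(numeric(0), 8000), "non-empty")
  expect_error(audio_signal(c(1, NA), 8000), "finite")
  expect_error(audio_signal(1:10, 500), "sample_rate")
})

test_that("binary transcript encodes one byte per window", {
  t <- make_transcript(c(60, 60, 58, 0))
  f <- withr::local_tempfile(fileext = ".hst")
  n <- write_transcript_binary(t, f)
  expect_equal(n, 4L)
  expect_equal(readBin(f, "raw", 10), as.raw(c(0x3C, 0x3C, 0x3A, 0x00)))

  empty <- make_transcript(integer(0))
  expect_equal(write_transcript_binary(empty, f), 0L)
  expect_equal(file.size(f), 0)
  expect_equal(nrow(read_transcript_binary(f)$events), 0L)
})

test_that("byte count always equals window count: 10 s at 250 ms is 40 bytes", {
  t <- make_transcript(rep(c(46, 0, 54, 0), 10))   # 40 windows
  f <- withr::local_tempfile(fileext = ".hst")
  expect_equal(write_transcript_binary(t, f), 40L)
  expect_equal(file.size(f), 40)
})

test_that("binary transcript read inverts write and rejects out-of-range bytes", {
  f <- withr::local_tempfile(fileext = ".hst")
  writeBin(as.raw(c(0x3C, 0x00)), f)
  expect_equal(read_transcript_binary(f)$events$pitch, c(60L, 0L))

  set.seed(42)
  for (i in 1:25) {
    p <- sample(0:127, sample(1:80, 1), replace = TRUE)
    write_transcript_binary(make_transcript(p), f)
    expect_identical(read_transcript_binary(f)$events$pitch, as.integer(p))
  }

  writeBin(as.raw(c(0x3C, 0xFF)), f)
  expect_error(read_transcript_binary(f), "above 127")
})

test_that("sidecar stores the producing configuration", {
  t <- make_transcript(c(60, 0), window_ms = 100)
  f <- withr::local_tempfile(fileext = ".hst")
  write_transcript_binary(t, f)
  expect_true(file.exists(paste0(f, ".json")))
  r <- read_transcript_binary(f)
  expect_equal(r$config$pitch$window_ms, 100)
})

test_that("MIDI output has one note per non-rest window at the Fig-4 mapping", {
  f <- withr::local_tempfile(fileext = ".mid")
  n <- write_midi(make_transcript(c(60, 0, 62)), f)
  expect_equal(n, 2L)
  bytes <- readBin(f, "raw", file.size(f))
  expect_equal(rawToChar(bytes[1:4]), "MThd")
  expect_equal(as.integer(bytes[9:10]), c(0L, 0L))     # format 0
  expect_equal(as.integer(bytes[11:12]), c(0L, 1L))    # one track
  expect_equal(sum(bytes == as.raw(0x90)), 2L)         # two note-ons

  # a 250 ms window is an eighth note at 120 bpm: 240 ticks at 480 tpq,
  # encoded as the two-byte VLQ 0x81 0x70
  expect_equal(as.integer(bytes[11:12]), c(0L, 1L))
  i90 <- which(bytes == as.raw(0x90))[1]
  expect_equal(as.integer(bytes[i90 + 1:2]), c(60L, 96L))
  expect_equal(as.integer(bytes[i90 + 3:4]), c(0x81, 0x70))

  expect_equal(write_midi(make_transcript(c(0, 0, 0)), f), 0L)
  bytes <- readBin(f, "raw", file.size(f))
  expect_equal(sum(bytes == as.raw(0x90)), 0L)

  expect_equal(write_midi(make_transcript(rep(60, 8)), f), 8L)
  bytes <- readBin(f, "raw", file.size(f))
  expect_equal(sum(bytes == as.raw(0x90)), 8L)
})
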
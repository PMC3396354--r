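test_that("a 12-semitone shift doubles an on-grid peak's frequency", {
  s <- make_tone(100, fs = 4000, dur = 0.25)       # bin 4 Hz, peak at bin 25
  sp <- frame_spectrum(s$samples, sample_rate = 4000)
  up <- shift_spectrum(sp, 12)
  expect_equal(dominant_frequency(up), 200)
  # peak magnitude carried over unchanged (no collisions at factor 2)
  expect_equal(Mod(up$coefficients[51]), Mod(sp$coefficients[26]))
})

test_that("a zero shift is the identity", {
  s <- make_tone(120, fs = 8000, dur = 0.25)
  sp <- frame_spectrum(s$samples, sample_rate = 8000)
  expect_identical(shift_spectrum(sp, 0), sp)
})

test_that("14 semitones maps bin k to round(k * 2^(14/12))", {
  s <- make_tone(60, fs = 4000, dur = 0.25)        # bin 15
  sp <- frame_spectrum(s$samples, sample_rate = 4000)
  up <- shift_spectrum(sp, 14)
  # round(15 * 2.2449) = 34 -> 136 Hz, within one bin of 60 * 2^(14/12) = 134.7
  expect_equal(dominant_frequency(up), 136)
  expect_lt(abs(dominant_frequency(up) - 60 * 2^(14 / 12)), 4)
})

test_that("inverse FFT reconstructs frames and closed forms", {
  set.seed(8)
  x <- stats::rnorm(1000)
  sp <- frame_spectrum(x, sample_rate = 4000)
  back <- inverse_spectrum(sp)
  expect_lt(max(abs(back$samples - x)) / max(abs(x)), 1e-9)

  flat <- structure(list(coefficients = complex(real = c(4, 0, 0, 0)),
                         bin_hz = 1000, n = 4L), class = "pcg_spectrum")
  expect_equal(inverse_spectrum(flat)$samples, rep(1, 4))
})

test_that("shifted spectra invert to real frames with the shifted pitch", {
  s <- make_tone(100, fs = 4000, dur = 0.25)
  sp <- frame_spectrum(s$samples, sample_rate = 4000)
  up <- shift_spectrum(sp, 12)
  # conjugate symmetry restored: the raw inverse transform is already real
  raw_inv <- stats::fft(up$coefficients, inverse = TRUE) / up$n
  expect_lt(max(abs(Im(raw_inv))), 1e-9 * max(abs(Re(raw_inv))))
  fr <- inverse_spectrum(up)
  re <- dominant_frequency(frame_spectrum(fr$samples, sample_rate = 4000))
  expect_equal(re, 200)
})

test_that("two octave shifts quadruple the re-estimated frequency", {
  s <- make_tone(100, fs = 4000, dur = 0.25)
  sp <- frame_spectrum(s$samples, sample_rate = 4000)
  f0 <- dominant_frequency(sp)
  sp2 <- shift_spectrum(shift_spectrum(sp, 12), 12)
  f2 <- dominant_frequency(frame_spectrum(inverse_spectrum(sp2)$samples,
                                          sample_rate = 4000))
  expect_lt(abs(f2 - 4 * f0), 4)                  # within one bin width
})

test_that("frequency scaling law holds across shift sizes for pure tones", {
  for (sst in c(8, 12, 14, 20)) {
    for (f0 in c(60, 80, 100)) {
      s <- make_tone(f0, fs = 8000, dur = 0.25)   # bin 4 Hz
      sp <- frame_spectrum(s$samples, sample_rate = 8000)
      fshift <- dominant_frequency(shift_spectrum(sp, sst),
                                   pitch_config(f_max = 4000))
      expect_lt(abs(fshift - f0 * 2^(sst / 12)), 4)
    }
  }
})

test_that("pitch additivity: a 12-semitone shift adds exactly 12 to the pitch", {
  # on the 4 Hz grid, avoiding the octave law's rounding-boundary
  # frequencies (e.g. 120 Hz), where the +12.04 mapping rounds to +13
  for (f0 in c(52, 60, 80, 104)) {
    s <- make_tone(f0, fs = 8000, dur = 0.25)
    sp <- frame_spectrum(s$samples, sample_rate = 8000)
    p0 <- pitch_number(dominant_frequency(sp))
    p1 <- pitch_number(dominant_frequency(shift_spectrum(sp, 12)))
    expect_identical(p1 - p0, 12L)
  }
})

test_that("shift policy leaves estimates at/above the trigger untouched", {
  s <- make_tone(120, fs = 8000, dur = 0.25)
  fr <- window_frame(0, s$samples, 250)
  ev <- apply_shift_policy(fr)
  expect_equal(ev$shift_count, 0L)
  expect_equal(ev$freq_hz, 120)
  expect_identical(ev$pitch, 46L)
  expect_false(ev$unresolved)
})

test_that("shift policy lifts 60 Hz once and 30 Hz at least twice", {
  s60 <- make_tone(60, fs = 8000, dur = 0.25)
  ev60 <- apply_shift_policy(window_frame(0, s60$samples, 250))
  expect_equal(ev60$shift_count, 1L)
  expect_equal(ev60$freq_hz, 136)                # round(15*2.2449)=34 bins
  expect_gte(ev60$freq_hz, 100)

  # 30 Hz on-grid needs a 2 Hz grid: 500 ms windows
  s30 <- make_tone(30, fs = 4000, dur = 0.5)
  ev30 <- apply_shift_policy(window_frame(0, s30$samples, 500))
  expect_equal(ev30$shift_count, 2L)             # "very low" rule
  expect_equal(ev30$freq_hz, 152)                # 30*2^(28/12)=151.2, bin-exact
  expect_false(ev30$unresolved)
})

test_that("silent frames yield rests and a zero shift disables lifting", {
  ev <- apply_shift_policy(window_frame(0, numeric(2000), 250))
  expect_identical(ev$pitch, 0L)
  expect_equal(ev$shift_count, 0L)

  s <- make_tone(60, fs = 8000, dur = 0.25)
  ev0 <- apply_shift_policy(window_frame(0, s$samples, 250),
                            shift_cfg = shift_config(shift_semitones = 0))
  expect_true(ev0$unresolved)
  expect_equal(ev0$shift_count, shift_config()$max_applications)
  expect_equal(ev0$freq_hz, 60)                  # estimate never moved
  expect_identical(ev0$pitch, pitch_number(60))
})

test_that("the policy always terminates within max_applications", {
  set.seed(13)
  for (i in 1:10) {
    x <- stats::rnorm(800)
    ev <- apply_shift_policy(window_frame(0, x, 100),
                             shift_cfg = shift_config(max_applications = 3))
    expect_lte(ev$shift_count, 3L)
  }
})
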
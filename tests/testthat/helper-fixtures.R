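# Shared fixtures: tones and small transcripts built in code.

make_tone <- function(freq, fs = 8000, dur = 1, amp = 1, phase = 0) {
  audio_signal(amp * sin(2 * pi * freq * (0:(round(dur * fs) - 1)) / fs + phase), fs)
}

# a transcript object with given pitches (for serialization tests)
make_transcript <- function(pitches, window_ms = 250) {
  n <- length(pitches)
  df <- data.frame(window_index = seq_len(n) - 1L,
                   freq_hz = rep(NA_real_, n),
                   shift_count = rep(0L, n),
                   pitch = as.integer(pitches),
                   unresolved = rep(FALSE, n))
  heartscribe:::new_transcript(
    df, transcription_config(pitch = pitch_config(window_ms = window_ms)),
    "fixture")
}

# brute-force O(N^2) DFT, the independent oracle for the FFT spectrum
dft_oracle <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
  }, complex(1))
}

# spectral flatness (geometric / arithmetic mean of the power spectrum)
# over the 1-500 Hz band of one window
flatness <- function(x, fs) {
  p <- Mod(stats::fft(x))^2
  bin <- fs / length(x)
  k <- max(1, ceiling(1 / bin)):floor(500 / bin)
  p <- p[k + 1]
  p <- p + 1e-30
  exp(mean(log(p))) / mean(p)
}
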
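Package: heartscribe
Title: Textual Transcription of Heart Sounds by Pitch Estimation and
    Spectral Frequency Shifting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts phonocardiogram (heart sound) recordings into a compact
    byte-per-window textual transcript of musical pitch numbers. Each analysis
    window is Fourier transformed, its dominant frequency in the 1-500 Hz band
    is estimated, and windows whose estimate falls below 100 Hz are lifted by a
    configurable number of semitones through spectral bin remapping and inverse
    FFT before quantization to the nearest MIDI-style pitch number. Includes
    zero-phase low-pass filtering and relative-threshold amplitude gating for
    preprocessing, a batch and a causal streaming processing path, a labelled
    synthetic phonocardiogram generator covering eight diagnostic categories
    (normal, split second sound, ejection sound, clicks, gallop rhythm, and
    systolic, diastolic and continuous murmurs), transcript serialization to a
    raw byte stream, TSV and Standard MIDI File output, and evaluation tools
    that score transcripts against ground truth and sweep the threshold,
    window-size and shift-size parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
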
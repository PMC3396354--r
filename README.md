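# heartscribe

Textual transcription of heart sounds: turn a phonocardiogram (PCG)
recording into a compact byte-per-window stream of musical pitch numbers.

Heart sounds are quasi-periodic pulse trains — S1 and S2, each ~100 ms,
with fundamentals in the 20–150 Hz band — recorded for minutes to hours in
monitoring settings. Storing them as audio is bulky and searching them is
awkward. `heartscribe` transcribes each fixed-size analysis window
(250 ms by default) to one byte holding its quantized pitch number
(0 = rest), giving a 4-byte-per-second text stream that can be indexed,
diffed and searched like any other text, and replayed symbolically via MIDI.

The transcription core is:

* **Dominant frequency per window** from the untapered FFT,
  `f(p) = Δf · argmax_k |X_k|`, restricted to 1–500 Hz, after Chebyshev-II
  low-pass filtering (250 Hz passband / 400 Hz stopband, ≥ 40 dB) and
  amplitude gating at `T · A_max` (default `T = 0.6`).
* **Frequency shifting**, the step that makes low-frequency cardiac sounds
  quantizable at all: while `f(p) < 100` Hz, every spectral bin `k` is
  remapped to `round(k · 2^(s/12))` (`s = 14` semitones by default; applied
  at least twice when the original estimate is below 50 Hz), the spectrum
  inverted, and the pitch re-estimated.
* **Pitch quantization** `N(p) = round(40 · log10(f(p) / 261.6) + 60)`,
  clamped to [1, 127]: pitch 60 is middle C (261.6 Hz) and doubling a
  frequency adds one octave.

A synthetic PCG generator with per-window ground truth covers eight
diagnostic categories (normal, split second sound, ejection sound, clicks,
gallop rhythm, systolic/diastolic/continuous murmurs), so the whole
pipeline is testable without patient recordings, and the evaluation module
re-runs the threshold / window-size / shift-size calibration sweeps on a
reproducible synthetic cohort. Batch and causal streaming (real-time
emulation) paths are both provided.

## Worked example

Generate a gallop-rhythm record, transcribe it, and score it against the
generator's ground truth:

```r
library(heartscribe)

rec <- generate_pcg(pcg_spec("A5", seed = 42))   # 10 s, 70 bpm, noise 0.05
tr  <- transcribe(rec$signal, rec$config)
tr
#> <transcript: 40 windows (250 ms), 5 rests, source ''>

head(tr$events[tr$events$pitch != 0, ], 5)
#>   window_index freq_hz shift_count pitch unresolved
#> 1            0     120           0    46      FALSE
#> 2            1     180           1    54      FALSE
#> 3            2     196           2    55      FALSE
#> 4            3     120           0    46      FALSE
#> 5            4     180           1    54      FALSE

accuracy(tr, rec$truth)
#> P_acc = 100.0% (40 / 40 windows correct)

write_transcript_binary(tr, "a5.hst")            # 40 bytes: one per window
```

Reading the events: the 120 Hz S1 pulse sits above the 100 Hz trigger and
quantizes directly to pitch 46; the 80 Hz S2 is lifted once by 14 semitones
to the 180 Hz bin (pitch 54); the 40 Hz gallop pulse is below 50 Hz, so the
shift applies twice, landing on 196 Hz (pitch 55). Silent diastolic windows
transcribe as pitch 0 and occupy one zero byte each.

The shift is what makes this work — disabling it collapses accuracy, here
on a two-category mini-cohort:

```r
cohort <- make_cohort(categories = c("A1", "A5"), replicates = 2,
                      duration_s = 5, seed = 11)
sweep_shift(cohort, shifts = c(0, 14), modes = "batch")
#>   parameter category  mode p_acc n_records
#> 1         0       A1 batch    70         2
#> 2         0       A5 batch    40         2
#> 3        14       A1 batch   100         2
#> 4        14       A5 batch   100         2
```

## Command line

A thin CLI over the same functions ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "heartscribe.R", package = "heartscribe"))')
Rscript $CLI simulate   --category A5 --seed 42 --out a5.wav --truth a5.truth.tsv
Rscript $CLI transcribe --input a5.wav --out a5.hst --window-ms 250 --threshold 0.6 --shift 14
Rscript $CLI evaluate   --transcript a5.hst --truth a5.truth.tsv
Rscript $CLI sweep      --kind shift --out shift_sweep.tsv
```

Exit codes: 0 on success, 2 on usage errors, 1 on runtime errors. Every run
logs its full effective configuration and seeds, so outputs are
reproducible byte-for-byte.

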
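# cricketsong

Semi-automated analysis of field-cricket calling songs in R.

Male crickets (*Gryllus bimaculatus*) attract females with a stereotyped
calling song: trains of **syllables** (one wing-closing movement each,
~15–25 ms) grouped into **chirps** of mostly 3–4 syllables, repeated with
chirp periods of 300–400 ms at a carrier frequency near 5 kHz. Rearing
conditions — for example lifelong constant illumination versus a normal
light:dark cycle — can shift song parameters such as chirp duration and the
inter-syllable interval (ISI), which matter for female phonotaxis. Comparing
groups therefore requires measuring tens of thousands of events per animal,
far beyond manual annotation.

`cricketsong` provides that measurement chain end to end:

1. **Detection.** The waveform is peak-normalized to [−1, 1] and its
   amplitude envelope extracted over short (2 ms) overlapping frames. A
   double (hysteresis) threshold defines events: a candidate must exceed a
   high threshold (0.1 by default) and extends over the surrounding frames
   until the envelope falls below a second, low threshold that suppresses
   noise between chirps and syllables. Each boundary is then refined to the
   nearest zero-amplitude sample of the raw waveform, and events outside a
   5–60 ms duration window are discarded as clicks or artefacts.
2. **Song model.** Syllables with gaps ≤ 40 ms form a chirp; gaps of
   40–2000 ms are inter-chirp intervals; longer gaps are pauses and excluded
   from interval statistics. Per recording the package computes chirp and
   syllable durations, inter-chirp and inter-syllable intervals (overall and
   separately for 3- and 4-syllable chirps), syllable-count proportions,
   3→4-syllable transition intervals, and the dominant frequency (averaged
   Hann periodogram, 1–10 kHz band).
3. **Statistics.** The battery used for group comparisons: Welch *t*-test,
   *F*-test of variances, a Shapiro–Wilk normality check with a log → sqrt
   transform ladder, a nested *t*-test that collapses recordings to
   individual means (the correct unit of replication), and a χ² goodness of
   fit on syllable-count proportions,
   X² = Σ (Oᵢ − Eᵢ)² / Eᵢ, Eᵢ = pᵢ · ΣO.
4. **Synthesis.** A seeded generator produces songs with exact ground truth
   (gated-sine syllables with zero-amplitude edges, controllable
   syllable-count mixture, timing jitter, noise), including `"LD-like"` and
   `"LL-like"` presets anchored to published group parameters (mean ISI 16
   vs 11.71 ms; 4-syllable chirp shares 75% vs 51%), so every detection and
   statistical claim is testable without field recordings.

## Worked example

```r
library(cricketsong)

spec <- song_preset("LD-like", n_chirps = 30, noise_rms = 0.01, seed = 42)
syn  <- synthesize_song(spec)
syl  <- detect_syllables(syn$recording)
ch   <- group_chirps(syl)
evaluate_detection(syn$truth, syl, ch)[c("recall", "precision",
                                         "max_boundary_error_ms")]
#> $recall
#> [1] 1
#> $precision
#> [1] 1
#> $max_boundary_error_ms
#> [1] 0.3174603

summarize_recording(syn$recording, ch)[
  , c("n_chirps", "mean_chirp_duration_ms",
      "mean_inter_syllable_interval_ms", "dominant_frequency_hz")]
#>   n_chirps mean_chirp_duration_ms mean_inter_syllable_interval_ms
#> 1       30               106.8148                        16.20856
#>   dominant_frequency_hz
#> 1              4888.037
```

Every one of the 109 true syllables is recovered with boundaries within a
third of a millisecond; chirps average ~107 ms (a 75/24/1 mixture of 4-, 3-
and 2-syllable chirps at 18 ms syllables and 16 ms intervals), and the
dominant frequency sits close to the 4900 Hz carrier (bin width 5.4 Hz).

Group comparisons work on summary tables with an `individual` column:

```r
run_compare(summary_LD, summary_LL,
            features = "mean_inter_syllable_interval_ms")
```

A thin command-line front end with `detect`, `summarize`, `compare` and
`simulate` subcommands is installed at
`system.file("cli", "cricketsong.R", package = "cricketsong")`.

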
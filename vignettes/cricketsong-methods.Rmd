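---
title: "Methods: detection, song parameters and group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection, song parameters and group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cricketsong)
```

## The measurement problem

A cricket calling song is a pulse train: syllables of roughly 15–25 ms,
grouped into chirps of mostly 3–4 syllables, with inter-syllable intervals
around 12–16 ms, inter-chirp intervals of a couple hundred milliseconds and
occasional long pauses. Group comparisons (for example between illumination
treatments) rest on means of these durations and intervals over thousands of
chirps per recording, so the detector's boundary placement — not just its
hit rate — propagates directly into the biology. This vignette documents the
procedure, every tunable that matters, and the choices made where the design
was genuinely open.

## Detection model

**Normalization.** Each recording is divided by its absolute peak, so all
amplitude thresholds are fractions of full scale. Silent input is left
unchanged rather than raising an error: detection then returns zero events,
which is the correct answer for silence. Normalization makes the whole chain
gain-invariant, which the test suite asserts for gains down to $10^{-3}$.

**Envelope.** The amplitude envelope is the per-frame maximum of $|x|$ over
2 ms frames advancing by 50% of the frame (defaults `frame_ms = 2`,
`hop_fraction = 0.5`). The frame maximum is parameter-light and preserves
the meaning of an amplitude threshold on a normalized signal: a frame value
of 0.1 means some sample in that frame reached 10% of full scale. An
analytic-signal (Hilbert) magnitude envelope is available behind
`detection_config(envelope = "hilbert")` for signals where the frame maximum
is too coarse. The 2 ms default resolves 5 ms syllable gaps while averaging
over several carrier periods at 4–6 kHz.

**Double threshold.** An event is a maximal run of frames with envelope
above the low threshold that contains at least one frame above the high
threshold (0.1). The low threshold closes event boundaries and suppresses
noise between chirps and syllables. Its default is 0.05: for Gaussian
chamber noise of RMS $\sigma$ relative to the song peak, the *frame maximum*
of the noise is concentrated near $\sigma\sqrt{2\ln 2m}$ (about $3.2\sigma$
for 2 ms frames at 44.1 kHz), so with noise at 1% of peak the noise envelope
sits near 0.03. A low threshold of 0.02 would then sit *below* the noise
floor of the envelope and merge all events into one run, while 0.05 is
comfortably above it and still half of the high threshold that any real
syllable must reach. Raising the high threshold can only remove events
(monotonicity), and both thresholds are configuration, not claims about any
particular corpus.

**Boundary refinement.** Syllable borders are defined at zero amplitude of
the raw waveform. The refiner anchors at the first (last) sample inside the
candidate whose magnitude reaches the high threshold and walks outward until
$|x| \le \varepsilon$, with
$\varepsilon = \max(\texttt{zero\_eps}, 4\,q_{0.10}(|x|))$ and
`zero_eps = 1e-4`. Two details matter:

* *Why anchor at the high-threshold sample rather than the frame edge?* The
  first frame of a run can begin up to one full frame (2 ms) before the
  burst; snapping to a zero at the frame edge in silence would bias onsets
  early by up to that amount. Walking inward-out from the first
  unambiguously supra-threshold sample lands on the zero crossing bounding
  the burst, keeping errors well under 1 ms.
* *Why an adaptive $\varepsilon$?* Dithered or noisy recordings rarely touch
  $|x| \le 10^{-4}$; in Gaussian noise of RMS 0.01 the expected wait for
  such a sample is several milliseconds, which would drag boundaries into
  the noise. The 10th percentile of $|x|$ estimates the noise floor (songs
  spend most samples in gaps); four times it makes the stop condition fire
  within a fraction of a carrier period. On clean signals the percentile is
  0 and the fixed `zero_eps` gives sample-exact boundaries.

Refinement is deterministic and idempotent; boundaries never cross a
neighboring event; if no zero is found within one frame of the candidate
edge the edge is kept and a warning counts such cases. Candidates with no
supra-threshold sample (possible only with hand-built candidate lists) are
returned unchanged.

**Duration filter.** Events outside 5–60 ms are discarded: the window
brackets syllable periods of 30–40 ms (syllable ~18 ms plus interval
~12–16 ms) with wide margins, rejecting sub-millisecond clicks and long
artefacts. The discarded count is reported.

## Song model

Gaps between consecutive syllables are classified by duration: ≤ 40 ms is an
inter-syllable interval (same chirp); 40–2000 ms is an inter-chirp interval;
longer gaps are pauses — they terminate the chirp but enter no interval
statistic. The 2 s pause bound is deliberately far above the 300–400 ms
chirp periods of this species, so it only excises genuine silence. By
construction every syllable belongs to exactly one chirp and a chirp's
duration equals the sum of its syllable durations and internal gaps.

Syllable-level means (syllable duration, ISI, overall and per 3-/4-syllable
class) are computed over the first `chirp_cap = 3500` chirps, mirroring the
fixed per-recording sample used in the field workflow so recordings of
different lengths contribute comparably; chirp-level means (chirp duration,
inter-chirp interval) use all chirps. Counts of 1-, 2- and 5-syllable chirps
are tabulated, never dropped.

The dominant frequency is the peak of a segment-averaged periodogram (Hann
window, 8192-sample segments, 50% overlap) restricted to 1–10 kHz,
computed over the whole recording; the per-chirp alternative was rejected
as it weights silence and signal unequally across recordings of different
duty cycle. Silent recordings return `NA` rather than a number.

## Statistics

* **Welch t** and the **variance F-test** (larger over smaller variance,
  two-sided p capped at 1) serve the overall full-data chirp-duration
  comparison. Degenerate zero-variance inputs follow explicit conventions
  (p = 1 for identical constants; p = 0, flagged, for different constants).
* **Normality ladder.** Shapiro–Wilk at $\alpha = 0.05$; on rejection a log
  transform is tried (strictly positive data only), then square root,
  keeping the first that passes and recording it. The ladder order is a
  declared convention — variance-stabilizing transforms for right-skewed
  duration data, strongest first. In `run_compare()` the transform is
  selected on the pooled values of both groups and applied to both, so the
  two samples are always compared on the same scale.
* **Nested t-test.** Recordings are subsamples; individuals are the
  biological replicates. Each individual's recordings are collapsed to
  their mean and the two treatments compared by an equal-variance t on
  individual means with $n_1 + n_2 - 2$ df. For balanced designs this is
  algebraically identical to the t from a nested ANOVA testing treatment
  over individuals-within-treatment — the test suite keeps an independent
  nested-ANOVA implementation to document the equivalence to $10^{-10}$ —
  and it is immune to pseudoreplication: duplicating recordings within an
  individual changes nothing. For unbalanced data the individual-means
  convention is used as stated rather than guessing at proprietary
  weighting schemes.
* **χ² goodness of fit** accepts non-integer "counts" (the statistic is
  well defined on non-negative reals), which allows reconstructing printed
  test statistics from published percentages; expected proportions are
  normalized internally, so uniform scaling of the weights is harmless. A
  zero expected proportion with a nonzero observed count is an error.

## The synthetic generator

`song_spec()` renders each syllable as a sine carrier (4900 Hz default,
phase 0 at onset) gated by 1 ms raised-cosine edges, so true onsets and
offsets sit at zero amplitude — exactly the boundary definition the
detector uses, making sub-millisecond boundary recovery a well-posed test.
Timing is Gaussian with truncation (non-positive gaps and syllables shorter
than the gates are re-drawn); syllable counts are drawn from a configurable
mixture; per-syllable amplitude jitter is uniform on
$[1-\texttt{jitter}, 1]$; white noise is added after gating and ground
truth records pre-noise gate times (peak normalization is time-invariant).
A fixed spec is bit-reproducible.

The presets anchor to published group parameters where those are printed:
`"LD-like"` has mean ISI 16 ms and syllable-count mixture 1/24/75% (2-, 3-,
4-syllable); `"LL-like"` has mean ISI 11.71 ms and mixture 2/47/51%. Both
share an 18 ms syllable, a 240 ± 20 ms inter-chirp interval (chirp periods
inside the 300–400 ms band), a 4900 Hz carrier (within the species' band;
no treatment difference in carrier is modeled) and noise at 0.5% of peak —
the standard deviations and noise level are this package's own choices of a
realistic chamber recording. `make_group_dataset()` adds a per-individual
Gaussian offset (SD 1 ms by default) to the ISI mean — individuals differ
in tempo more than in syllable morphology — and derives per-recording seeds
from one master seed.

What the generator does **not** emulate: reverberation and echoes,
non-stationary backgrounds (traffic, wind, conspecifics), amplitude
modulation within a syllable, frequency glides, or multi-animal overlap.
Passing the closure tests therefore demonstrates correctness of the
algorithmic chain on in-model signals, not robustness on adverse field
recordings.

## Validation scales and expectations

The validation suite and `scripts/acceptance.R` use sizes chosen to
exercise the claims at meaningful statistical resolution: 20 seeded songs of
40 chirps (both presets, noise at 0 and 1% of peak) for detector closure —
recall, precision and chirp annotation must be exact and boundary errors
≤ 1 ms; one 5-individuals × 5-recordings experiment at 500 chirps per
recording, run through the full audio pipeline at 16 kHz, for ISI recovery;
50 ground-truth replicates of that design for power and direction; and 1000
replicates under identical presets for null calibration of the nested
t-test (expected rejection 5% ± 2%).

One interpretation note: with a 1 ms between-individual SD and five
individuals per group, a group's realized mean ISI scatters around the
preset mean with SD $1/\sqrt{5} \approx 0.45$ ms. A ±0.5 ms recovery claim
is therefore evaluated against the *dataset's ground-truth* group mean —
the quantity detection can actually control — while the recovered-vs-preset
values are reported alongside for context.

## Known limitations

* WAV input only (PCM 16/24/32-bit and float); no resampling is ever done
  implicitly, and rates below 8 kHz are out of scope.
* The detector assumes one singer; overlapping animals merge into single
  events.
* Frame-maximum envelopes bound the temporal resolution of *candidate*
  boundaries at one hop (1 ms by default); the waveform-level refinement
  recovers precision only where the signal actually returns to (near) zero
  between events.
* `shapiro.test()` caps at 5000 values; larger samples are checked on 5000
  evenly spaced order statistics.
* The 3→4-syllable transition-interval statistic is honestly empty when no
  such transitions occur; downstream comparisons must tolerate `NA`.
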
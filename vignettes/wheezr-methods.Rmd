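---
title: "Methods: wheeze event detection in short pediatric lung-sound recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wheeze event detection in short pediatric lung-sound recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pediatric lung auscultation with a smartphone microphone yields short
(5–10 s) mono recordings from four standardized sites — trachea, right
anterior, and the right and left posterior inferior chest — across three
age groups (0–5, 6–9, 10–17 years). A wheeze is a continuous tonal
adventitious sound: fundamental frequency roughly 100–1000 Hz, duration
above about 100 ms, visible as a horizontal ridge on a spectrogram.
`wheezr` detects wheeze *events* (timed onset/offset intervals) within
such recordings and aggregates them to a per-recording binary outcome,
then evaluates performance with the standard diagnostic-accuracy and
agreement statistics. Because real clinical recordings of this kind are
not publicly deposited, the package ships a synthetic cohort generator
so every stage is testable end to end.

## Preprocessing

Recordings are averaged to mono, resampled to 4 kHz, band-pass filtered
to 100–1800 Hz, and peak-normalized to unit maximum amplitude.

* **Sample rate 4 kHz.** Wheeze fundamentals and their first few
  harmonics sit well below the 2 kHz Nyquist; the rate bounds
  spectrogram size and network cost.
* **Band 100–1800 Hz.** Removes heart-sound and handling rumble below
  100 Hz and out-of-band hiss, following computerized respiratory-sound
  practice.
* **Filter implementation.** The default is an exact zero-phase spectral
  (FFT) band-pass: every DFT bin outside the band is zeroed. This filter
  is idempotent — re-preprocessing an already-preprocessed signal changes
  its RMS only at machine precision — which makes the pipeline safe to
  compose and is asserted by a test. The cost is mild time-domain
  ringing at clip boundaries, irrelevant at our analysis scale. A
  4th-order Butterworth run forward–backward (`filter_type = "iir"`) is
  provided as the classical alternative; its shallow skirts make
  repeated application slightly lossy, which is why it is not the
  default.
* **Windowing.** Each recording is tiled by non-overlapping 10-s
  windows; the final window is zero-padded at the tail, so event
  timestamps on the recording timeline are never shifted. Overlap is
  configurable but defaults to none. Concatenating the windows and
  trimming the pad reconstructs the input exactly.

## Feature representations

Three representations are computed per window (64 ms Hann frames, 32 ms
hop; about 311 frames per 10-s window — a tractable sequence length for
the recurrent stage):

1. **Log-mel spectrogram**: STFT power through a 64-band triangular mel
   filterbank spanning 50–2000 Hz, log-compressed to dB and floored at
   `reference − 80 dB`. With the default per-window maximum reference,
   digital silence maps entirely to the floor and no cell is `−Inf`. An
   absolute (`"unit"`) reference is available; under it, scaling the
   waveform by a constant shifts the log-mel by a constant, which the
   Sobel stage then cancels — a gain-invariance property the suite
   checks.
2. **Sobel-filtered mel spectrogram**: a 3×3 Sobel gradient with
   replicate-edge padding applied to the *log*-mel (so edge response
   reflects dB contrast). The default `"frequency"` orientation responds
   on the flanks of horizontal tonal ridges — the visual signature a
   human reader uses — with antisymmetric sign across the crest.
3. **Handcrafted per-frame features**: spectral centroid, bandwidth,
   roll-off (0.85), flatness, zero-crossing rate, RMS, and 13 MFCCs.
   Silent frames map to zero by convention. These are z-scored with
   statistics estimated on the training split only (a leakage guard).

## The detector

The detector is a hybrid convolutional–recurrent network producing one
wheeze probability per spectrogram frame:

* two temporal convolution blocks (kernel 5 frames, 16 channels each,
  ReLU) over the stacked mel + Sobel-mel columns;
* the handcrafted vector concatenated after the convolutional stage (the
  fusion point is deliberately isolated in one builder so it can be
  revisited);
* a unidirectional LSTM (hidden size 24) over the frame sequence;
* a per-frame sigmoid output.

Training minimizes class-weighted binary cross-entropy per frame with
Adam. Wheeze frames are rare, so the positive-class weight defaults to
the inverse frame-label frequency of the training split (capped at 20).
Dropout (0.1) is applied after the convolutional stage and before the
output layer. Early stopping monitors validation frame-level F1 with
patience 4 over at most 12 epochs. Splits are enforced to be disjoint at
the *patient* level; overlapping splits are an error. All randomness
(initialization, batching, dropout) derives from one integer seed, and a
fixed seed reproduces checkpoints bit-for-bit in single-threaded runs.
The network is implemented directly in base-R matrix arithmetic
(im2col-style convolution, backpropagation through time); at the
package's problem sizes (hundreds of 10-s windows, ~17k parameters) a
fit takes on the order of a minute on one CPU.

### Event decoding

Frame posteriors become events by a hysteresis-free three-step rule, all
constants exposed in `detector_config()`:

1. threshold at `decode_threshold` (default 0.5);
2. merge sub-threshold gaps shorter than `merge_gap_s` (default 0.05 s);
3. drop surviving runs shorter than `min_event_s` (default 0.1 s, the
   conventional minimum wheeze duration), with a one-hop tolerance.

Each run is emitted as an event from the first frame's start to one hop
past the last frame's start. The one-hop tolerance in step 3 exists
because a frame is labeled positive only when at least half its 64 ms
interval overlaps an event, so an event exactly at the minimum duration
yields a decoded run up to one hop shorter than its true extent; without
the tolerance the label→decode round trip would drop boundary-length
events. With it, decoding a clean 0/1 posterior recovers every event at
or above the minimum duration within one hop of its true boundaries — an
exact property the suite asserts, alongside exact equivalence of the
decoder with a brute-force run-enumeration oracle on random posteriors.
A consequence of the half-overlap rule worth knowing: an event shorter
than half a frame sitting between frame starts produces no positive
frame at all.

### Recording-level aggregation

Window events are shifted by their window offset onto the recording
timeline. Events extending into the zero-padded tail are truncated at
the true duration; events lying entirely inside the pad are discarded —
the pad is silence the pipeline appended, so any detection there is a
model artifact, not audio. (Whether the original analysis kept or
dropped pad-region detections is unstated; discarding is the
conservative choice and is the one divergence risk we document.) A
recording is wheeze-positive iff at least one mapped event survives in
any window.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
exercised; it is first-class, tested code, not a fixture.

* **Breath tracks**: pink noise amplitude-modulated by alternating
  raised-cosine inspiratory/expiratory envelopes at age-typical resting
  respiratory rates (preschool 26, school-age 20, adolescent 15
  breaths/min). Inspiration is louder than expiration at chest sites and
  the asymmetry is reversed at the trachea — a plausibility choice,
  config-exposed. The envelope's autocorrelation peaks at the cycle
  period, which a test verifies.
* **Wheeze events**: stacks of 1–3 harmonics on a fundamental drawn from
  100–1000 Hz, slow frequency drift up to ±10%, raised-cosine ramps,
  durations 0.1–1.5 s, mixed at an SNR drawn per event. This is the
  standard acoustic definition of a wheeze (tonal, > 100 ms) — the
  clinical data were annotated by ear, so the generator's acoustic model
  is a stand-in, not a claim about any real dataset. Ground-truth
  intervals are exact, never overlap (placement is stick-breaking over
  the free time, so any feasible request succeeds), and never extend
  past the recording.
* **Artifacts**: speech-like syllabic harmonic bursts, decaying handling
  bumps, and hard clipping, reflecting the real-world failure modes of
  smartphone auscultation; a recording's quality flag is driven by the
  artifact energy fraction.
* **Cohort structure**: per-recording wheeze status is
  Bernoulli(0.18) and quality Bernoulli(0.743) by default — the
  prevalence and quality proportion of the emulated study — with one
  recording per location per patient, an age mix of roughly
  29/20/51% (preschool/school/adolescent), 17% parent-collected
  recordings, and 5–10 s durations. Empirical marginals converge to the
  configured probabilities (checked against exact binomial 99% bands at
  2000 recordings).

What the generator does **not** emulate: real airway acoustics, crackles
or other adventitious sounds, device frequency responses of specific
smartphone models (a random low-order coloration hook exists but is off
by default), ambient hospital noise statistics, or annotator
disagreement. Passing the recovery tests therefore demonstrates that the
pipeline's machinery is correct and learnable on tonal events in
breath-like noise — not that the reported clinical performance would be
reproduced on real smartphone audio.

### Scales used by the tests and the acceptance script

The end-to-end recovery check trains on 100 patients × 4 locations (400
ten-second windows) and scores 50 held-out patients (200 windows),
generated at balanced prevalence (0.5) and high SNR (6–15 dB) — the
regime in which a correct implementation should achieve recording-level
F1 ≥ 0.80, and a property chosen once, before any outcome was observed.
The study-emulation defaults (prevalence 0.18, quality 0.743) are kept
for everything that represents the cohort itself. Calibration checks use
10,000 binomial replicates (Wilson coverage), 2000 items × 3 raters
(Fleiss null), 1000 random posteriors (decoder equivalence), and 500
random 2×2 tables (kappa closed form).

## Evaluation statistics

* **Metrics**: PPV, sensitivity, specificity, accuracy
  `(TP+TN)/(TP+TN+FP+FN)` and F1 `2·PPV·Sens/(PPV+Sens)` from the
  recording-level confusion table, quality recordings only. A metric
  with a zero denominator is defined as 0 and flagged. F1 always lies
  between PPV and sensitivity (harmonic-mean bound, property-tested).
* **Confidence intervals**: 95% Wilson score intervals. The original
  report does not name its CI method; Wilson is our decision — it is
  well-calibrated at the stratum sizes involved (empirical coverage
  93–97% in a seeded simulation) and never escapes [0, 1]. F1's interval
  uses the effective proportion `2TP/(2TP+FP+FN)`.
* **Agreement**: Cohen's kappa (two raters) and Fleiss' kappa (three or
  more), with the Landis–Koch bands (< 0 poor, 0–0.20 slight, 0.21–0.40
  fair, 0.41–0.60 moderate, 0.61–0.80 substantial, 0.81–1.00 almost
  perfect). Degenerate tables (a single category throughout) leave kappa
  undefined and flagged rather than forcing a value.
* **Association tests**: Pearson's chi-square unless more than 20% of
  expected cell counts fall below 5, in which case Fisher's exact test
  is selected (network algorithm for small tables; seeded Monte-Carlo
  with 10^5 draws for large non-2×2 tables). The selected test is always
  reported alongside the p-value. Bonferroni post hocs are
  `min(1, m·p)`.
* **Rounding**: reproduction checks round half away from zero to the
  printed precision (integers for metric percentages, one decimal for
  the quality proportion), matching how published tables are typeset.

## Reproducing published aggregates

With no deposited recordings, the published performance table can still
be re-derived arithmetically from its marginal counts. From 1500 quality
recordings, 271 manual positives, 217 model positives and the printed
sensitivity (55%), `reconstruct_from_aggregates()` enumerates every
integer TP whose rounded sensitivity matches (148–150), and
`reproduce_reported()` narrows by the printed PPV and selects the
candidate closest to the printed proportions (TP = 149). The resulting
table reproduces all five printed overall percentages and the 74.3%
quality proportion exactly, and the harmonic-mean formula applied to the
printed per-stratum PPV/sensitivity reproduces six of seven printed
stratum F1 values exactly.

The seventh (right posterior inferior) prints F1 = 68 while the harmonic
mean of its printed PPV = 66 and sensitivity = 69 is 67.47 → 67. This is
rounding propagation in the source, not an implementation discrepancy:
the published F1 was computed from unrounded proportions, and exhaustive
enumeration shows *no* integer confusion table at that stratum's size
(341 quality recordings) reproduces all four of its printed metrics
simultaneously. The report therefore flags per-stratum exactness and
requires agreement within one percentage point there, rather than
silently adjusting any input.

## Known limitations

* The acoustic wheeze model is deliberately simple (harmonic stacks in
  shaped pink noise); real wheezes show richer modulation, and real
  recordings contain confounders (stridor, transmitted upper-airway
  noise) the generator does not produce.
* The network is small and CPU-bound by design; it is a faithful,
  trainable implementation of the architecture class, not a re-creation
  of any specific trained model or its weights.
* Quality assessment is a human-supplied flag throughout; the package
  propagates it (and lets the generator drive it from artifact energy)
  but does not judge quality from audio.
* Kappa routines are validated on synthetic and worked tables; the
  original annotation tables are not available, so the published
  agreement coefficients are out of reach by construction.
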
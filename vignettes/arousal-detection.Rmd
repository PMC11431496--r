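---
title: "EEG-free arousal detection from limited-channel sleep recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG-free arousal detection from limited-channel sleep recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hstarousal)
```

## The problem

Cortical arousals are brief (at least 3 s) interruptions of sleep, scored on
the electroencephalogram under AASM rules.  Home sleep testing devices
usually record no EEG, but arousals leave autonomic fingerprints in signals
those devices *can* record: a transient heart-rate surge, a change in
respiratory effort amplitude and rate, and an interruption of snoring.
`hstarousal` implements a complete pipeline for studying how well
combinations of such signals support arousal detection: a synthetic
recording generator with ground-truth arousals, preprocessing, a
convolutional-recurrent per-second detector, threshold search with
AASM-style event postprocessing, a three-level evaluation framework, and a
greedy incremental signal-selection driver.

The candidate channel pool is `Thor` (thoracic respiratory effort from an
inductance belt), `DHR` (ECG-derived heart rate), `Snore` (cannula
vibration), `Pos` (body position code), `Pos_chg` (binary position-change
indicator derived from `Pos`) and `WS` (binary wake/sleep trace derived
from the 30 s-epoch hypnogram; 1 = asleep).

## The detector

The network maps a multichannel 4 Hz input of $T$ seconds ($4T$ samples)
to one arousal probability per second:

* an **inception block**: four parallel convolution blocks (convolution →
  batch normalization → ReLU) with kernel sizes 5, 33, 65 and 129, outputs
  concatenated along the channel axis.  The large kernels give reception
  fields from ~1 s up to ~32 s at 4 Hz, matching the time scales of
  respiratory and cardiac arousal responses.
* two **residual blocks**, each with two components of two convolution
  blocks and a skip connection; the second component convolves with
  stride 2, so the two blocks together downsample 4 Hz → 1 Hz.  The four
  residual kernel sizes (1, 2, 7, 2) are mapped as: component 1 uses
  (1, 2); component 2 uses (7, 2) with the stride on its first convolution
  and a stride-2, kernel-1 projection on its skip path.  This mapping is
  one consistent reading of the four sizes; the reference architecture
  does not pin the assignment.
* two unidirectional **LSTM layers** over the 1 Hz feature sequence, and a
  linear head with a sigmoid.

Channel widths are free parameters (defaults: 16 filters per inception
branch, 64 residual channels, hidden size 64), chosen small enough for CPU
training and configurable upward.  Same-length padding keeps the length
arithmetic exact; even kernels (size 2) pad one extra sample on the left.
Since no deep-learning framework is available in the target environment,
forward and backward passes (convolution, batch normalization, LSTM, Adam)
are implemented directly in vectorized R; the analytic gradients are
verified against central finite differences in the test suite.

## Synthetic recordings

The generator emulates the study conditions the pipeline is meant for.
Defaults: one-hour records, 15 arousals per hour of sleep (a typical
middle-aged screening cohort sits in the 10–25/h range), event durations
5–15 s, minimum inter-event gap 30 s (at least 10 s, so ground truth can
never interact with the 5 s merge rule), wake fraction 0.15 with sticky
wake bouts (two-state Markov chain), and per-channel Gaussian noise.

Arousal signatures:

* `DHR`: additive surge of `hr_surge_bpm` (default 10 bpm) with a 2 s
  linear onset ramp, a plateau for the rest of the event, and exponential
  decay (τ = 5 s, truncated 10 s after offset).  The brief ramp keeps the
  mean in-event elevation close to the nominal surge, so the configured
  effect size is recoverable from the signal.
* `Thor`: a frequency- and amplitude-jittered ~0.25 Hz sinusoid whose
  amplitude is multiplied by `thor_amplitude_factor` and whose rate rises
  ~30% during events.
* `Snore`: epoch-gated oscillatory bursts (per-epoch probability
  `snore_probability`, sleep epochs only), suppressed during events.

The per-record event count target is `round(arousal_rate × sleep hours)`;
placement is rejection sampling with onsets drawn uniformly over sleep
time, stopping at the target or after 10× as many attempts.  A
deterministic target makes the configured rate the realized per-record
rate, which keeps cohort-level arousal-index checks meaningful at small
cohort sizes.  Everything is seeded: the same configuration reproduces the
same cohort bit for bit.

What the generator does *not* emulate: real cardiorespiratory coupling,
apnea events, movement artifacts, sensor drift, or inter-subject
variability beyond seed-to-seed noise.  Passing the end-to-end tests on
this data shows the pipeline is correctly wired and can learn the encoded
signatures — not that the detector reaches any particular performance on
clinical recordings.

## Preprocessing

All selected channels are resampled to 4 Hz (linear interpolation for
continuous channels, nearest neighbour for binary/categorical ones — the
method is this package's choice; the recipe only fixes the rate) and
standardized by subtracting the record median and dividing by the
interquartile range.  Binary channels (`WS`, `Pos_chg`) keep their 0/1
coding: a median/IQR transform of a nearly constant indicator is
degenerate and would destroy the semantics the wake/sleep signal is
defined with.  No filtering is applied.  Heart-rate outliers from R-peak
misdetection are repaired before standardization: samples outside
25–220 bpm or further than 30 bpm from a 5 s rolling median are replaced
by linear interpolation between valid neighbours (the bounds and window
are this package's operationalization; the goal, not the method, is fixed
by the recipe).

A record is excluded when any selected channel is missing or noisy for
strictly more than 50% of sleep time; "noisy" is operationalized as
flat-lined for more than 5 s or out of physiological range.

## Training

Per-second binary cross-entropy; batches of 30 record streams advanced in
lockstep by truncated backpropagation through time with a depth of 90
output seconds (360 input samples), LSTM state carried across segments
within a record and reset between records; Adam (β₁ = 0.9, β₂ = 0.999,
weight decay λ = 1e-5); initial learning rate 1e-4, reduced by a factor of
10 when validation AUPRC (computed over sleep seconds only) fails to
improve for four consecutive epochs; 30 epochs; the checkpoint with the
best validation AUPRC is kept.  Records shorter than the longest in their
batch are masked out of the loss rather than padded into it.

The defaults above are the full-scale recipe.  The package's own synthetic
experiments are much smaller — tens of records of 20 minutes rather than
~1000 full nights — which cuts the number of optimizer steps by three
orders of magnitude.  Those experiments therefore pass `lr_init = 1e-3`
explicitly (about 10× the full-scale rate) and 10 epochs; with Adam, total
parameter displacement scales with steps × learning rate, so a smaller
study needs a larger rate to traverse a comparable distance.  All
experiment sizes used by the tests: unit tests use 1–10 records of 1–15
minutes with very small models; the end-to-end recovery experiment uses a
30-record cohort (20 train / 4 validation / 6 test) of 20-minute records
with 8 filters per branch, 16 residual channels and hidden size 16.

## Postprocessing and threshold search

Probabilities are binarized with a strict threshold (a second exactly at
the threshold is negative), maximal positive runs become half-open events,
events separated by strictly less than 5 s are merged (transitively;
exactly 5 s is kept), and events shorter than 3 s are then discarded.
Merging runs before the duration filter, so clusters of short detections
can survive as one event.  The 5 s separation deliberately relaxes the
10 s AASM recommendation to absorb up to 3 s of onset/offset uncertainty;
3 s is the AASM minimum arousal duration.

The decision threshold maximizes event-based F1 on validation data: a
0.01-step grid sweep of *pointwise* F1 picks the starting point `t0`; a
three-point pattern `{t0 − 0.02, t0, t0 + 0.02}` is then scored by event
F1 after full postprocessing, shifting one spacing toward a winning
endpoint, halving the spacing to 0.01 when the centre wins, and stopping
when the centre wins at spacing 0.01 (ties prefer the centre, so a flat
landscape returns `t0`; at the grid boundary the boundary is returned).

## Evaluation

* **Pointwise**: precision/recall/F1 plus AUPRC (step-wise
  precision–recall integration over unique thresholds, no interpolation)
  and AUROC (rank statistic), over concatenated sleep seconds.
* **Event-based**: a detection matches a ground-truth event when it covers
  strictly more than Ω_min = 0.5 of it.  A detection matching at least one
  event is one true positive; a detection spanning several events counts
  once but credits each spanned event as found (recall is ground-truth
  accounted).  Events with a majority of their seconds in wake are
  discarded on both sides before matching.
* **Recordwise**: event metrics per test record, summarized as mean (SD);
  records without ground-truth events are flagged and excluded from the
  summaries.  Comparisons between signal combinations use a bootstrap
  paired t-test (resampling mean-centred paired differences, two-sided,
  default 10 000 replicates) with Holm step-down correction; the Holm
  family is the set of pairwise comparisons in one analysis round.
  Relative confusion matrices cross-tabulate ground-truth events by which
  of two detectors found them.  Arousal-index agreement uses Pearson
  correlation and Bland–Altman limits (mean bias ± 1.96 SD).

One property of the bare coverage criterion deserves emphasis: a single
detection spanning an entire record scores a perfect event F1 (one true
positive, no false positives, every ground-truth event covered), and an
*uninformative* model — whose probabilities hover near the positive-class
prevalence — reaches exactly that solution through the threshold search.
To keep event scores meaningful, the pipeline reclassifies detections
longer than 30 s as predicted wakefulness (`discard_long_detections()`)
before matching: scored arousals last 3–15 s, and longer sustained shifts
count as awakening, so a half-night "arousal" is physiologically
meaningless anyway.  The matcher itself, and the merge/discard chain,
implement the published semantics unchanged.

## Incremental signal selection

Round I trains single-signal models on `DHR`, `Thor` and `Snore` only
(position and wake/sleep carry no standalone arousal information); each
later round augments the best previous combination with every unused
signal and advances the winner by mean recordwise event-based F1.  Two
schedules are provided: pure greedy (run to pool exhaustion, 18
combinations for the 6-signal pool, optionally stopping when a round fails
to improve) and the published 16-combination path, in which round III
explores every triple made of the round-I winner plus a 2-subset of the
advancing pairs' partners and `Pos` (`Pos_chg` excluded — the published
schedule drops it without explanation, and the switch simply encodes that
choice), and rounds IV–V extend the incumbent with the remaining
non-`Pos_chg` signals one per round.  Per-candidate seeds derive from the
master seed and the combination key, so results are order-invariant and
bit-reproducible.

## Numerical and degenerate-input choices

* Time is seconds from record start, 0-based; intervals are half-open
  `[onset, offset)`; the 1 Hz label at index `t+1` covers `[t, t+1)`.
* Flat channels (IQR = 0) are median-centred and flagged rather than
  divided by zero; an all-invalid heart-rate trace is replaced by its
  clamped median and flagged.
* Batch-normalization uses ε = 1e-5 and momentum 0.1 for running
  statistics; inference uses the running statistics.
* Zero-variance paired differences make the bootstrap test return p = 1
  with a flag; a perfect Bland–Altman agreement with degenerate variance
  reports r = 1 rather than NA.
* Inputs whose length is not a multiple of 4 samples are padded by
  repeating the last sample and truncated to `floor(n/4)` outputs.

## Limitations

The synthetic generator is a wiring-and-learnability instrument, not a
physiological simulator; numbers obtained on it say nothing quantitative
about clinical performance.  Real-data use requires EDF recordings with
NSRR-style XML annotations and inherits their scoring conventions.  The
hand-rolled network is CPU-oriented; it is adequate for the desk-scale
studies here but not tuned for full-cohort training runs.
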
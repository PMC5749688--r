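---
title: "Decoding appraisal checks from epoched EEG and facial EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding appraisal checks from epoched EEG and facial EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(appraisalDecode)
```

## The problem

Appraisal theories of emotion — most prominently the Component Process
Model — hold that emotions arise from a fixed sequence of rapid stimulus
evaluation checks: is the event novel, is it intrinsically pleasant, does it
help my goals, do I control it, do I have the power to change it. Each check
is hypothesized to leave a measurable trace in central (EEG) and peripheral
(facial EMG) physiology. `appraisalDecode` implements a complete
machine-learning protocol for testing that hypothesis on epoched recordings
from factorial experiments: every trial belongs to one condition cell (a full
combination of check levels), and for each check in turn the cells are
collapsed to that check's levels and a participant-independent classifier is
asked to recover them from the signals.

The package covers six stages, each usable on its own:

1. **synthesis** — a seedable generator of ERP-like epoch sets;
2. **preprocessing** — EMG conditioning, baseline correction, artifact and
   outlier rejection;
3. **trial handling** — check relabeling, within-participant averaging of
   T trials, channel-set restriction;
4. **features** — a static spectro-temporal descriptor vector per instance;
5. **decoding** — nested participant-independent 3-fold cross-validation
   around a linear maximum-margin classifier;
6. **statistics** — unweighted average recall (UAR) against exact binomial
   empirical chance levels.

## The decoding protocol and its assumptions

Participants are partitioned at random into three folds; in each of the
three rotations one fold is the test set, one the validation set and the
remaining one the training set, so a model is never evaluated on signals
from a participant it has seen. Within a rotation:

* all sets are standardized to the training set's per-feature mean and
  standard deviation (constant features are centered, divisor 1);
* minority classes in the training set are upsampled by whole-set
  replication until class proportions are as even as whole copies allow
  (ties resolve to fewer copies);
* the complexity parameter C of the linear classifier is selected from
  {1e-5, …, 1e-1} by validation UAR (ties to the smallest C, i.e. the
  strongest regularization);
* training and validation sets are then concatenated, the statistics and
  upsampling recomputed on that concatenation (it *is* the training set of
  the final phase), and a model retrained reusing the selected C — the
  protocol's wording supports reusing C rather than re-tuning, and that is
  what we do;
* the model predicts the held-out fold and nine bootstrap resamples of it
  (uniform with replacement, same size), giving 3 + 3 × 9 = 30 test
  evaluations per configuration.

The classifier is a linear maximum-margin machine: the standard
box-constrained dual (0 ≤ α_i ≤ C) solved by deterministic dual coordinate
descent with the bias absorbed as an augmented feature; prediction is
sign(w·x + b). Ternary problems (intrinsic pleasantness) are handled
one-vs-one with majority voting, ties broken by declared class order. Any
solver meeting these post-conditions would be acceptable; ours is
implemented in C++ for speed and visits instances in a fixed order, so
training is exactly reproducible.

## Performance measures

Per test set we report the **UAR**, the unweighted mean of per-class
recalls: invariant to class imbalance, 50% for any constant binary
prediction. Because test sets are finite, the relevant chance level is not
100/n_classes but the **empirical chance level**: the smallest achievable
accuracy k/n whose binomial cumulative probability reaches 1 − α (exact
CDF, no normal approximation). We compute it per fold from that fold's test
size and report the across-fold mean as the headline (for the reference
configuration of 889 instances over three participant-balanced folds this
gives 54.78%, matching the printed 54.8% of the source protocol), along
with the pooled-size variant. **diffUAR** is mean UAR minus this chance
level, and a one-tailed one-sample t-test over the 30 UAR values supplies
conventional stars. The nine bootstrap resamples per fold are not
independent observations, so this t-test is anticonservative; treat the
chance threshold, not the stars, as the primary yardstick (our null
calibration test asserts only that the test fires in a minority of
zero-effect runs).

## The synthetic world

The generator emulates exactly the structure the protocol consumes, not the
biophysics of the scalp. Per trial,

```
epoch = gain_p × Σ_checks amplitude(level) · topography ⊗ Gaussian(μ + jitter_t, σ)
        + 1/f^β background + white noise
```

* **class-dependent components** are Gaussian-in-time bumps (default peak
  400 ms, width 80 ms — P3/late-positive-potential territory) with a fixed
  centro-parietal topography and per-level amplitudes;
* **background** is 1/f^β noise (default β = 1, 10 µV RMS) made by shaping
  white-noise spectra with f^(−β/2) and inverse transforming — standard,
  fast, seedable; white sensor noise (default 2 µV) is added on top;
* **participant variability** is a log-normal multiplicative gain on the
  components (sdlog 0.2) and **trial variability** a per-trial latency
  jitter (sd 20 ms) drawn once per trial and applied to all channels, since
  real components shift coherently across the scalp;
* **EMG designs** are generated directly as non-negative rectified-style
  signals (|background| + |white| + burst); a separate raw mode
  (`raw_emg_signal()`) emits 1024 Hz band-limited oscillatory EMG so the
  conditioning chain can be tested in isolation.

Defaults were chosen once, on field-typical grounds: stimulus-locked ERP
components of a few µV against ~10 µV 1/f background is a realistic
single-trial signal-to-noise regime, and the packaged `study1`/`study2`
designs mirror the source studies' cell structures and class imbalances
(2 × 3 cells over 25 participants with novelty ~1:3.5; 2 × 2 × 2 cells over
24 participants with control ~1:3) at reduced per-cell trial counts so they
generate in seconds. The source recordings held hundreds of trials per
participant; nothing in the instance bookkeeping depends on the count, and
the all-trial-average instance counts (150 and 192) are reproduced exactly.

What a green simulation test does **not** establish: absolute decoding
accuracies comparable to the published tables (the original effect sizes in
signal units are unknown, so synthetic UARs are not comparable), robustness
to volume conduction, ocular artifacts, or non-stationary recordings. The
generator also emits no continuous raw EEG; epochs are born segmented.

## Preprocessing choices

* **Filters.** The protocol names only corner frequencies; we use
  zero-phase 4th-order Butterworth responses, applied in the frequency
  domain as the squared Butterworth magnitude — exactly the amplitude
  response of forward-backward IIR filtering, with zero phase error on ERP
  latencies and no edge recursion on short epochs. The EMG chain is
  band-pass 20–400 Hz → rectify → 40 Hz low-pass → resample to 256 Hz
  (linear interpolation onto the output grid; output clamped at 0 against
  microscopic smoothing ripple). The optional EEG chain (0.1 Hz high-pass
  at 24 dB/oct, 30 Hz low-pass at 48 dB/oct) exists for raw-mode inputs
  only — packaged epochs are already band-limited.
* **Artifact rules.** Absolute amplitude (75 µV; gambling variant 110 µV
  and only this rule), range (100 µV), flat stretch (activity below
  0.50 µV for longer than 100 ms, evaluated as run lengths, which equals a
  sample-by-sample sliding window), and step (50 µV between consecutive
  samples). Whether rules apply per channel or jointly was unstated; we
  evaluate per channel and reject on any channel, the strict reading, and
  flag it in reports.
* **EMG outliers.** Per muscle, threshold = 2 × P75 (linear-interpolation
  percentile, quantile type 7 — recorded in the report) of per-trial
  whole-epoch ranges pooled over participants and conditions; a trial is
  removed if its baseline- or post-stimulus-segment range exceeds any
  muscle's threshold, and participants with more than half their trials
  removed lose all trials.

## Feature layout

Per channel: descriptors of the full post-stimulus segment, descriptors of
each sliding window, then six extras — (1 + n_windows) × (n_banks + 1) + 6
features. EEG: 200 ms windows at 50% overlap limited to the first 1000 ms
(9 windows), 8 filter banks log-spaced on 1–40 Hz → 96 per channel, 6144
for the full 64-channel montage. EMG: 400 ms windows over the whole
1500 ms, final window truncated to 1200–1500 ms (7 windows), 10 banks on
20–60 Hz → 94 per region. Numerical choices:

* a "rectangular window with 10% Hanning fade" is read as a raised-cosine
  ramp over 10% of the window length *at each end* (the 10%-total variant
  is selectable via `fade_fraction`);
* filter banks are triangular on the one-sided magnitude spectrum, natural
  log, floor ε = 1e-10 (all features finite for finite input); segments are
  zero-padded to the next power of two before the FFT so short windows
  still resolve the band;
* RMS is computed on the untapered segment (energy should reflect the
  signal), spectra on the tapered one (the taper controls leakage);
* entropy is the natural-log Shannon entropy of the band-restricted,
  normalized magnitude spectrum; zero spectra give centroid 0 and
  entropy 0 by convention;
* the slope regresses log bank amplitude on log center frequency — for
  log-spaced banks this equals an index regression up to the factor
  log(f_hi/f_lo)/(n_banks − 1);
* note that tapering a nonzero *constant* segment injects low-frequency
  energy, so "all banks at floor" holds for the zero signal, not for
  arbitrary constants;
* the full segment is the entire available post-stimulus signal. The
  source protocol's 1500 ms nominal full window is irreconcilable with its
  own −200…+800 ms oddball epochs; we therefore expose epoch length as
  configuration, ship the oddball design with 1000 ms epochs (the minimum
  for the canonical 96-feature layout), and raise an informative error
  when the canonical layout is impossible.

Trial averaging groups consecutive same-class trials per participant in
chronological order (the most reproducible reading; a seeded shuffle is
available but off by default) and discards the remainder `n mod T`.
All-trial averages group by class for classification but by condition cell
when reproducing the published instance counts — only the cell-wise
grouping yields 150 = 25 × 6 and 192 = 24 × 8; both groupings are exposed.

## Known limitations

* No ocular-artifact correction, channel interpolation, or re-referencing:
  inputs are assumed to be cleanly epoched already.
* No mixed-model comparison of configurations; reports stop at per-
  configuration UAR, diffUAR and stars.
* The t-test over bootstrap-inflated test sets is anticonservative (see
  above).
* Stored containers are plain text (JSON + TSV) rather than HDF5, trading
  compactness for portability and diffability; configs are JSON.
* The multi-class scheme (one-vs-one, ordered tie-break) and the fold-role
  rotation (fold i tests, fold i+1 validates) are fixed conventions where
  the protocol is silent.

## A minimal run

```{r example, eval = FALSE}
design <- binary_design(participants = 12, trials_per_cell = 60)
effects <- default_effects(design, scale = 12)
epochs <- baseline_correct(generate_epochs(design, effects, noise_spec(),
                                           seed = 1))
out <- decode_check(epochs, "novelty", avg = 5, seed = 1)
out$report
```

Every number this vignette cites (54.78% chance, the 96/94/6144 layouts,
the 30-evaluation protocol, the 150/192 instance counts, recovery and null
calibration at the reduced design scale) is recomputed by the package's own
test suite (`tests/testthat/test-acceptance.R`) and acceptance script
(`scripts/acceptance.R`).
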
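---
title: "Wavelet phase synchronization and absence-seizure detection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet phase synchronization and absence-seizure detection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdsync)
```

## The problem

Absence seizures in childhood and juvenile absence epilepsy appear on the
scalp EEG as generalized 2.5–5.5 Hz spike-and-wave discharges (SWDs):
high-amplitude complexes that are strongly phase-locked across the whole
10-20 montage.  Global synchronization is the most conspicuous property of
this seizure type, yet the distributions of interictal and ictal
synchronization overlap too much for synchronization alone to detect
seizures reliably.  `swdsync` therefore combines two features per 1-s
analysis window — the global wavelet phase-synchronization index and the
normalized EEG amplitude — in a small k-NN classifier, and re-uses the raw
(non-post-processed) detector output to quantify how *fragmented*
(internally interrupted) each discharge is.

## Phase extraction

The analysis rests on the complex Morlet wavelet
$$\psi(t) = \pi^{-1/4} e^{2\pi i f_c t} e^{-t^2/2},
\qquad
\hat\psi(f) = \sqrt{2}\,\pi^{1/4} e^{-2\pi^2 (f-f_c)^2},$$
whose spectrum peaks at the center frequency $f_c$.  Stretching the wavelet
by a scale $a$ tunes it to the pseudo-frequency $f_a = f_c/a$.  The CWT
coefficient at time $t_0$ is the Riemann-sum discretization of
$$T[s](a,t_0) = \frac{1}{a}\int s(t)\,\psi^*\!\Big(\frac{t-t_0}{a}\Big)dt,$$
evaluated by FFT convolution (`cwt_morlet()`), and the instantaneous phase
is its complex argument.  The $1/a$ normalization is kept as written; any
scale-dependent prefactor cancels in the phase.

Numerical choices:

* **Kernel truncation.** The wavelet is cut at six envelope standard
  deviations ($|t-t_0| \le 6a$ s); the discarded tail holds under $10^{-8}$
  of the wavelet energy.  The FFT path agrees with a direct time-domain
  convolution to better than $10^{-6}$ relative error (tested).
* **Boundaries.** The CWT is computed once over the full continuous
  recording and sliced into windows afterwards; the signal is
  reflect-padded by 1 s per side and the pads discarded.  At the default
  scale ($f_c = 1$, $f_a = 12$, $a = 1/12$) the envelope standard deviation
  is ≈ 83 ms, so 1 s of padding confines edge error to well below test
  tolerances.  Isolated short segments passed to `cwt_morlet()` directly
  get the same reflect padding.
* **Degenerate phases.** Where $|T|$ falls below $10^{-12}$ of the series
  maximum the argument is numerically meaningless; those samples become
  `NA` and are excluded pairwise from all synchronization averages.

## Synchronization indices

For channels $k,l$ the index is the resultant length of the
phase-difference distribution over the window,
$$\gamma(k,l) = \sqrt{\langle \sin\Delta\phi\rangle^2 +
\langle \cos\Delta\phi\rangle^2} \in [0,1],$$
the standard phase-locking value: 0 for a uniform phase-difference
distribution, 1 for perfect locking.  A widely used variant omits the
square root (the squared resultant length); both forms share the endpoint
properties, and the square-root form is adopted here because it is the
standard definition and keeps the index on the scale on which the
detection thresholds (≈ 0.5) and group profiles are interpretable.

The *global* index $\bar\gamma$ averages the $N(N-1)/2$ distinct pairs of
the active subset, and the *channel* index averages one channel's $N-1$
pairs (for topographic displays).  Both divide by the number of terms —
bare sums would leave the range and all reported values inconsistent with
a $[0,1]$ index.

Four electrode subsets are built in (`channel_subset()`): the full `S19`
10-20 montage and the reduced `S12`, `S6` (a practical EEG-headband
layout) and `S4` sets.  The amplitude feature averages over the *active*
subset only: a reduced headset has no access to other channels.

## Windowing, taxonomy and features

Windows are 1 s long at a 0.5-s step (half overlap, emulating a live
stream).  All intervals are half-open `[start, end)`; overlap means
nonempty interior intersection, which makes adjacency at window boundaries
unambiguous.  Relative to each annotated seizure, windows are coded 0
(interictal), 1–2 (leading partial overlaps), 3 (first fully embedded), 4
(interior), 5 (last embedded), 6–7 (trailing partials); codes 2 and 6
require two partial windows at that boundary, which the 1-s/0.5-s geometry
does not always produce (a grid-aligned onset leaves a single leading
partial).  The binary ground truth for testing counts *any* overlap as
ictal.

The amplitude feature is $A_m / A_{\mathrm{ref}}$, where $A_m$ is the mean
absolute value over subset channels and window samples and
$A_{\mathrm{ref}}$ is the same average over a 30-s interictal segment at
the start of the recording (children's EEG amplitude varies several-fold
with age and impedance; normalization makes the feature transferable
across subjects).  If the recording opens ictally, the first seizure-free
30-s stretch is used — a fallback that keeps the definition total.

## Detector

Training rows follow fixed selection rules: ictal rows are fully embedded
windows (codes 3–5) whose $\bar\gamma$ exceeds the 95th percentile of the
interictal $\bar\gamma$ distribution (linear-interpolation quantile, fixed
for reproducibility); partial-overlap windows are discarded from training
(but count as ictal at test time); interictal rows are a seeded uniform
subsample, three per ictal row, because interictal windows outnumber ictal
ones by two orders of magnitude.  Features are standardized by the
training rows' location and scale.

Classification is a plain 10-neighbour Euclidean vote with no distance
weighting.  Two determinism choices are made explicit: distance ties
resolve by training-row order, and vote ties (possible with even $k$)
resolve toward *interictal*, the choice that favours fewer false
positives.  Cross-validation is leave-one-subject-out: each subject is
predicted by a model trained on all others, with the interictal threshold
and subsample recomputed inside each fold (no information from the
held-out subject leaks into its model).

Post-processing relabels any isolated ictal window as interictal, so the
shortest surviving ictal interval is two consecutive windows = 1.5 s
(short epileptiform discharges rarely have clinical correlates).  The
operation is idempotent and never adds ictal time; both properties are
enumerated exhaustively in the tests.

## Metrics and fragmentation

Overlapping decisions are OR-merged: a 0.5-s half-interval is ictal if any
covering window is.  OVR is the percentage of annotated seizure time
covered by the merged ictal timeline; PERR the percentage of non-seizure
time falsely marked ictal; FP counts interictal windows classified ictal
and MT the maximal runs of such windows (FP/MT are counted on window
decisions, PERR on the merged timeline).  Fragmentation of an
abnormal-activity interval is
$$\mathrm{SFRAG} = 100\% - \mathrm{OVR},$$
computed from the detector with post-processing *off* (post-processing
would paper over exactly the interruptions being measured).  The identity
OVR + SFRAG = 100 on shared input is asserted in the tests.  Because
features live on 1-s windows, interruptions shorter than about 0.5 s are
generally invisible and gap durations are blurred by up to a window — the
resolution-limit tests implant 0.25-s gaps and require SFRAG < 5%.

## The synthetic generator

No public absence-EEG corpus with the needed annotations exists, so the
package ships a generator (`sim_config()`, `gen_cohort()`) that emulates
the statistical structure the detector relies on:

* **Background**: per-channel independent $1/f$ (pink) noise at 20 µV RMS
  plus narrowband (Gaussian passband, 1 Hz wide) alpha-rhythm noise around
  10 Hz, doubled on O1/O2.  Modelling alpha as narrowband *noise* rather
  than a sinusoid matters: independent pure sinusoids would be mutually
  phase-locked by construction and would inflate interictal synchronization.
* **Discharges**: a shared cycle — Gaussian-derivative spike plus slow
  half-sine wave — repeated at 3 Hz, broadcast to all channels with ~10%
  gain spread and per-channel time shifts drawn from the configured phase
  jitter (0.3 rad default), scaled to 4× the background RMS, with 0.25-s
  cosine ramps at the edges.  The sharp spike provides the harmonic energy
  at the 12-Hz analysis frequency that makes the discharge visible to the
  phase analysis, which is also why the 12-Hz band maximizes the
  ictal–interictal contrast for 3-Hz SWDs.
* **Schedule**: six seizures per 15-min recording, durations triangular on
  3–20 s with mode 10 s (matching the clinical minimum/maximum/median
  without inventing a distribution family), at least 15 s apart, none
  before 30 s.  Per-subject amplitude scales span a 3× range to exercise
  the amplitude normalization.
* **Fragmentation**: one implanted gap per seizure covering a configured
  fraction of its duration, disrupting the rhythm by cessation
  (discharge → background), spike loss (slow delta persists) or
  desynchronization (per-channel phases randomized) — the three observed
  disruption modes.
* **Artifacts**: short (< 2 s) synchronized epileptiform bursts (2 expected
  per recording) to exercise false-positive behaviour, and frontal blink
  transients (8 expected), which the 12-Hz phase analysis should ignore.

What the generator does **not** emulate: volume conduction and reference
effects (channels are independent rather than weakly correlated, so the
interictal baseline $\bar\gamma \approx 0.4$ is honest but not
clinical), age-dependent spectra, muscle/electrode artifacts of complex
morphology, and drowsiness/vigilance changes.  Passing the recovery tests
therefore demonstrates that the pipeline is correct and sensitive under
the assumed signal structure, not that clinical performance numbers
transfer.

## Study sizes used in the tests

The recovery suites run at deliberately modest sizes chosen as realistic
desk-scale stand-ins: the detection study uses 10 subjects × 15 min × 6
seizures (LOOCV over 10 folds, ≈ 18 000 windows) and requires ≥ 95% of
seizures found, mean OVR ≥ 85% and mean PERR ≤ 1%; the fragmentation study
implants gap fractions 0/10/25/50% into 16-s seizures and requires
recovery within ±10 percentage points.  Smaller shared fixtures (3
subjects × 5 min) back the unit tests.

## Known limitations

* Causal (forward-only) filtering leaves the group delay uncompensated —
  intentional, to keep the pipeline applicable to a live stream; tests
  discard transients explicitly.
* The EDF writer handles whole-second recordings with integer sampling
  rates, one record per second, and encodes at the 16-bit quantization of
  the per-channel data range.
* Fragmentation is a retrospective quantity: it needs externally delimited
  abnormal-activity intervals and raw (non-post-processed) decisions.
* The detector is window-based; seizure onsets/offsets are localized no
  better than the 0.5-s step, and partial windows at seizure edges bound
  OVR away from 100% even for perfect window decisions.
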
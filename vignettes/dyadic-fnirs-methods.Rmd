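---
title: "Methods: dyadic contingency coding and infant fNIRS analysis"
author: "dyadnirs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dyadic contingency coding and infant fNIRS analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadnirs)
```

# Overview

`dyadnirs` implements a complete analysis chain for studies that relate the
quality of mother–infant interaction to the infant's cortical response to
social contingency, measured with functional near-infrared spectroscopy
(fNIRS) over the bilateral posterior superior temporal sulcus (pSTS). The
chain has four scientific components:

1. **Behavioral contingency scoring** — a chance-corrected maternal
   responsiveness index computed from coded event streams;
2. **Maternal touch coding** — duration proportions of seven touch
   categories from 2-s video segments;
3. **Observer reliability** — tolerance time-unit kappa, event-alignment
   kappa, Cohen's kappa, and two-way mixed-model ICC;
4. **fNIRS preprocessing and group statistics** — from raw dual-wavelength
   intensity to baseline-corrected HbO/HbR region-of-interest epochs, then
   time-bin repeated-measures ANOVA, condition difference scores, and
   maternal-predictor regressions.

Because raw recordings of this kind are rarely shareable, the package ships
a synthetic-data generator that emulates the study design with known ground
truth, so every stage is testable end to end.

# The responsiveness index

Coders annotate mutual-gaze episodes and the facial (smile, eyebrow, tongue
protrusion) and vocal behaviors of both partners. The first minute of the
interaction is a warm-up and is discarded; the following four minutes are
analyzed. A maternal behavior is *contingent* on an infant behavior when it
starts within $W = 1000$ ms after the infant behavior's onset; for infant
vocalizations the window extends to 1000 ms after the *offset*, so mothers
who wait for their infant to finish are not penalized. A maternal behavior
starting at exactly the infant onset is not contingent; when several
maternal behaviors fall in one window only the first counts; simultaneous
infant behaviors are each credited separately.

With $C$ contingent maternal behaviors, $I$ infant behaviors, $M$ maternal
behaviors, and $D$ the mutual-gaze duration (ms), the index is

$$ R \;=\; \frac{C}{I} \;-\; \left(1 - e^{-\,M W / D}\right). $$

The subtracted term is the probability that a Poisson process of rate
$M/D$ produces at least one event in a window of length $W$ — the chance
that an unresponsive mother would appear contingent by accident. $R = 0$
therefore means chance-level responding. Note the units: $D$ is kept in ms
and $W = 1000$ ms converts the rate to the one-second window. The package
validates this calibration by simulation: for independent mother and
infant Poisson streams the mean index is statistically indistinguishable
from zero (see `tests/testthat/test-acceptance.R`).

Two conventions were genuinely open and are configurable:

* the window's upper boundary at exactly $+1000$ ms is treated as
  *inclusive* (the onset itself is exclusive, per the simultaneity rule);
* a maternal behavior already paired with one infant event may still be
  the "first" response to a *different* infant event
  (`allow_reuse = TRUE`); disallowing reuse is available behind the flag.

Both streams are restricted to events whose onset falls inside a
mutual-gaze episode, consistent with $M/D$ being a within-gaze rate.
Windows that straddle a gaze-episode boundary are truncated by this
restriction; with realistic episode lengths this is a sub-percent effect,
and the calibration test uses a single full-session gaze episode where the
Poisson null is exact.

# Touch coding

The interaction video is divided into 2-s segments. When several touch
categories occur in one segment, the highest-priority category is coded,
in the fixed order affective > harsh > playful > attention-getting >
instrumental > static > incidental; an untouched segment codes "none".
Each coded segment is assumed touched for its full duration. Category
durations divided by the video duration give the two regression
predictors: overall touch proportion and affective-touch proportion.
Videos whose length is not a multiple of 2 s keep their final partial
segment, weighted by its actual duration — the normalization exists
precisely to absorb slightly different interaction lengths.

# Reliability statistics

* `timeUnitKappa` discretizes both coders' timelines into 1-s units and
  tolerates ±1 unit of timing deviation: a unit agrees if the other coder
  holds the same code anywhere in the tolerance window; otherwise the two
  codes at that unit are tallied as a confusion. With tolerance 0 this
  reduces *exactly* to Cohen's kappa, which the tests assert.
* `eventAlignmentKappa` aligns the two event sequences globally by dynamic
  programming; two events may align only if their onsets differ by ≤ 2 s
  *and* they overlap at least 80 % of the shorter event (the overlap
  referent was unstated in the tradition this follows; the shorter-event
  convention is adopted and exposed). The alignment maximizes aligned
  pairs, with code agreement as tie-break, and unaligned events count
  against a nil code. For up to 8 events the DP is verified against
  exhaustive enumeration of all monotone alignments.
* `iccTwoWayMixed` reads "two-way mixed model ICC" as ICC(3,1) —
  single-rater consistency, $(MS_T - MS_E)/(MS_T + (k-1)MS_E)$ — with an
  absolute-agreement variant ICC(A,1) behind `type = "agreement"`.

These tally conventions are "GSEQ-style": the exact internal conventions
of the classical sequential-analysis software are not fully published, so
the tolerance rule is applied symmetrically and documented here.

# fNIRS preprocessing

Stages run in this order, and the returned manifest records the order and
all parameters of every run:

1. **Looking filter.** A trial is kept only if the infant looked at the
   screen for *more than* 50 % of the trial and *at least* 50 % of the
   brushstroke time (pooled over a trial's strokes). Subjects need ≥ 3
   valid trials per condition.
2. **Channel pruning.** Mean intensity outside 0.09–1 V or
   $20\log_{10}(\mathrm{mean}/\mathrm{SD}) < 0$ dB at either wavelength
   drops the channel.
3. **Optical density.** $OD(t) = -\ln(I(t)/\bar I)$ per channel and
   wavelength (natural-log convention; the extinction table is rescaled by
   $\ln 10$ accordingly).
4. **Motion detection.** Sliding 1-s windows; a window is flagged when its
   range exceeds 0.4 OD or 14 SDs of the channel's first differences (the
   SD referent was unstated; first differences over the whole recording
   are used and documented).
5. **Wavelet correction.** A periodized Daubechies DWT (db2 default) is
   decomposed only down to the detail scale just above 0.15 Hz, so the
   hemodynamic band stays in the untouched approximation; detail
   coefficients more than 0.5 interquartile ranges beyond their level's
   quartiles are zeroed. On a clean slow hemodynamic signal this changes
   the RMS by < 5 % while sharp spikes lose most of their amplitude.
6. **Heart-rate check.** An automated surrogate for visual inspection: a
   channel passes when its smoothed periodogram peak in 1.5–3.5 Hz exceeds
   30× the median power above 1 Hz. Simulated cardiac pulsation yields
   ratios above ~300; channels without it stay below ~15, so the margin is
   wide on both sides. Every decision is logged per channel.
7. **Residual check and trial rejection.** Motion detection is re-run on
   the corrected signal; a trial overlapping a residual artifact on any
   ROI channel (configurable to all channels, or to the trial span only)
   is rejected, and the ≥ 3-trials rule is re-applied.
8. **Band-pass 0.01–1 Hz.** Cascaded zero-phase Butterworth sections
   (2nd-order high-pass, 4th-order low-pass, each run forward–backward),
   numerically safer than a single narrow bandpass at these normalized
   frequencies. 0.1 Hz passes within 5 %; 2.5 Hz is attenuated below 5 %.
9. **Modified Beer–Lambert law.** Per channel the 2×2 extinction system is
   solved with DPF 5.1 and the channel's source–detector distance; molar
   extinction coefficients are the standard Prahl compilation values at
   760/850 nm, shipped in code and swappable. Because OD is referenced to
   the channel mean, concentrations are changes about an arbitrary
   baseline — recovery is therefore exact only up to a per-channel DC
   offset, which is how the round-trip tests compare.
10. **ROI epochs.** ROIs are right = channels {8, 9, 13, 14}, left =
    {23, 24, 28, 29}; an ROI needs ≥ 2 surviving channels. Epochs run 18 s
    from trial onset (six 3-s bins; the window deliberately extends 3 s
    past the 15-s trial into the next baseline — configurable to 15 s) and
    are baseline-corrected by the mean of the final 3 s of the preceding
    12-s baseline (interval unstated in the tradition; configurable).

# Group statistics

`binEpochs` averages the condition-averaged epochs into six 3-s bins.
`rmAnova` runs the classical two-way within-subject ANOVA (condition ×
bin), each effect tested against its subject-by-effect interaction with
uncorrected degrees of freedom (Greenhouse–Geisser is deliberately not
applied by default, matching the uncorrected df convention; the F values
are verified against an explicit sums-of-squares oracle to 1e-10, and the
null type-I rate is calibrated by simulation). `posthocBins` runs paired
t-tests per bin, uncorrected by default with Holm available.
`diffScores` averages HbO over the whole post-stimulus window and
subtracts noncontingent from contingent — negative values mean a larger
noncontingent response. `fitRegression` is ordinary least squares of a
difference score on the five per-dyad predictors (overall touch,
affective touch, sensitivity, responsiveness index, age), with listwise
deletion and an explicit rank check that names collinear predictors.
Difference scores average channels within ROI first, then trials within
condition (the alternative order was unstated; this one is fixed and
documented).

# The synthetic-data generator

`simulateDyad` produces infant behaviors as a homogeneous Poisson process
restricted to mutual gaze, maternal responses as independent Bernoulli
triggers with uniform latency, and spontaneous maternal behaviors as a
second Poisson process. `simulateTouch` draws independent per-segment
categories. `simulateNirs` builds a block design of up to 10 trials per
condition (12 s baseline + 15 s trial, ABBABAAB order starting
contingent), convolves condition boxcars with a peak-normalized
double-gamma HRF (peak 5 s, undershoot 15 s), restricts responses to ROI
channels, adds sinusoidal cardiac (2.5 Hz — an infant heart rate),
respiratory (0.6 Hz), Mayer-wave (0.1 Hz), slow-drift and white noise in
concentration space, forward-projects through the *same* Beer–Lambert
model the pipeline inverts, and injects recording-wide motion events in
OD space (movements hit all channels at once, with per-channel
amplitudes). Per-trial looking proportions are Beta-distributed.

Defaults were chosen once to match the study conditions they emulate:

* sampling rate 7.8125 Hz (typical for the instrument class; the source
  study does not report one);
* HbO amplitudes 0.30 µM (contingent) vs 0.39/0.45 µM (noncontingent,
  left/right), reproducing the reported difference-score magnitudes of
  roughly −0.09 and −0.15 µM and their sign;
* HbR at −1/3 of HbO;
* looking Beta(4, 1.5) and 0.5 motion events/min, which yield ≈ 6.2 valid
  trials per condition — matching the reported retention (6.19/5.87) —
  and a high inclusion rate (the study's additional losses came from
  aborted sessions, which are not simulated);
* motion amplitudes 0.5–1.5 OD, above the 0.4 OD detection threshold, so
  detection performance is measurable against ground truth.

What the generator does **not** emulate: photon transport through tissue
(the optical model is the same linear MBLL in both directions), HRF
variability across infants and regions, serially dependent behavior
streams, coder disagreement beyond code flips, heteroscedastic or
artifact-correlated looking behavior, and aborted sessions. Passing
recovery tests on these simulations therefore demonstrates the pipeline's
internal consistency and calibration — not that real infant data meet the
generator's assumptions.

# Numerical choices and degenerate inputs

* The DWT pads to a power of two by reflection; synthesis is the exact
  transpose of analysis, so reconstruction without thresholding is exact
  to machine precision (a property test asserts 1e-10).
* Motion events shorter than one sample period still affect the nearest
  sample, so ground truth and signal cannot disagree about an event's
  existence.
* An all-one-code reliability table makes kappa undefined; it is returned
  as `NA` with the raw agreement, with a warning. Constant ICC scores and
  zero-variance post-hoc differences are likewise signaled rather than
  silently propagated.
* `I = 0` or `D = 0` makes the responsiveness index undefined and raises
  an error naming the unanalyzable dyad, as does a session with no mutual
  gaze in the analysis window.
* Ties between simultaneous maternal candidates are broken by stream
  order; infant simultaneity groups are defined by exactly equal onsets.

# Problem sizes used in validation

The validation suite sizes its simulations to be decisive yet quick: 1000
random sessions for the detection oracle, 500 dyads for the null
calibration, 1000 null datasets (n = 30) for the ANOVA type-I rate, eight
recordings for artifact detection, and one 200-dyad study for the
end-to-end regression recovery, run on the 8 ROI channels that carry the
analysis. The full-montage generator is exercised separately; restricting
a simulation study to ROI channels changes only runtime, not any analyzed
quantity.

# Known limitations

* SNIRF/HDF5 I/O is not provided; recordings are exchanged through the
  documented wide-TSV + JSON-sidecar dialect.
* The heart-rate check is a spectral surrogate for what was originally a
  visual inspection; its prominence threshold is calibrated on the
  generator's noise model.
* The wavelet correction attenuates but does not remove large artifacts;
  the pipeline relies on the residual check to reject what remains, which
  is why both stages exist.
* The regressions assume linear, homoscedastic effects; with ~50–60
  complete dyads (the realistic retention of such studies) their power
  for small effects is limited, as the original design discussions
  acknowledge.
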
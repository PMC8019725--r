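---
title: "Quantifying Mauthner-cell input dynamics during startle habituation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Mauthner-cell input dynamics during startle habituation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(startletrace)
```

## The system and the measurement problem

The acoustic startle response of larval zebrafish is driven by a pair of
giant hindbrain neurons, the Mauthner cells (M-cells); a single action
potential in one M-cell triggers the short-latency C-bend (SLC) escape,
which occurs 2–12 ms after stimulus onset. The M-cell integrates two
glutamatergic inputs at distinct subcellular compartments: VIII-nerve
afferents on the distal lateral dendrite (LD) and spiral fiber neurons
(SFNs) forming the axon cap around the axon initial segment (AIS). Under
repeated stimulation the escape probability declines (habituates), and the
question of interest is how release dynamics at these two compartments, and
the activity of SFNs, shape the startle threshold and its habituation.

The raw data for such a study are (a) line-scan fluorescence recordings from
genetically encoded glutamate (iGluSnFR, 250 Hz) or calcium (GCaMP, 20 Hz)
indicators, (b) reference Z-stacks used for focal-plane bookkeeping, and
(c) behavioural trial tables (response, latency, direction per fish and
stimulus). `startletrace` implements the full quantification chain for these
three inputs, plus a synthetic-data generator that produces all of them with
known ground truth so that every stage of the chain can be validated by
parameter recovery. None of the quantities asserted in this vignette are
taken on faith: each is recomputed by the test suite or by
`scripts/acceptance.R`.

## From raw fluorescence to dF/F0

Relative fluorescence change is computed as `(F - F0) / F0`, with the
baseline `F0` taken as the mean over a window immediately preceding the
first stimulus. The baseline duration defaults to 0.5 s; the choice is a
convention (any pre-stimulus window estimates the same quantity on
stationary baselines) and is exposed in the configuration (`baseline_window`).
dF/F0 is exactly invariant to multiplicative gain of the detector, which the
tests assert to float precision.

Smoothing is by convolution with a unit-area discrete Gaussian kernel of SD
2 samples by default. A kernel SD in *samples* is one reading of the usual
"filtered with two times the standard deviation" convention; since the
phrase is ambiguous the SD is a configuration knob (`sigma`), and the
default follows the common practice for line-scan data. Edges are handled by
reflection padding, which preserves the baseline level at the trace ends
(zero padding would pull the ends toward zero and bias baseline statistics).

## Motion correction

Two artifacts matter for head-mounted line-scan recordings:

* **Z drift.** A 30-slice reference stack (2 µm increment) is acquired
  beforehand; after each stimulus a single frame is registered to the stack
  by normalised cross-correlation (`select_z_plane()`), i.e. the Pearson
  correlation of pixel intensities against each slice, and the focal plane
  is re-selected as the maximiser. Ties break toward the previously selected
  plane (drift is continuous), else toward the lower index. Registration is
  deliberately exhaustive — 30 correlations per frame is cheap and the
  exhaustive maximiser is its own oracle.
* **X-Y drift.** The spatial profile along the scan line is registered to
  the mean profile of the first 150 time points by integer-sample shifts
  (`correct_xy_drift()`), searching ±`max_shift` (default 5) and flagging
  frames whose best shift exceeds `discard_shift` (default 5). Sub-sample
  interpolation is deliberately omitted: integer shifts recover imposed
  drift exactly in the noise-free case and within ±1 sample at realistic
  noise, and interpolation would smooth the profile it is trying to
  preserve. The discard rule replaces a manual "substantial motion
  artifacts" judgement with an explicit, reproducible criterion; the search
  range extends beyond `discard_shift` so over-limit drift is detected
  rather than clipped.

## Event detection and kinetic fitting

Release events are maximal runs of at least `min_duration` consecutive
samples (default 5, i.e. 20 ms at 250 Hz) above the recording mean plus
`k_sd` standard deviations (default 2). The run-length requirement is the
package's choice: a bare mean + 2 SD threshold fires on ~2.3% of single
Gaussian samples, and five consecutive supra-threshold samples suppress
those false alarms to below one event per one-minute trace (verified by
simulation of the null). Events closer than a 0.2 s refractory window are
merged. Detection is invariant to adding a constant and to positive
rescaling of the trace.

Each extracted event is binned by a factor of 5 and fitted with a
peak-normalised difference of exponentials

$$f(t) = A\,c\,\bigl(e^{-(t-t_0)/\tau_d} - e^{-(t-t_0)/\tau_r}\bigr),
\qquad \tau_r < \tau_d,$$

with $c$ chosen so the waveform's peak equals $A$. "Two exponentials" is
read as this rise/decay form — the standard indicator-transient shape — not
as a sum of two decays; a `double-decay` model is available behind a flag.
The model is averaged over each bin during fitting so that binning
attenuates model and data identically. Because the waveform is symmetric
under relabelling $(\tau_r, \tau_d)$, fitted constants are re-ordered so
that $\tau_r < \tau_d$ always holds. Initial guesses are $\tau_r$ =
time-to-peak / 3, $\tau_d$ = time from the peak to 37% of it, $A$ = the
binned peak; optimisation is Levenberg–Marquardt with positivity bounds and
tolerance 1e-9; non-convergence yields `accepted = FALSE` with an infinite
MSE sentinel. Fit quality is the mean squared error of the binned series
with dF/F0 expressed in *percent*, and fits with MSE above 10 are rejected;
the percent scale is the package's reading of that conventional ceiling (on
a fractional scale an MSE of 10 would never reject anything), and both the
scale and the ceiling are configurable. The reported "time constant" of a
transient is the decay constant $\tau_d$.

Parameter recovery under the study's recording conditions (250 Hz, $\tau_r$
= 10 ms, $\tau_d$ = 100 ms, noise SD 5% of the unit amplitude) is unbiased:
the acceptance suite requires the median recovered $\tau_d$ of 200 simulated
transients to fall within 10% of truth, and observes errors well under 1%.

## Short-term depression and the single-pool model

The generator's stimulus-locked amplitudes follow a single-pool resource
depletion model: available resource $R$ starts at 1, each stimulus releases
a fraction $u$ of it (relative amplitude $= R$ at that moment), and $R$
recovers toward 1 exponentially with time constant $\tau_{rec}$ between
stimuli:

$$R \leftarrow R(1-u) \quad\text{(at each stimulus)},\qquad
R \leftarrow 1-(1-R)e^{-\mathrm{ISI}/\tau_{rec}} \quad\text{(between)}.$$

This is the minimal phenomenological model consistent with homosynaptic
depression — it is a property of the *generator*, used to produce data whose
steady-state amplitude decreases with stimulation frequency; the analysis
functions fit no depression model and the parameters are never claimed to be
estimates of biological quantities. Defaults $u = 0.2$, $\tau_{rec} = 5$ s
produce depression depths comparable to the 40–70% range seen in
glutamate-imaging habituation experiments at 1–4 Hz.

The analysis side mirrors the standard protocol: 60 stimuli at 1, 2 or 4 Hz
(ISI 1 s, 500 ms, 250 ms); per stimulus, the peak dF/F0 in the half-open
window `(onset, onset + min(ISI, 0.5 s)]` (the window length is a package
default — only its upper bound, the ISI, is dictated by non-overlap); peaks
of every five consecutive stimuli averaged per fish and normalised to that
fish's mean over the first five, making bin 1 exactly 1 for every fish and
the curve exactly invariant to per-fish gain; cohort curves average the
per-fish normalised bins (normalising the cohort mean instead would weight
fish by brightness). Intensity–response curves normalise per fish to the
response at the 91.7 dB reference volume of the 81.8–91.7 dB ladder (five
stimuli per intensity); fish with a non-positive reference response are
excluded with a warning rather than propagating an undefined ratio.

## Release threshold and activation probability

The escape threshold in release units is estimated by rescaling per-trial
amplitudes to their maximum and scanning all cuts between consecutive
distinct values for the one that best classifies escape vs. no-escape
(ties resolve to the midpoint of the optimal interval). The scan is
exhaustive, so it is its own oracle; a logistic-regression alternative
(threshold at the 50% point) is available behind a flag. "Maximum" is the
maximum of the supplied amplitudes — a cohort-level reference when trials
are pooled across fish; callers who prefer per-fish maxima can rescale
before calling. Because an accuracy-maximising cut always reports *some*
threshold, an exact binomial test compares the achieved accuracy with the
majority-class base rate; thresholds whose accuracy is compatible with the
base rate (p ≥ 0.05) are flagged uninformative.

SFN activation probability across repeated trials is the fraction of trials
with any post-stimulus sample above the trial's baseline mean + 2 baseline
SDs — a per-trial criterion, unlike event detection's whole-recording
threshold.

## Behavioural statistics

Escape latencies classify as SLC inside the inclusive 2–12 ms window
(inclusive bounds are a convention; the window endpoints are parameters),
LLC for responders outside it, `none` otherwise. Cohort response
probabilities per trial index require complete (non-ragged) cohorts and feed
the exponential habituation fit
$p(n) = p_\infty + (1 - p_\infty)e^{-n/k}$; a non-declining series is
flagged rather than forced through the model, with `k` capped at 10⁴ trials
as the "no habituation" sentinel. Latency distributions are compared with
the two-sample Kolmogorov–Smirnov test, laterality with an exact binomial
test against 0.5, and group contrasts with two-sample/paired t-tests or
one-way ANOVA with Shapiro–Wilk normality screening; Tukey HSD is the
default post-hoc choice, and no multiple-testing correction is applied by
default (a Holm option exists) to match common practice in this literature.
Significance stars follow the `*p<0.05, **p<0.01, ***p<0.001` convention.

## The synthetic generator: what it does and does not emulate

`simulate_session()` produces stimulus-locked difference-of-exponentials
transients with depletion-governed amplitudes, Poisson spontaneous events
(default 4/min, doubling to 8/min under the drug condition, matching the
2–4 releases/min range reported for the AIS and its doubling under
NMDA-receptor blockade), additive white Gaussian noise (default SD 0.04
dF/F0, i.e. 5% of the default 0.8 amplitude), and a slow sinusoidal baseline
drift — any smooth confound suffices to exercise baseline handling, and a
sinusoid is the simplest controllable one. Per-event amplitude variability
at fixed intensity is not documented for this preparation, so it is exposed
as a free lognormal CV (`amplitude_cv`, default 0). One seed drives each
session; all sub-streams derive from it, and every generator is
bit-reproducible for a fixed seed.

`simulate_zstack_frames()` slices a smooth two-blob 3-D object whose
in-plane pattern changes monotonically along z, so that all 30 slices are
mutually distinguishable at the 5% frame noise used in the tests.
`simulate_behavioral_cohort()` draws Bernoulli responses from the
exponential habituation law (or deterministically from supplied release
amplitudes against a threshold fraction), with SLC latencies from a
truncated normal inside 2–12 ms and a configurable rare long-latency
mixture (default 5%).

What the generator does **not** emulate: photobleaching, correlated
(pink/shot) noise, indicator nonlinearity and saturation, non-rigid tissue
motion, inter-fish kinetic heterogeneity, and any biophysical M-cell or
receptor model — the drug condition is a parameter set change (smaller `u`,
doubled spontaneous rate), not a receptor mechanism. Passing recovery tests
on this generator therefore demonstrates correctness of the *computations*,
not robustness to every artifact of real recordings.

## Numerical conventions and degenerate inputs

* Times are seconds; dB values are stored as given; dF/F0 is a fraction
  except inside the fit MSE, which uses percent.
* Time grids must be uniform within 1e-9 relative tolerance; duplicated
  timestamps are reported by row number.
* Zero-variance traces yield no events (with a warning state) rather than
  an error; zero-variance frames and baselines are errors, since the
  requested statistic is undefined.
* `bin_by_factor()` drops a trailing remainder, preserving the mean exactly
  when the factor divides the length.
* Kernel normalisation sets the *sampled* maximum equal to the amplitude,
  so noise-free stimulus-locked peaks equal the generator amplitude exactly
  at any sampling rate; the analytic peak time is reported alongside.
* Problem sizes in the test and acceptance suites (200 transients, 50
  one-minute traces, cohorts of 12–70 fish, 20 seeds for curve ordering,
  1000 null replicates for calibration) were chosen to give stable Monte
  Carlo estimates at interactive runtimes.

## Worked example

```{r example}
prot <- stimulus_protocol(60, frequency = 1)
ses <- simulate_session(prot, kinetic_params(0.8, 0.010, 0.100),
                        depletion_params(0.2, 5),
                        noise_params(gaussian_sd = 0.04),
                        seed = 1, emit = "raw")
dff <- gaussian_smooth(compute_dff(ses$recording), sigma = 2)
peaks <- stimulus_locked_peaks(dff)
round(depression_curve(matrix(peaks, 1), frequency = 1)$normalized_mean, 3)
```

## Known limitations

Integer-sample X-Y correction cannot fix sub-sample drift; continuous Z
correction between frames is not modelled (correction is per-stimulus);
ragged behavioural cohorts must be completed or subset upstream; and the
release-threshold estimator assumes a monotone amplitude–escape
relationship — a non-monotone coupling would need the logistic flag or a
different model.
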
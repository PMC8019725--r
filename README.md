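# startletrace

Quantification of subcellular fluorescence dynamics and behavioural
habituation in the zebrafish Mauthner-cell startle circuit.

## What this package is for

The acoustic startle response of larval zebrafish is commanded by the paired
Mauthner cells (M-cells): one action potential triggers a short-latency
C-bend (SLC) escape 2–12 ms after the stimulus. The M-cell receives
glutamatergic input at two subcellular compartments — VIII-nerve afferents
on the lateral dendrite (LD) and spiral fiber neurons (SFNs) on the axon
initial segment (AIS) — and repeated stimulation habituates the escape.
Studying how these inputs set the startle threshold and drive habituation
requires quantifying three kinds of data:

* **line-scan fluorescence recordings** (glutamate indicator at 250 Hz,
  calcium at 20 Hz) around stimulus trains,
* **reference Z-stacks** (30 slices, 2 µm) for focal-plane bookkeeping,
* **behavioural trial tables** (response, latency, escape direction per
  fish × stimulus).

`startletrace` implements the full analysis chain for all three, for
experimenters running this kind of head-mounted imaging + behaviour assay:

* dF/F0 against a pre-stimulus baseline, Gaussian smoothing (reflection
  padding), Z-plane registration and X-Y line-scan drift correction by
  normalised cross-correlation, binning;
* transient detection at the mean + 2 SD threshold with a run-length rule,
  biexponential kinetic fitting
  `A·c·(exp(-(t-t0)/τ_d) − exp(-(t-t0)/τ_r))` with binning, MSE-based
  quality control and τ ordering;
* stimulus-locked peak extraction, intensity–response curves normalised to
  the 91.7 dB reference, short-term depression curves (five-stimulus bins
  normalised per fish to the first five), SFN activation probability,
  release-threshold estimation by exhaustive accuracy-maximising cut, and
  exponential habituation fits `p(n) = p∞ + (1−p∞)·exp(−n/k)`;
* behavioural statistics: SLC/LLC latency classification, two-sample
  Kolmogorov–Smirnov, exact binomial laterality, t-tests and one-way ANOVA
  with Shapiro–Wilk screening.

Because raw recordings of this kind are rarely deposited, the package ships
a first-class synthetic-data generator (`simulate_session()`,
`simulate_zstack_frames()`, `simulate_linescan_matrix()`,
`simulate_behavioral_cohort()`) that emulates all three data types with
known ground truth — stimulus-locked transients whose amplitudes follow a
single-pool depletion recursion (`R ← R(1−u)` per stimulus, exponential
recovery with τ_rec between stimuli), Poisson spontaneous events, Gaussian
noise, baseline drift, imposed Z/X-Y motion, and Bernoulli escape outcomes —
so every analysis stage is validated by parameter recovery.

## Worked example

```r
library(startletrace)

# one fish, 60 stimuli at 1 Hz, depressing glutamate release at the AIS
prot <- stimulus_protocol(60, frequency = 1)
ses  <- simulate_session(prot, kinetic_params(0.8, 0.010, 0.100),
                         depletion_params(0.2, 5),
                         noise_params(gaussian_sd = 0.04),
                         seed = 1, emit = "raw")
ses$recording
#> trace_recording: AIS (vehicle), 15501 samples x 1 line(s) at 250 Hz, 62.00 s, 60 stimuli, units=raw

dff   <- gaussian_smooth(compute_dff(ses$recording), sigma = 2)
peaks <- stimulus_locked_peaks(dff)
round(depression_curve(matrix(peaks, 1), frequency = 1)$normalized_mean, 3)
#>  [1] 1.000 0.711 0.707 0.684 0.677 0.700 0.698 0.694 0.688 0.683 0.693 0.694
```

Bin 1 is 1 by construction (peaks of stimuli 1–5 normalised to themselves);
the curve then settles near 0.69 — the steady state of the depletion
recursion at 1 Hz with u = 0.2, τ_rec = 5 s. Event detection and kinetics:

```r
ev  <- detect_events(dff)                      # 60 events on this session
v   <- as.numeric(dff$values[, 1])
i0  <- which.min(abs(dff$times - ev$onset_s[1]))
fit_biexponential(v[i0:(i0 + 249)], dt = 1/250)
#> first event: tau_rise 12.4 ms, tau_decay 100.3 ms, amplitude 0.75 dF/F0,
#> MSE 1.99 (percent^2), accepted TRUE
```

The decay constant recovers the generator's 100 ms; the MSE is far below
the quality ceiling of 10. Behavioural habituation of a 70-fish cohort:

```r
beh <- simulate_behavioral_cohort(70, prot, habituation_rate_k = 10,
                                  p_floor = 0.1, seed = 2)
ser <- habituation_probability_series(beh)
fit_exponential_habituation(ser$probability, ser$trial_index)[c("k", "p_floor")]
#> habituation fit: k = 9.7 trials, floor = 0.10
```

A thin command-line wrapper over the same functions lives in
`inst/cli/startletrace.R` with subcommands `simulate`, `preprocess`,
`transients`, `habituate` and `behavior`.

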
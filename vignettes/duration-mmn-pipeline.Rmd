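---
title: "Simulating and analysing the duration mismatch negativity at multiple stimulation rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing the duration mismatch negativity at multiple stimulation rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnpipe)
```

## The scientific problem

The mismatch negativity (MMN) is a fronto-centrally negative deflection of
the auditory event-related potential (ERP), evoked when a rare "deviant"
sound violates a regularity established by frequent "standard" sounds. It is
generated pre-attentively, which makes it attractive as an objective probe
of auditory sensory memory in clinical populations who cannot perform
behavioural tasks — here, children and young adults with CLN3 disease
(juvenile neuronal ceroid lipofuscinosis), compared with typically
developing (TD) peers.

The paradigm this package implements is a passive duration oddball: 1000 Hz
tones of 100 ms (standards, 85%) and 180 ms (deviants, 15%), delivered at
stimulus onset asynchronies (SOA) of 450, 900 or 1800 ms in separate blocks
(2, 4 and 8 blocks of 500, 250 and 125 trials — 14 blocks, 1000 trials per
SOA). Slowing the stimulation rate stresses the decay of the sensory memory
trace, so the MMN is expected to shrink as the SOA grows; a clinical group
with a fragile trace should lose the MMN at slow rates first. The package's
inference layer quantifies exactly that: per-subject MMN amplitudes
(deviant-minus-standard, 200–240 ms window, F3/Fz/F4 composite), mixed
models over group x SOA x condition, planned paired comparisons with JZS
Bayes factors, age trends via bootstrap Spearman correlations, and a
spatio-temporal cluster-based permutation test over all channels and times.

Because no recordings are distributed with this package, a first-class
synthetic module generates full cohorts with the statistical structure the
analysis assumes; every downstream stage is tested against it.

## The synthetic cohort generator

`sample_cohort()` draws subject profiles: ages from truncated normals
(TD 13.9 ± 5.2 y in 6–26; CLN3 16.9 ± 5.5 y in 6–28), CLN3 stages 1:2:3
mixed 9:10:6, and a per-SOA *MMN gain* — a dimensionless multiplier on the
base MMN amplitude of −1.5 µV at Fz (an order of magnitude consistent with
group-averaged duration-MMN waveforms; tunable via `base_amplitude`).

The default `effect_model()` encodes the pattern the pipeline is designed
to detect:

* TD: gain 1 at all three SOAs, increasing by 35% per decade of age;
* CLN3: gain 0.55 / 1.0 / 0.05 at 450 / 900 / 1800 ms, decreasing by 45%
  per decade;
* between-subject lognormal gain jitter (SD 0.25), floored at zero.

`erp_template()` builds the evoked responses: standards get a generic
N1/P2 complex (Gaussians at 100 and 190 ms) with a fronto-central
topography; deviants add the MMN, a Gaussian in time centred at 220 ms
(FWHM 40 ms) whose spatial pattern is a fixed dipolar map, positive
frontally and inverted at the mastoids — so the deviant-minus-standard wave
is negative at Fz and positive at M1/M2, as a supratemporal generator
projects. The map is normalized so the Fz peak equals the injected
amplitude exactly, which makes amplitude recovery testable.

`render_continuous_eeg()` superimposes the event-locked templates on:

* 1/f background noise (spectral synthesis, amplitude ∝ 1/sqrt(f)),
  spatially smoothed over the unit sphere (Gaussian kernel, σ = 0.7 chord
  distance) so neighbouring channels correlate as real EEG does;
* a posterior-dominant 10 Hz alpha oscillation;
* blink transients (Gaussian, ~100–200 µV, prefrontally dominant with a
  steep frontal-to-posterior falloff) at a configurable rate per minute;
* sporadic broad-band movement artifacts large enough to trip the ±150 µV
  rejection rule;
* optionally one corrupted channel per subject (white noise at 10x SD).

Deviant placement uses exact-count randomization — `round(0.15 n)` deviants
per block, none in the first three trials, never two in a row. These
constraints are conventional MMN practice; they also make the deviant
proportion exactly assertable in tests. Sessions begin with a silent
lead-in (the inter-block gap, default 2 s) so the first trial has full
pre-stimulus support, and tones get cosine-squared 10 ms rise/fall ramps
(the ramp shape is a free choice; only the duration is part of the design).

What the generator does **not** emulate: realistic head-model (BEM) forward
projection, heterogeneous ERP morphologies and latencies across subjects,
non-stationary noise, electrode drift and re-gelling artifacts, line noise.
Passing tests therefore demonstrate that the *analysis chain* is correct
and calibrated under plausible signal and noise statistics — not that it
was validated on real patient EEG.

## The preprocessing chain

`run_pipeline()` applies, in order: decimation to 128 Hz → 1–40 Hz
band-pass → bad-channel detection and spherical-spline interpolation →
epoching (−100…800 ms) → two-stage amplitude rejection → baseline
correction (−100…0 ms) → re-referencing to T7 (T8 if T7 is bad) → ocular
denoising. Choices that the design left open:

* **Zero-phase filtering.** All filters are applied with zero phase so MMN
  latency is undistorted. Implementation: the designed IIR filter's squared
  magnitude response is applied in the frequency domain with reflection
  padding — the same response a forward–backward pass converges to, without
  its startup transients, and considerably faster on long multichannel
  records. Designs come from `signal::cheby1`/`cheby2`.
* **Decimation** uses the conventional 8th-order Chebyshev I anti-alias
  low-pass with cutoff at 0.8x the new Nyquist, then keeps every k-th
  sample; event indices are rescaled to the nearest new-grid sample.
* **Band-pass design.** The Chebyshev II band is specified by its stopband;
  placing the stopband edges *at* 1 and 40 Hz would push the transition
  band into the passband and erode slow ERP components by ~10%. The package
  places the stopband edges at half the low edge and 1.2x the high edge
  (0.5 and 48 Hz at the defaults), making 1–40 Hz a true passband; the
  noiseless end-to-end chain then preserves the injected window mean within
  ~2% (tested).
* **Bad channels** are flagged by a robust z-score (> 3) of the log channel
  spread or a mean correlation < 0.4 with the 5 nearest neighbours
  (3–7 supported). The spread is estimated as 1.4826 x MAD so sparse blink
  transients do not masquerade as continuously bad channels, with a floor
  on the between-channel scale: a channel must deviate from the median
  spread by at least a factor of 2 before it can be an SD outlier, so the
  signal-bearing channels of very clean recordings are not flagged merely
  because the array is otherwise homogeneous. If more than 25% of channels
  are flagged, the recording itself is considered degenerate and nothing
  is flagged.
* **Spherical splines** follow the standard Legendre-series construction
  (order m = 4, 50 terms, ridge 1e-5); leave-one-out recovery of a
  spline-generated field is accurate to well under 1% (tested).
* **Rejection.** Stage 1 removes trials with any |V| > 150 µV. Stage 2
  works per condition (role x SOA) within subject: the per-epoch maximum of
  |V| over all channels within 0–500 ms post-stimulus is compared against
  the condition mean + 2 SD. "First 500 ms" is read as post-stimulus;
  intervals are closed on the left, open on the right throughout. Rejection
  is monotone — a trial, once rejected, is never readmitted.
* **Epoch grid.** t = 0 is a grid sample; the window bounds are expanded
  outward to the enclosing grid samples (at 128 Hz: −101.6 to 804.7 ms), so
  the −100…800 ms span is always fully covered.
* **Ocular removal** operates on epoched data. The default mode
  (`"template"`) is a deterministic regression: the blink time course
  measured at the prefrontal channels, restricted to detected blink windows
  (robust threshold on the Fp/AF mean), is projected out of every channel.
  An ICA mode (FastICA, tanh contrast, symmetric decorrelation, seeded) is
  provided: components are removed (at most 2) only if frontally dominant
  (frontal:posterior weight ratio > 3) *and* correlated > 0.7 with the
  blink time course. Where the original description leaves the placement of
  ICA in the chain ambiguous (continuous vs epoched vs averaged data), we
  run it on epoched data; the deterministic mode is the pipeline default
  because it is exactly reproducible and its failure mode (no blinks
  detected → identity) is transparent.

## The measurement and inference layer

Per subject and SOA, the MMN amplitude is the mean of the deviant-minus-
standard difference over the F3/Fz/F4 composite and all samples whose
centres lie in the closed 200–240 ms window. We adopt the deviant-minus-
standard orientation (MMN negative frontally); grand averages weight each
subject equally, the ERP-field norm.

Subjects enter the group analysis if every condition retains ≥ 50 accepted
trials (`min_trials`, scaled configurations lower it in proportion to their
deviant counts), or — failing that — if their frontal-composite waveform
stays within the candidate-group mean ± 3 SD pointwise over 0–800 ms; this
reproduces the cohort bookkeeping rule (e.g. 25 candidates → 4 excluded,
1 retained by exception → 21 analysed, which is asserted as a test).

* **Mixed models.** `fit_lme()` fits
  `amplitude ~ SOA * Condition * Group + (1 | subject)` (REML, treatment
  coding with references SOA 900, STD, TD) via lmerTest, plus a "score"
  variant replacing Group with the continuous CLN3 staging score within the
  clinical group. The literal `(1 + Age | subject)` random term is
  supported but, with a single age per subject, is unidentifiable in
  general; fits under it are returned with their singularity diagnostics
  recorded, and the intercept-only form is the default. Likelihood-ratio
  tests always refit both models by ML, since REML likelihoods are not
  comparable across fixed-effects structures.
* **Planned comparisons** are paired t-tests of DEV vs STD window means per
  group and SOA, two-sided by default (one-sided options give one-sided
  CIs). No multiplicity correction is applied across the three SOAs, by
  design; the raw p-values are reported. Zero-variance differences are
  resolved by continuity (identical vectors → t = 0, p = 1; constant
  nonzero shift → p = 0).
* **JZS Bayes factors.** The default-prior Bayesian t-test with Cauchy
  scale r = 0.707 on the standardized effect. The mixing integral over the
  prior variance g (inverse-gamma(1/2, 1/2)) is evaluated by adaptive
  quadrature (default) or by Monte-Carlo averaging over draws
  g = 1/chi-square(1) — the resampling estimator, 10^6 iterations by
  default. The two agree within a small fraction of a percent (tested
  against each other and against an independent implementation). Evidence
  bands: BF10 > 3 supports the alternative, 1–3 is weak, < 1 supports the
  null.
* **Correlations.** Spearman's rho on midranks with a paired percentile
  bootstrap (default 1000 resamples); "significant" means the 95% CI
  excludes zero. For age trends, the (age, amplitude) pairs of one group
  are concatenated across the three SOAs into a single test, with per-SOA
  linear fits returned for overlay.
* **Cluster-based permutation test.** Per channel x time point, a paired t
  across subjects; suprathreshold points (two-tailed p < 0.05, df = n − 1)
  are clustered under spatio-temporal connectivity — spatial neighbours at
  the same sample, the same channel at adjacent samples — positive and
  negative separately, and scored by summed t (maxsum). The exchangeable
  null for a paired design is the within-subject condition exchange, i.e. a
  random sign flip of each subject's difference wave; each permutation
  contributes its most extreme signed cluster mass, and an observed cluster
  is significant when its mass falls outside the 2.5th–97.5th percentiles
  of that distribution. Monte-Carlo p-values use (b + 1)/(B + 1). Channel
  neighbourhoods come from a Delaunay triangulation of the
  azimuthal-equidistant projection with edges beyond 1.5x the median length
  pruned (k-nearest fallback for degenerate layouts); in the shipped
  32-channel layout every channel has ≥ 2 neighbours and Fz's neighbours
  include F3 and F4.

## Numerical and design choices worth knowing

* The montage is an idealized 32 + 2 unit-sphere layout with 10-20-style
  angles, label-compatible with the standard 32-channel cap; downstream
  code consumes only relative geometry.
* All voltages are µV, all times ms; seeds expand deterministically from a
  single master seed into per-subject and per-stage streams, so a run is
  bit-reproducible from its configuration.
* F3, Fz, F4, T7 and T8 are never simulated as subject-specific bad
  channels (the measurement composite and reference must exist); detection
  still evaluates them like any channel.
* EDF+ I/O is provided (`write_edf`/`read_edf`) with 16-bit physical
  scaling and standard time-stamped annotation lists carrying role, SOA and
  block per trial.

## Problem sizes in the shipped simulation studies

The full protocol (41 + 21 subjects, one-hour sessions, 512 Hz) is what
`run_config()` describes. The package's repeated simulation studies — the
test suite and `scripts/acceptance.R` — use `scaled_run_config()`: 8 + 8
subjects, 2/4/8 blocks of 100/30/15 trials (30/18/18 deviants per SOA),
acquisition directly at the 128 Hz analysis rate, background noise 1 µV,
blink and artifact rates at their defaults. Group sizes and noise were
fixed by a design-time power analysis (planned-comparison power > 99% per
SOA for a full-gain MMN at n = 8) so that qualitative pattern recovery is a
property of the method, not of luck; the fast SOA keeps the largest trial
count for the same reason the full protocol does — closely spaced epochs
share more background-noise autocorrelation, so their average converges
more slowly. Calibration studies (familywise error of the cluster test,
CI coverage of the mixed model and the bootstrap correlation) run at the
sizes stated in their tests (200/100/500 replicates).

## Known limitations

* The synthetic ERP is stationary and identical in morphology across
  subjects up to gain; latency jitter and morphology variation would lower
  real-data SNR relative to these simulations.
* The ICA implementation is a compact FastICA, not a full Infomax/AMICA;
  its contract here is narrow (frontally dominant, blink-locked components)
  and the deterministic regression mode is the default.
* The `(1 + Age | subject)` random slope is honoured syntactically but is
  degenerate with one age per subject; conclusions about age belong to the
  fixed-effects covariate and the correlation analyses.
* The EDF reader targets files written by this package (one continuous
  segment, uniform rate, one annotation signal); it is not a general EDF
  browser.
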
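---
title: "Methods: dual-channel AHI estimation from oximetry and airflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-channel AHI estimation from oximetry and airflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Obstructive sleep apnoea is graded by the apnoea–hypopnoea index
(AHI): apnoeas (≥ 90% airflow reduction) plus hypopnoeas (30–90%
reduction) of at least 10 s, per hour of sleep. Abbreviated home tests
record only a subset of the polysomnographic montage; this package
estimates the AHI from the two channels of a typical type-IV monitor —
pulse-oximetry SpO₂ and nasal-prong-pressure airflow — and quantifies
how well the estimate can replace the reference AHI for screening
decisions.

The pipeline treats the problem as supervised regression: each
overnight recording is summarised by 38 features, a bootstrap-
stabilised filter keeps the relevant and non-redundant ones, and a
support-vector regressor maps them to an AHI estimate. Three models are
built — oximetry-only, airflow-only, and dual-channel — because the
central scientific question is whether the two signals are
complementary.

## Preprocessing

* **SpO₂.** Samples below 50% saturation are physically implausible
  and removed. "Transient deeps" (probe displacement) are detected by a
  slope rule: samples where the 1-s-averaged saturation changes faster
  than 4 %/s, plus the interval enclosed between a fall and the next
  recovery (within 30 s), are invalidated. The signal is then
  anti-alias filtered and decimated to 3 Hz, the conventional rate for
  oximetric feature extraction. The slope threshold is a package
  default (configurable): genuine desaturations evolve over tens of
  seconds at well under 1 %/s, so 4 %/s separates artefact from
  physiology with a wide margin.
* **Airflow.** Sustained malfunction is flagged by two rules:
  flatline segments of ≥ 30 s whose moving 10-s SD falls below 1% of
  the whole-record SD, and rail-saturation runs of ≥ 5 s. The signal is
  low-pass filtered at 1.2 Hz with a zero-phase (forward–backward)
  fourth-order Butterworth filter — zero phase so event morphology is
  not displaced in time — and decimated to a 5 Hz analysis rate. 5 Hz
  keeps everything below the 1.2 Hz cut-off (Nyquist 2.5 Hz) while
  making the quadratic-cost features tractable on full nights.
* **Duration gate.** Recordings with less than 4 h of valid signal on
  either channel after cleaning are rejected (the bound is inclusive:
  exactly 4 h passes). Invalid stretches are bridged by interpolation
  for filtering only; they stay flagged and never count towards valid
  duration, and all per-hour indices divide by valid recording time.

## The feature battery

Per channel (prefix `spo2_` / `af_`):

| family | features | notes |
|---|---|---|
| time moments | M1t–M4t | mean, unbiased variance, skewness, kurtosis (not excess) |
| spectral | M1f–M4f, SE, MF, WD, MA, mA, PR | computed on the band-restricted Welch PSD |
| non-linear | SampEn, CTM, LZC | irregularity, variability, complexity |
| clinical | ODI3, ODI4, Sat_MIN, CT90 (SpO₂); RDI (airflow) | events per valid hour |

The OSA-related bands are 0.014–0.033 Hz (SpO₂) and 0.025–0.050 Hz
(airflow): recurrent respiratory events impose an amplitude modulation
with periods of roughly 30–70 s, which is where the discriminative
spectral power sits. The Welch estimate uses 512-s Hann segments with
50% overlap and an FFT zero-padded to ≤ 1 mHz resolution — the SpO₂
band is only 19 mHz wide, so a coarser grid could not resolve it.
Spectral entropy is normalised by `log(N)` over the in-band bins
(0 = single line, 1 = flat); the Wootters distance
`arccos(Σ√(pᵢuᵢ))` measures disequilibrium against a flat in-band
spectrum; relative power divides in-band power by total power
excluding the DC bin.

Non-linear parameters follow the conventions of the prior single-
channel literature rather than being re-derived here: sample entropy
with `m = 1`, `r = 0.25·SD`, computed per 20-min epoch and averaged
(an exact whole-series mode exists; epoching bounds the quadratic
template count on ~10⁵-sample nights — internally an
`O(n log n)` counting scheme is used and verified against the direct
`O(n²)` count); CTM radius 1 %SpO₂ for oximetry and `0.25·SD` for
airflow; LZC by median binarisation and LZ76 exhaustive-history
parsing normalised as `c(n)·log₂(n)/n` (implemented via the
longest-previous-factor decomposition of a suffix array, and verified
against a direct definitional parser).

Desaturation events (ODI3/ODI4) are falls of ≥ 3%/4% below a running
baseline — the maximum over the preceding 120 s, frozen during events —
sustained for ≥ 10 s, merged when separated by < 10 s, and terminated
on recovery to within 1% of baseline. Airflow events compare a moving
RMS amplitude envelope (4-s window, one breathing cycle) against a
120-s local reference (mean envelope outside events): runs below 70%
of the reference lasting ≥ 10 s (after compensating the envelope
window's smearing) are events, classified apnoea when the envelope
stayed below 10% for ≥ 10 s.

The 21/17 split of the default registry (airflow omits `M1t`, which is
≈ 0 for an oscillatory signal, and `Sat_AVG` is the oximetry `M1t`
under another name, so it is not duplicated) reconstructs the
conventional feature counts; the registry is fully configurable and
`extract_features()` honours any subset.

## Feature selection

FCBF measures both relevance and redundancy by symmetrical uncertainty
`SU(X,Y) = 2·I(X;Y)/(H(X)+H(Y))` on discretised variables. The target
coding is the 4-class OSA severity of the reference AHI; features are
binned by Fayyad–Irani MDL against that target (a feature with no
MDL-approved cut collapses to one bin and has SU = 0). One FCBF pass
ranks features by relevance and discards any feature predominated by a
kept one (`SU(fᵢ,fⱼ) ≥ SU(fⱼ,target)`). To remove dependence on the
particular training sample, the pass is repeated over 1000 bootstrap
replicates (patients resampled with replacement, rediscretised per
replicate); a feature's significance is its selection count and the
selection threshold is the mean count over the whole input set. The
threshold-on-mean-count reading of "average relevance" is the package's
interpretation; an alternative (mean SU) exists and is deliberately not
the default.

## AHI regression

An ε-insensitive support-vector regressor with Gaussian kernel
`k(a,b) = exp(−‖a−b‖²/(2σ²))`. Conventions that matter:

* `σ` is the kernel *width*; it is mapped internally to the solver's
  `gamma = 1/(2σ²)` (a classic source of drift between
  implementations).
* Features are z-scored with training constants before the kernel —
  without this, a single large-scale feature (e.g. M2f) would dominate
  the distance and the printed σ magnitudes would be meaningless. The
  target stays on the raw AHI scale.
* `ε = 0.1` events/h by default (configurable); the grids are
  `C ∈ 10⁻³…10⁴` and `σ ∈ {10⁻²…10³}` coarse plus
  `{20, 50, 100, 150, 200, 250, 300, 500}` refined around 10².
* Model selection is leave-one-out cross-validation on the training
  set, scored by the intraclass correlation between actual and
  LOO-predicted AHI; ties resolve to the smaller `C`, then smaller
  `σ` (preferring the less complex model). Negative predictions are
  clamped to 0 since the AHI is a rate.

## Evaluation layer

The ICC is the two-way, single-measure, **absolute-agreement**
coefficient (ICC(A,1)): agreement between an estimate and a reference
is an absolute question — a perfectly correlated but offset estimator
must be penalised. A consistency variant (ICC(C,1)) is available via
the `type` argument, but absolute agreement is the default and the one
used throughout. Bland–Altman limits use the unbiased SD and
±1.96; the Mountain curve folds empirical percentiles at the median.
Cohen's κ is unweighted; binary metrics use the textbook definitions
with undefined branches (e.g. LR+ at 100% specificity) returned as
`Inf`/`NaN` rather than silently dropped. The AUC is the exact
Mann–Whitney probability (ties ½), which equals the trapezoidal area
under the empirical ROC curve. Confidence intervals are percentile
bootstrap, B = 1000, resampling patients. Severity classification uses
raw (unrounded) estimated AHI values against the 5/15/30 boundaries.

The triage calculator mirrors a deployment protocol: estimated No-OSA
patients are followed up and estimated severe patients treated
(conservative; avoidable studies = No-OSA + severe columns of the
confusion matrix), optionally also treating estimated moderate cases
(extended). Collop-style feasibility thresholds convert a pre-test
probability (cohort prevalence) and a 95% post-test target into the
minimum LR+ a portable test must exceed.

## The synthetic PSG generator

Real recordings cannot ship with the package, so every stage is
validated on simulated nights with known truth. The generator
reproduces the features of real data that the pipeline actually
consumes:

* breathing as a 0.25 Hz oscillation with slow amplitude modulation;
* respiratory events placed by a renewal process (exponential gaps
  rescaled to fit without overlap, ≥ 10 s apart) so the realised count
  equals `round(target_AHI × sleep_hours)` exactly; durations
  log-normal with median 22.4 s, truncated to [10, 90] s; 20% apnoeas
  (drop ≥ 90%) and 80% hypopnoeas (drop 30–90%);
* desaturations lagging each event by 15–30 s, falling linearly over
  the event and recovering exponentially (τ = 15 s), with depth
  3–12% coupled linearly to event duration (longer → deeper, plus
  jitter) — this creates the learnable SpO₂↔airflow relationship the
  dual-channel model exploits;
* baseline saturation 94% with slow drift, Gaussian sensor noise,
  0.1% quantisation; 450-min recordings with 87% sleep efficiency;
* injectable artefacts: SpO₂ spikes below 50% and airflow flatlines.

The ground-truth AHI divides by simulated *sleep* time while every
downstream index divides by valid *recording* time; the resulting
systematic underestimation is intentional — it reproduces the known
bias of recording-time indices and is exactly the kind of distortion
the regression stage must learn around.

What the simulator does **not** model: arousals and sleep staging,
body-position effects, central or Cheyne–Stokes event morphology,
pulse-rate information, and realistic inter-patient variability of
breathing waveform shape. Passing tests therefore demonstrate that the
pipeline recovers a known signal-to-AHI mapping under controlled
conditions, not clinical-grade accuracy on patients.

## Numerical and design choices

* Filtering is zero-phase and applied about the signal mean, so
  startup transients stay proportional to the fluctuation rather than
  the DC level; cleaning is idempotent (a `processed` flag prevents
  double filtering).
* Decimation halves the rate (0.45-Nyquist guard filter) until within
  a factor 4 of the target, then applies the prescribed cut-off and
  resamples onto the exact output grid.
* Degenerate inputs: zero-variance series give skewness/kurtosis 0
  with a `degenerate` flag; SampEn with no template matches returns a
  flagged `NaN` and the recording's row is rejected; constant features
  are dropped at standardisation with a warning; single-class
  bootstrap resamples are redrawn and counted.
* FCBF relevance ties break by canonical feature order (stable);
  severity boundaries are half-open (`[5, 15)` etc.) and applied to
  raw estimates.
* Tests and the acceptance script simulate at the analysis rates
  (3 Hz SpO₂, 5 Hz airflow) and use 245–450-min nights; these sizes
  are the package's choice of test conditions — the generator defaults
  remain the nominal device rates (75/250 Hz) and study-length nights.

## Known limitations

* The 21/17 feature registry is a reconstruction of conventional
  counts; other plausible registries exist and are supported via the
  `registry` argument.
* The MDL discretisation makes bootstrap FCBF O(B · p · n log n);
  B = 1000 on a ~100-patient table takes tens of seconds, which is the
  dominant selection cost.
* ICC values on real data depend on the (unnamed in the literature)
  ICC variant; third-decimal agreement with published values is not
  guaranteed for that statistic.
* The airflow event detector is envelope-based; it does not implement
  manual scoring rules (no flow-shape or desaturation/arousal linkage
  for hypopnoeas), so its RDI underestimates sparse, shallow events by
  design.
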
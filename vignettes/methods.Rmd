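---
title: "ST-segment morphology and recurrent-network risk stratification: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ST-segment morphology and recurrent-network risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After a non-ST-elevation acute coronary syndrome (NSTE-ACS), clinicians must
decide quickly which patients face a high risk of cardiovascular death within
the following year. Conventional risk scores combine demographics, history and
laboratory values; continuous Holter ECG recorded in the first hours after
admission carries additional prognostic information in the fine structure of
the ST segment — the interval between the end of the QRS complex and the
T wave, whose level and slope reflect myocardial ischemia — including changes
too small to see by eye.

`strisk` implements a complete pipeline for this problem:

1. **Preprocessing** of a single-lead 128 Hz ECG: 5-minute segmentation,
   baseline-wander removal, wavelet denoising, signal-quality gating,
   wavelet/derivative-based beat delineation, R-amplitude normalization.
2. **ST morphology quantification**: for each retained beat, 16 samples
   centred on the midpoint between the S-wave and T-wave labels are projected
   onto an orthonormal polynomial basis (Gram–Schmidt on monomials at 16
   equispaced points — a discrete Legendre-style basis). Coefficient 1 is the
   ST level (exactly 4 × the window mean on 16 points), coefficient 2 the
   slope; higher orders capture curvature and, at 128 Hz, mostly noise, so
   only the first two are kept. Each component is normalized per patient by
   its SD over the full first-day series.
3. **Risk models**: a no-intercept L2 logistic regression on seven history
   features (age, sex, smoking, hypertension, diabetes, prior MI, prior
   angiography); a logistic regression on the mean and SD of the first two
   coefficients over the first 50 clean beats; a 2–13–1 Elman recurrent
   network over the same 50-beat window; and a two-level ensemble
   `Y = sigmoid(w1 Y_RNN + w2 Y_LR)`. Without bias terms anywhere the
   ensemble has 26 + 169 + 13 + 7 + 2 = 217 trainable scalars.
4. **Evaluation**: stratified 80/20 bootstrap (the event fraction held fixed
   in both halves each round), mean test AUC with Hanley–McNeil confidence
   intervals, upper-quartile Cox hazard ratios at 1-year/60/30/14-day
   horizons with administrative censoring at the horizon, two-category and
   category-free net reclassification indices, Kaplan–Meier curves, and
   paired t-tests across rounds.

A synthetic ECG/cohort generator makes every stage testable without clinical
data.

## The synthetic world

The generator states one fixed world; its defaults are not tuned per test.

**Beats.** A schematic template at 128 Hz: truncated-Gaussian P and T waves,
piecewise-linear QRS, and a strictly linear ST region
`st_level + st_slope * (k - centre)` that covers the 16-sample extraction
window with margin for ±3-sample delineation error. The S-to-T-label span is
25 samples, inside the 16–32 retention rule. Default heart rate is 55 bpm so
the ST–T complex occupies under half of the beat period — a property the
baseline estimator needs (below). Per-beat ST level/slope jitter, white
noise, and 0.3 Hz sinusoidal wander are optional. This is a test harness,
not a physiological simulator: no rhythm variability, no QRS morphology
change, one lead, fixed RR.

**Cohorts.** Seven history features with prevalences typical of an NSTE-ACS
trial population (median age 63, 35% female, 73% hypertension, ...), optional
TIMI risk score (27/53/20% low/moderate/high), LVEF and BNP. Each patient has
an AR(1) series of per-beat ST level and slope with patient-specific
amplitude (`jitter`, lognormal) and autocorrelation (`rho`, uniform on
(0, 0.9)). The *irregularity latent* is the SD of first differences of the
level series, standardized across the cohort — irregular (jumpy) ST series
mean high risk. Survival times are exponential proportional hazards on
`history_effects . x + st_irregularity_effect * z`, administratively censored
at one year, with the baseline hazard calibrated by root-finding so the
expected event fraction equals 3.4%. The default effect sizes were fixed
once so that the history-only latent discriminates at AUC ≈ 0.66–0.70
(matching the reported discrimination of history-only models in this
population) and the ST effect at 1.5 log-hazard per SD.

A green test on this world establishes that the pipeline recovers what was
planted and that the statistical machinery is correct. It does *not*
establish clinical performance: the generator matches marginal prevalences
and the event rate, not the joint distribution of any real cohort.

## Numerical and statistical choices that needed deciding

**Baseline removal.** The classic two-pass running-median recipe fails in
this world, for a provable reason: with ST spans of 16–32 samples the
elevated ST–T stretch is ~45% of the beat period, and a 0.3 Hz, 0.2 mV
wander sweeps several tenths of a mV within any window long enough to span a
period, so the window median cannot separate a ~0.1 mV ST shift from wander.
`remove_baseline()` therefore keeps the 200 ms median pre-filter (robust QRS
suppression) but tracks wander with a moving average whose window is locked
to the detected beat period (autocorrelation of the squared derivative;
fallback 1.1 s). Averaging over exactly one period turns the beat's
contribution into a constant DC offset, and four passes track a 0.3 Hz
sinusoid to ~1%. The first and last window at each edge are filter
transients. The beat-shape DC is removed along with the baseline; every
downstream use (correlation recovery, per-patient SD normalization,
model fitting) is invariant to that constant.

**Wavelet denoising.** Daubechies-4, 4 levels, soft thresholding. The
universal threshold over-shrinks QRS detail badly enough to *increase* RMS
error on the synthetic template, so the per-level Donoho–Johnstone hybrid
SURE threshold is used instead (noise scale from the finest-level MAD).

**Quality index.** An agreement SQI: F1-style one-to-one concordance (150 ms
tolerance) between a conservative amplitude R-detector and a liberal
derivative-energy detector; keep threshold 0.8. Clean records score ~1,
flatline 0, broadband noise well below 0.8 because the two detectors fire in
unrelated places and in very different numbers.

**Basis construction.** Householder QR of the monomial Vandermonde matrix on
scaled abscissae, signs fixed positive — mathematically the Gram–Schmidt
basis, numerically orthonormal to machine precision (classical Gram–Schmidt
on raw 0..15 monomials is meaningless above degree ~10 in double precision).
The constant column is snapped to exactly 1/4 so `c1 = 4 * mean` holds to
the last bit. Sample (n−1) SDs everywhere. Normalization SDs come from the
full first-day series while summary features come from the 50-beat window —
the only reading under which the SD features are informative. Zero-SD
components get divisor 1 and a flag.

**No-intercept logistic fits.** The design is centred on training column
means before the IRLS ridge fit; without this, a no-intercept model on
all-positive features with 3% prevalence pushes every weight negative just
to reproduce the base rate. The centres are data statistics like the min-max
scaling constants, not model parameters. The ridge penalty is chosen by
stratified 3-fold CV over `10^seq(-3, 3)` maximizing validation AUC, with a
mid-grid fallback when folds are single-class.

**RNN training.** The published description fixes only the architecture
(2 input, 13 tanh hidden with full recurrence, 1 sigmoid output, no biases).
Everything else was open and was settled by what actually trains at desk
scale: full-batch gradient descent with classical momentum 0.9, learning
rate 0.15, a fixed 100-epoch budget (an inner validation split holds ~3
events at this scale and is pure noise as a stopping signal), class-weighted
cross-entropy (a pairwise logistic ranking loss is also implemented),
gradient-norm clipping at 5, and a leaky-integrator initialization
`W_rec = 0.6 I + U(-0.05, 0.05)`, `W_in ~ U(-0.3, 0.3)`, so the final
hidden state exposes window-level statistics before any training. Training
is bit-reproducible given (data, seed).

**Ensemble stacking.** Naive same-data stacking over-weights the RNN, whose
in-sample outputs separate the training classes almost perfectly, and a
small stacking holdout (a quarter of a 3%-event training set holds 2–7
events) estimates the two weights as pure noise. The combiner is therefore
estimated by two-fold cross-fitting: each half of the training set is scored
by sub-models trained on the other half (reduced epoch budget — the fold
models exist only to calibrate two scalars), the two weights are fitted on
the pooled out-of-fold predictions, and the final sub-models are refit on
the full training set. Prediction uses the formula
`sigmoid(w1 Y_RNN + w2 Y_LR)` exactly.

**Bootstrap conventions.** Per-stratum train size `round(0.8 * n)` (this
reproduces a 3,516-patient train set from 4,395 patients with 149 events);
per-round seeds derived from the master seed by a counter; rounds eliminated
for a horizon when the test set has fewer than two events by that horizon or
the Cox fit fails, with a loud warning above 5% eliminated; 75th percentile
by linear interpolation; ties at the cutoff go to low risk; external cutoffs
truncated (toward zero) to one significant digit.

## A limitation found and kept

At the desk scale exercised here (n = 1000, 3.4% events, so ~27 events per
training set) the four-feature ridge logistic on ST summary statistics is a
more statistically efficient learner than the 208-weight recurrent network,
in every variant of the synthetic world we examined. Mean held-out AUCs
therefore order history-LR (~0.59) < ensemble (~0.66) < history+ST-LR
(~0.76): the ensemble beats the history model by far more than 0.05, but
does **not** overtake the history+ST summaries model, whereas the source
analysis (trained on 119 events) reported the ensemble ahead by +0.009. The
corresponding acceptance check is implemented as stated and left failing;
no threshold was moved. The finding is itself informative: the temporal-
information advantage of the recurrent model is an asymptotic one that a
desk-scale event count cannot resolve.

## Known limitations

- The delineator is a simplified template-aware detector; it meets the
  ±2/±3-sample accuracy contract on clean synthetic beats but is not a
  general-purpose clinical delineator.
- The baseline estimator assumes quasi-periodic beats (it locks to the
  dominant RR); heavy arrhythmia would degrade it.
- The generator has fixed RR within a record and plants risk only through
  history covariates and ST irregularity.
- Multivariate Cox adjustment is supported (`cox_hr(covariates = ...)`) but
  the synthetic TRS/LVEF/BNP are drawn independently of the hazard, so
  adjusted HRs on synthetic cohorts are not scientifically meaningful.
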
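---
title: "Deriving a voice-based MCI discrimination index: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving a voice-based MCI discrimination index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcidi)
```

## The problem and the data model

Subjects are recorded in two states: a *calculation* state (serial
subtraction of 7 from 100, answers spoken aloud, about five utterances
per subject) and a *reading* state (the printed sequence of correct
answers read aloud, twice). An acoustic front end — outside this
package's scope — turns each utterance into a vector of p numeric
prosodic functionals. The package consumes the resulting long-format
table, one row per (subject, state, utterance).

The working hypothesis is that cognitive decline makes the dual task
harder, and that the added load changes prosody during calculation
relative to the subject's own reading baseline. The object of analysis
is therefore the **feature difference**: per subject and feature, the
calculation-state mean minus the reading-state mean. Differencing
removes the subject's baseline (and any subject random intercept)
exactly, which is what makes a between-subject comparison of
within-subject change meaningful.

For screening, each feature is modelled at the utterance level with a
Gaussian random-intercept model

$$f_{ikp} = (\beta_{0p} + b_{ip}) + \beta_{1p}\, s_{ik} + \epsilon_{ikp},$$

where $s_{ik}$ indicates the calculation state, $b_{ip}$ is a
per-subject intercept and $\beta_{1p}$ is the state effect. Averaging
is deliberately *not* done at this stage: the repeated utterances are
the information the mixed model exploits.

## The pipeline and its tunables

| Stage | Parameter | Default | Why |
|---|---|---|---|
| State-effect screen | significance level | 0.01 | permissive per-feature filter; later stages prune further |
| MMSE filter | absolute Pearson r threshold | 0.15 (strict >) | keeps features whose *change* tracks cognition |
| AUC ranking | features kept | number of training subjects | keeps the selected-difference covariance full rank for PCA |
| PCA | cumulative explained-variance target | 0.80 (inclusive) | aggregates near-duplicate acoustic functionals |
| Lasso | repeats averaged | 20 | stabilizes against CV fold-split randomness |
| Lasso | folds per repeat, penalty rule | 5, min. mean binomial deviance | conventional |
| Threshold | BER mode | arithmetic mean | see below |
| MMSE cutoffs | healthy / MCI / CD | ≥28 / 24–27 / ≤23 | standard clinical practice; CD merged into MCI |

All of these live in one `pipeline_config()` object that is echoed, with
an MD5 hash and the seed, into every artifact the pipeline writes.

### No multiple-testing correction at stage 1

The 1% level is applied raw, per feature. That is intentional: the
screen is a filter, not an inferential claim, and with thousands of
acoustic functionals a corrected threshold would defeat its purpose.
The cost — about 1% of null features surviving stage 1 — is quantified
by a calibration test in the suite.

### Inference in the per-feature mixed model

The model is fitted by maximum likelihood. The likelihood is profiled
analytically down to the variance ratio $\rho = \sigma_b^2/\sigma_e^2$
(given $\rho$, the GLS coefficients and both variances are closed-form
from per-subject sufficient statistics), and $\rho$ is optimized in one
dimension. Estimates agree with `lme4::lmer(REML = FALSE)` to ~1e-7
(tested against it); the custom path exists because screening fits the
model once per feature, and thousands of features times a generic
mixed-model fit is the pipeline's only real bottleneck. The Wald
statistic for $\beta_1$ is referred to a t distribution on
$N - n_{\mathrm{subjects}} - 1$ degrees of freedom (the within-subject
residual df), so that in the balanced one-row-per-state design the test
reduces exactly to the paired t-test. When the between-subject variance
is estimated at its zero boundary the boundary fit is returned with a
warning — the p-value remains valid as the model degenerates to ordinary
regression.

### AUC orientation

Single-feature ranking uses the direction-agnostic
$\max(a, 1-a)$ of the rank-based (Mann–Whitney) AUC, because a feature
whose difference *decreases* with impairment is exactly as useful as one
that increases; raw orientation is available via `orient = FALSE`. Ties
in the ranking are broken by ascending feature index so the selection is
reproducible. The tie-break and the strict inequality at the correlation
threshold are choices this package fixes; nothing in the problem forces
them.

### PCA conventions

PCA is computed on standardized differences (correlation-matrix PCA) by
default: acoustic functionals mix units (Hz, dB, dimensionless shape
statistics), and covariance-matrix PCA would let the largest-unit
feature dominate. `scale = FALSE` switches to covariance PCA. The
retained component count m is the smallest with cumulative explained
variance ≥ the target; equality is detected with a 1e-9 absolute
tolerance so that spectra hitting the target exactly in real arithmetic
(e.g. 4 of 5 equal eigenvalues at a 0.80 target) land on the inclusive
side rather than being lost to floating-point rounding. Verification
cohorts are centred and scaled with the *training* parameters and only
rotated — never re-fitted.

### The balanced error rate, and why it is not a harmonic mean

The decision threshold minimizes the balanced error rate over the
midpoints between consecutive sorted training scores (plus the
endpoints), predicting MCI at scores ≥ τ. The BER is sometimes described
as the harmonic mean of the false-positive and false-negative rates, but
the harmonic mean $2ab/(a+b)$ is degenerate as an objective: predicting
everyone healthy zeroes the false-positive rate and hence the harmonic
mean, so literally minimizing it always returns a boundary threshold.
Any non-trivial interior threshold must have minimized something else.
The package therefore defaults to the standard arithmetic-mean BER,
$({\rm FPR} + {\rm FNR})/2$, and exposes the harmonic variant via
`mode = "harmonic"` for completeness. Among ties the smallest candidate
threshold is returned.

### Coefficient averaging

Each lasso repeat re-draws the stratified CV fold assignment — the
stated source of run-to-run variation — and the per-repeat coefficient
vectors (unpenalized intercept included) are averaged arithmetically on
the fitted scale, rather than refitting on an averaged support. The
averaged coefficients are what enter the index. A property test checks
that the variance of the averaged coefficients shrinks as the repeat
count grows. With a single retained component, `glmnet` (which requires
two predictor columns) receives an additional constant-zero dummy column
whose coefficient is identically zero and is dropped.

## The synthetic world

`draw_cohort()` generates the stated world the acceptance suite runs in:

* 198 subjects per training cohort, 150 healthy / 48 MCI (the single
  cognitively-diseased subject of the motivating cohort is merged into
  MCI, which is why the default MCI fraction is 48/198);
* MMSE drawn per group (healthy: mean 29.6, SD 0.6; MCI: mean 25.9,
  SD 1.0, matched to the cohort summaries), rounded and — in the default
  strict-cutoff mode — clamped into the clinical ranges so labels and
  scores are mutually consistent;
* calculation-utterance counts `max(3, round(Normal(5.39, 1.21)))`, two
  reading rows per subject;
* per-feature subject random intercepts (SD 1), residual noise (SD 1),
  and three feature roles: pure noise, a state effect only
  (standardized β₁ = 0.8, random sign), and a state effect whose
  magnitude grows with MMSE deficit, γ per point below 30.

The MMSE-link slope default γ = 0.14 was **calibrated once**, by
simulation at the default cohort size, so that the planted features'
single-feature difference AUCs centre on the 0.63–0.70 band reported for
individually selected acoustic features — individually weak, jointly
informative. It was frozen before the acceptance suite was first run and
has not been revisited. Default fractions (25% state-only, 12.5%
MMSE-linked of p = 160 features) are a scaled-down stand-in for the
motivating study's 15,440-feature panel, of which roughly 80% passed the
state screen and a small minority carried cognitive signal.

One seed governs a cohort draw end to end (a single RNG stream consumed
in fixed order, rather than per-subject derived sub-streams — equally
deterministic, with no seed-arithmetic collision risk). Passing a
previous cohort's `truth` as `world =` reuses the feature-level
parameters so verification cohorts consist of new subjects measured on
the *same* features, which is what out-of-population verification means
here.

**What the generator does not emulate** — and hence what a green test
does *not* establish: recording-environment and venue shift between
cohorts, demographic confounding (age, sex), non-Gaussian feature
distributions, and any dependence of utterance counts on cognition.
Synthetic verification cohorts share the training population's
distribution, so verification accuracy in this package's examples is
substantially higher than real out-of-population verification would be;
the motivating study saw accuracy drop from 0.90 (training) to ≈0.6–0.7
(verification), and nothing here contradicts that experience. Feature
intercepts are drawn independently across features by default; an
optional within-block equicorrelation (`intercept_block_cor`) exists
because intercept correlation is what gives PCA non-trivial structure in
reading-state levels, though the planted MMSE link already correlates
the *differences* the pipeline actually aggregates.

## Cross-validation and leakage

`kfold_cv()` refits the **entire** pipeline — screening included — on
each fold's training subjects and applies the frozen result to the
held-out subjects. Running feature selection once on the full data and
cross-validating only the classifier would leak the held-out subjects'
labels into the feature set; the suite contains a test that corrupts
held-out rows and demands a bit-identical fold model. Stratified fold
draws are seeded; a draw whose training partition lacks a class is
re-drawn (logged). Pooled metrics are reported alongside per-fold means;
with k = n the scheme is leave-one-out.

## Numerical and degenerate-input conventions

* Zero-variance features: undefined Pearson correlation → excluded from
  stage 2 (never treated as r = 0); zero-variance columns fail PCA
  scaling loudly.
* Non-finite feature values fail validation immediately; no silent
  imputation (the recording protocol guarantees both states, so missing
  states are an error naming the subjects, not a case to patch).
* Metrics with zero denominators are reported `NA` ("undefined"), not 0.
* Comparisons against values printed at two decimals use half-up
  rounding (`round_half_up()`), matching how such tables are printed;
  banker's rounding would mis-compare exact halves like 0.625.
* Model JSON round-trips at full precision (`digits = NA`); identical
  seeds produce byte-identical artifacts.

## Known limitations

The package implements the derivation, not the acoustics: volume
normalization, utterance segmentation and functional extraction happen
upstream. The index inherits the screen's assumptions — linear MMSE
association, additive state effects — and the BER-threshold choice
deliberately trades the probability calibration of the logistic output
(where 0.5 would be the natural cut) for balanced errors under class
imbalance. Alternative learners reported to perform comparably (SVM,
boosting) are out of scope.
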
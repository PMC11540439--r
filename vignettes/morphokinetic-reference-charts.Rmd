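---
title: "Morphokinetic reference charts and the variance score: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphokinetic reference charts and the variance score: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvsref)
```

## The problem

Time-lapse monitoring of IVF embryos produces, for each embryo, a sequence of
annotated developmental milestones — from extrusion of the second polar body
(tPB2) through the cleavage divisions (t2–t9), compaction (tSC, tM) and
blastulation (tSB, tB) — each timed in hours post-insemination (hpi). Even
among euploid embryos, transfers fail or miscarry, and morphology grading
alone (Gardner expansion/ICM/TE grades) leaves much of that variation
unexplained. `mvsref` implements a longitudinal view of these annotations:

1. **Reference charts.** A growth-chart-style reference for euploid embryos:
   a mean curve $\mu(s)$ and an SD curve $\sigma(s)$ over the developmental
   stage index $s = 1,\dots,15$, and the implied Gaussian centile grid.
2. **Z-scores and the MVS.** Each annotation is standardized against the
   chart, $Z_{es} = (t_{es} - \mu_s)/\sigma_s$; the embryo-level
   *morphokinetic variance score* is the natural log of the variance of its
   Z-scores, $\mathrm{MVS}_e = \ln \operatorname{Var}_s(Z_{es})$. Low MVS
   means the embryo tracks one centile lane ("steady"); high MVS means it
   jumps between lanes ("erratic").
3. **Outcome association.** Logistic models of live birth on MVS and
   morphology, paired ROC/AUC comparison, repeated cross-validation for
   optimism-adjusted AUCs, an NPV-maximizing MVS cutoff, and a
   Cochran–Armitage trend test over ICM-by-MVS strata.

A synthetic cohort generator with calibrated defaults makes the whole
pipeline testable without patient data.

## The reference model

### Mean curve

Milestones are modeled on an integer pseudo-time axis, the *stage index*
1..15, rather than on clock time: the axis is the developmental sequence
itself, and the reference question is "at stage $s$, what is the distribution
of arrival times?". The mean curve is a linear mixed-effects regression of
time on a natural cubic spline in stage,

$$ t_{es} = f(s) + a_e + b_e s + \varepsilon_{es}, $$

with interior knots at every milestone (stages 2..14), a random intercept
$a_e$ and, by default, a random slope $b_e$ per embryo (embryos run
systematically early/late, and the magnitude of that offset grows along
development). Fitting uses `lme4::lmer`. With a knot at every milestone the
fixed-effect basis is saturated on the 15 stage points, so the population
curve can follow any smooth stage-mean profile; candidate bases (e.g. linear
vs spline) are compared with likelihood-ratio tests on ML refits
(`compare_models()`). An intercept-only random structure is available as a
fallback when the slope model does not converge.

### SD curve

The SD curve is estimated *separately* from the mean curve, from scaled
absolute residuals: population-level residuals
$r_{es} = t_{es} - \hat f(s)$ (random effects excluded) are transformed to
$|r_{es}|\sqrt{\pi/2}$ — under normality an unbiased local estimate of the
SD — and regressed on the same stage spline basis; fitted values are
$\hat\sigma_s$. Two choices deserve flagging:

* **Marginal, not conditional residuals.** Random effects are excluded when
  forming residuals, so $\hat\sigma_s$ measures the full between-embryo
  spread at stage $s$. That is the quantity needed to Z-score a *new*
  embryo against the chart; the conditional (within-embryo) SD would
  understate it.
* **Positivity.** Fitted SD values must be positive. A genuinely negative
  fitted value signals an overflexible basis and raises an error; the one
  exception is the degenerate near-noise-free cohort (the whole curve below
  $10^{-3}$ h), where numerically negative values are clamped at
  $10^{-9}$ h.

### Centile grid and calculator

Because Z-scores are modeled as Gaussian, the centile grid is
$c_{s,p} = \mu_s + z_p \sigma_s$ with $z_p$ the standard-normal quantile.
Grids are exported at 2 decimals (the printed-table convention); full
precision is kept internally and a full-precision export round-trips exactly
through `derive_gaussian_params()`, which inverts a grid back to
$(\mu_s, \sigma_s)$ from its widest symmetric centile pair (3rd/97th:
$\mu_s$ is the midpoint, $\sigma_s = (c_{97} - c_3)/(2 z_{0.97})$).
`percentile_of()` / `quantile_of()` are exact mutual inverses; the packaged
published grid (`mvsref_example_grid()`) makes the calculator usable without
refitting.

### Diagnostics

`diagnose_fit()` checks what a reference chart must satisfy on its training
cohort: pooled Z mean near 0 and SD near 1, per-milestone and pooled
Shapiro–Wilk normality, the lag-1 autocorrelation of within-embryo Z
sequences, and an outlier list at a configurable threshold (default
$|Z| > 4$). The default outlier policy is *report only* — outliers in real
annotation data need manual veracity review before removal, so the package
never drops them silently.

## Scoring decisions

* **Variance denominator.** The Z-score variance uses the sample ($n-1$)
  denominator, keeping its expectation at 1 for standard-normal Z regardless
  of how many milestones were observed; the population denominator is
  available as an option.
* **Missing milestones.** The MVS is computed over observed milestones only,
  with a floor of 3 observations; no imputation anywhere.
* **Degenerate variance.** An embryo exactly on one centile lane has zero
  Z-variance and $\ln 0$ is undefined; its variance is floored at
  $10^{-12}$ (MVS $\approx -27.6$), flagged, and classified as low-MVS — it
  is the steadiest possible embryo.
* **Cutoff boundary.** `classify_mvs()` is inclusive at the cutoff
  (low iff MVS $\le 0.3$ by default).
* **Per-SD odds ratios.** For regression, MVS is standardized by the scoring
  cohort's own MVS SD, so reported ORs are per-SD.

## The synthetic cohort generator

The generator is first-class, tested code; its defaults *are* the study
conditions the rest of the package is validated under.

* **Timings.** Per embryo, a latent factor $u_e \sim N(0,1)$ and
  $Z_{es} = \sqrt{\rho}\, u_e + \sqrt{1-\rho}\, \epsilon_{es}$, converted to
  times $\mu_s + \sigma_s Z_{es}$ with $(\mu_s, \sigma_s)$ derived from the
  packaged reference grid. Every milestone's marginal is exactly
  $N(\mu_s, \sigma_s^2)$ and every within-embryo pair of milestones has
  correlation $\rho$ (default 0.5) on the Z scale.
* **Monotonicity.** Real embryos cannot reach stage $s+1$ before stage $s$.
  Default handling is redraw-then-clip: an embryo whose drawn times are
  out of order is redrawn (up to 100 times), then clipped to the running
  maximum; the run errors if more than 5% of embryos needed clipping. Note
  the interaction with marginal calibration: the t3–t4 interval is short
  (1.44 h) relative to the two SDs (1.8 h, 2.1 h), so about a quarter of raw
  draws violate the order there, and conditioning on ordered draws shifts
  the t4 marginal upward by roughly 0.5 h. Tests of the Gaussian-calibration
  machinery therefore generate with `monotone = "none"`; default (ordered)
  cohorts are faithful to annotation semantics but have slightly distorted
  marginals at the tightly spaced cleavage stages.
* **MVS spread.** Under this latent-factor structure
  $\operatorname{Var}_s(Z_{es}) = (1-\rho)\,\chi^2_{14}/14$ in distribution,
  so the MVS SD is $\sqrt{\psi'(7)} \approx 0.39$ *whatever* $\rho$ is —
  the latent factor moves an embryo's level, not its steadiness. Clinical
  MVS spreads (about 0.9 points SD) imply genuine embryo-to-embryo
  differences in dispersion. An optional `embryo_dispersion_sd` parameter
  (default 0) multiplies each embryo's idiosyncratic noise by a lognormal
  factor; about 0.81 reproduces an MVS SD near 0.9, at the cost of
  heavier-than-Gaussian milestone marginals, which is why it is off by
  default and excluded from the calibration invariants.
* **Covariates and outcome.** Morphology grades and nuclear-error flags are
  drawn from the published cohort's marginal frequencies where printed (ICM
  18.5/70.9/10.6%, TE 20.9/62.9/16.2%, 2-cell errors 57.6%, 4-cell errors
  11.2%); expansion (15/45/40% for BL3/4/5) and day of blastulation
  (70/28/2%) are not printed and use plausible clinic values (biopsied
  blastocysts are mostly expanded; day-7 blastulation is rare). Live birth
  is drawn from a logistic model whose default log-odds are the published
  adjusted ORs (MVS 0.62 per SD, ICM B 0.51, ICM C 0.21, the remaining
  morphology terms near 1), with the intercept calibrated numerically so
  the expected live-birth rate is 55.6%; failures split into pregnancy loss
  vs no pregnancy at 48:103.
* **What it does not emulate.** Annotation noise and frame quantization
  (20-minute imaging intervals), day-specific reference differences,
  non-Gaussian (skewed) milestone distributions, informative missingness,
  and any richer correlation structure than a single factor. Passing tests
  on this generator validate the estimators under their assumptions; they do
  not certify performance on real clinic data.

## Inferential layer choices

* **Endpoint.** Live birth vs not (pregnancy loss and no pregnancy pooled)
  for all regression/ROC work; the three-way outcome is kept for rank-based
  descriptive comparisons (`compare_mvs_by_outcome()`, pairwise Wilcoxon).
* **CIs and separation.** Wald 95% CIs for ORs; complete separation and
  rank deficiency are detected and flagged rather than silently reported.
* **AUC comparison.** Apparent AUCs of nested models on the same subjects
  are compared with DeLong's paired test (`pROC::roc.test`). The CV layer
  uses outcome-stratified folds (preventing single-class folds at realistic
  n), pools held-out predictions within a repeat into one AUC per model per
  repeat, and compares models with a paired t-test across repeats; optimism
  is reported as apparent minus CV-mean AUC. The inner loop uses a
  rank-based AUC (ties at half credit), tested against brute-force pair
  enumeration.
* **Cutoff selection.** Candidate cutoffs are the observed MVS values
  (exact sweep, no grid); the selected cutoff maximizes the NPV of "high
  MVS predicts no live birth", smallest cutoff among ties; operating
  characteristics are reported at the selection and at the conventional 0.3.
* **Trend test.** Strata ordered A-low, B-low, C-low, A-high, B-high,
  C-high (best to worst) with equidistant scores via
  `stats::prop.trend.test`; empty strata are dropped with a warning. For two
  strata the statistic reduces to the uncorrected Pearson chi-squared.

## Problem sizes used in validation

The shipped tests validate parameter recovery at n = 500 embryos (mean curve
within ±0.5 h, SD curve within ±15%), marginal calibration at n = 5000
(Kolmogorov–Smirnov), correlation calibration at n = 10 000, coefficient
recovery at n = 5000 (within 2 Monte-Carlo SEs of the generating log-odds),
test size over 1000 null replicates (rejection in [3.5%, 6.5%] at the 5%
level), and scaled replications of the cross-validated model comparison at
n = 340 — the published cohort's size — over 10 seeds. The acceptance script
refits the full pipeline on one n = 340 cohort per run.

## Known limitations

* The stage-index axis treats milestones as equidistant; the spline is
  saturated at the milestones, so this is a labeling convention for the
  mean/SD curves rather than a modeling restriction, but it does shape the
  random-slope interpretation.
* Gaussian centiles: no LMS/skewness modeling; early milestones with small
  SDs are plausibly mildly skewed in real data.
* One reference chart for all cohorts: no day-of-blastulation-specific or
  clinic-specific charts.
* The MVS treats all milestones symmetrically; a delay at blastulation and
  a hiccup at the 3-cell stage contribute alike.
* Odds-ratio defaults in the generator are calibrated to published adjusted
  estimates; they are a simulation device, not a causal claim.
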
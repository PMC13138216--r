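---
title: "Methods: harmonized multi-study analysis of post-trauma PTSD and depression trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonized multi-study analysis of post-trauma PTSD and depression trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`traumameta` implements an individual-participant-data (IPD) meta-analytic
pipeline for trajectories of posttraumatic stress disorder (PTSD) and major
depressive disorder (MDD) after trauma, of the kind used when several
prospective emergency-room cohorts are pooled at the participant level. Each
participant is assessed twice: in the **acute** window (0--60 days since
trauma) and the **persistent** window (122--456 days). A disorder present at
the first wave only is an *acute* trajectory, present at both waves
*persistent*, at neither *never*. The package covers every stage --
instrument harmonization, diagnosis, imputation, inference, and calibration
diagnostics -- and ships a synthetic multi-study generator so the whole
pipeline is testable without access to restricted clinical data.

This vignette records the modelling choices, their defaults, and the places
where the design was genuinely open.

## 1. Instruments and diagnosis

**PTSD.** The Clinician-Administered PTSD Scale (CAPS) rates 17 DSM-IV
symptoms for frequency and intensity (each 0--4). Severity is the sum over
all items (0--136), decomposed into criterion B (reexperiencing, items 1--5),
C (avoidance, 6--12) and D (hyperarousal, 13--17). A symptom is *present*
when frequency ≥ 1 and intensity ≥ 2; diagnosis requires ≥ 1 B, ≥ 3 C and
≥ 2 D present symptoms (`score_caps()`). Criteria E/F (duration, impairment)
are deliberately not evaluated -- they are not consistently collected across
acute-care cohorts -- so "diagnosis" throughout means this symptom-pattern
rule.

**Depression.** Two instruments appear across studies: the 21-item BDI-II
and the 7-item HADS depression subscale (items 0--3 each). Case status uses
the moderate-severity threshold BDI ≥ 20; HADS totals are first mapped onto
the BDI metric through a crosswalk, under which HADS ≥ 13 is the equivalent
case rule (`classify_mdd()`). Lower conventional HADS cut-offs (≥ 7, ≥ 11)
equate to BDI scores well below 20 and would define a milder, non-comparable
phenotype.

## 2. IRT harmonization (crosswalk construction)

The crosswalk is built by item response theory rather than by ad-hoc
rescaling:

1. **Unidimensionality check.** Ordinal confirmatory factor analysis on
   polychoric correlations (`polychoric_correlation()`, two-step ML under a
   discretized bivariate normal; `fit_factor_model()`, unweighted least
   squares). Working thresholds: CFI > 0.95, TLI > 0.95, RMSEA < 0.06
   (≤ 0.10 tolerable). The estimator choice (ULS on polychorics, chi-square
   as the discrepancy scaled by *n* − 1) is ours; the indices are the
   standard ones and behave as expected on simulated one-factor data.
2. **Calibration.** A graded response model (GRM) is fit by marginal maximum
   likelihood to each pooled-by-instrument dataset (`fit_grm()`): instrument
   items plus three CAPS symptoms that overlap depression content
   (diminished interest, sleep disturbance, concentration -- C4, D1, D3) as
   anchor items. Anchors are recoded to a 0--4 ordinal by summing frequency
   and intensity and binning (0, 1--2, 3--4, 5--6, 7--8); the source data do
   not dictate a coding, and this one preserves granularity without sparse
   top categories. EM uses 61 quadrature points on [−6, 6], convergence at
   max |Δparameter| < 1e−4, cap 500 iterations; non-convergence warns with
   the trace retained. Pooling per instrument (rather than per study) is the
   package's reading of the two-pooled-datasets design; a per-study fit can
   be run by filtering the cohort first.
3. **Linking.** Mean/sigma constants from the pooled anchor *thresholds*:
   `A = SD(b_base)/SD(b_target)`, `B = mean(b_base) − A·mean(b_target)`.
   Pooling all threshold parameters of the three anchors (rather than item
   means) stabilizes the SD ratio when only three anchors exist.
4. **Equating.** True-score equating: for each integer HADS total *s*, the
   HADS test characteristic curve (TCC) is inverted by bisection and the BDI
   TCC evaluated there, rounded half-up; endpoints are pinned (0 → 0,
   21 → 63) and the table forced monotone (`build_crosswalk()`). TCC
   true-score equating was chosen over equipercentile methods because it
   yields a deterministic, sample-independent full-range table once the
   calibrations are fixed.

The package also ships the reference crosswalk table
(`hads_bdi_crosswalk()`), which is what the classification default uses;
`equate_cohort()` re-derives a crosswalk from data.

## 3. The synthetic multi-study generator

`generate_cohort()` emulates a five-study pool (N = 2571 by default;
`icpp_study_configs()`) with the study-specific instruments (HADS vs BDI),
assessment-timing distributions (truncated normal inside each window), and
follow-up rates of the real consortium the package models.

**Trajectory classes are generated directly from a multinomial logit** in
the seven baseline risk factors (plus optional per-study offsets), with
default log-odds set to the published effect-size regime (e.g. female →
persistent PTSD OR 2.14, acute PTSD OR 1.86; accident index trauma
protective; `default_covariate_effects()`). We deliberately did *not*
generate classes by thresholding a latent severity process: under threshold
crossing the fitted multinomial's estimand is not the stated odds ratio, so
parameter-recovery tests would confound model error with design error.
Direct class generation makes the configured OR the exact estimand while the
item-level machinery below still produces severities consistent with each
class. A second regime (`trajectory_model = "severity"`) draws wave-1
diagnosis from the covariates and then persistence from a logistic model in
the *realized* acute severities (defaults: per-15-point total PTSD OR 1.15,
per-5-point MDD OR 1.17), which is the estimand of the persistence models.

**Item responses** are drawn from the GRM item bank (`default_item_bank()`:
log-normal(0, 0.3) discriminations, sorted-normal thresholds, anchors at
discrimination 1.5), conditional on the class-implied diagnosis at each
wave: each participant's latent quantile is mapped into the truncated-normal
distribution on the required side of the diagnostic cutpoint (preserving
wave and disorder correlations, defaults 0.7 and 0.6), and items are
resampled until the scored diagnosis matches, with a deterministic
minimal-perturbation fallback. Consequently the classifier recovers the
generator's trajectory labels *exactly* when no missingness is applied --
the property the downstream tests rely on. HADS item thresholds are shifted
so both instruments' case rules coincide on the latent trait, mirroring the
empirical fact that HADS totals saturate faster than BDI totals.

**Missingness** applies to wave-2 assessments only. Default per-study PTSD
missingness is 1 − follow-up rate, with extra MCAR depression-instrument
missingness (default 0.19) reflecting the substantially higher MDD attrition
observed in such pools (~31% PTSD vs ~45% MDD); a study with complete
follow-up stays complete. The MAR mechanism makes wave-2 loss depend on
wave-1 severity (+0.5 logits per SD) and sex (+0.3), with the intercept
solved per study so the marginal rate still matches the target. The
real-world wave-1 missingness mechanism is unknowable from published
material, so both mechanisms are provided without asserting which is
realistic. Item-level nonresponse within an observed instrument is out of
scope.

**What passing tests do and do not show.** The generator reproduces the
structure the analysis assumes: latent-trait-driven ordinal items, a
diagnosis rule applied at two waves, covariate-linked class membership,
study-specific timing and attrition. It does not emulate instrument drift,
culture-specific item functioning, time trends in persistence inside the
follow-up window, or informative wave-1 missingness -- so recovery results
here validate the estimation machinery, not the clinical conclusions of any
particular real dataset.

## 4. Multiple imputation

`impute_cohort()` runs chained equations on the long (participant × wave)
table, honoring the two-level structure:

* continuous targets (severities): linear model with participant random
  intercept, study fixed dummies, and study-specific residual variances
  (`nlme::lme` with `varIdent`); posterior-predictive draws under
  asymptotic-normal parameter draws (maximum likelihood with parameter
  draws, not full Bayes -- deterministic and testable);
* binary targets (diagnosis flags): participant-random-intercept **probit**
  (`lme4::glmer`), chosen over logit because the latent-normal augmentation
  makes the conditional draws natural; fixed-effects fallback when the
  random intercept is unidentifiable;
* categorical variables: a dummy series of probits reassembled by
  most-probable category;
* predictor sets: every variable correlated at least 0.10 (absolute,
  pairwise-complete) with the target, plus study dummies always
  (`select_predictors()`). A diagnosis flag's own severity is excluded from
  its model -- the flag is (nearly) deterministic in it, which would
  separate the probit.

Missing wave-2 trajectory information is imputed at the **diagnosis-flag
level** and trajectories re-derived per completed dataset, keeping the
trajectory definition exact in every imputation. Visit order is increasing
missingness; chains are independent with seeds derived from `(seed, chain)`;
chain means per cycle are kept as mixing diagnostics. Defaults m = 20,
10 cycles (both unreported in the source literature, so documented here as
package defaults); examples and tests use smaller m and a few hundred
participants per study, which is where the estimators stabilize in our
simulations.

Pooling follows Rubin's rules (`rubin_pool()`): total variance
`T = U̅ + (1 + 1/m)·B` with Barnard--Rubin degrees of freedom. Chi-square
statistics (the constrained LRTs) pool by the D2 rule -- Rubin's rules do
not define a chi-square combination, and D2 is the standard choice.

## 5. Inferential models

`fit_multinomial()` is a Newton--Raphson maximum-likelihood multinomial
logistic fitter (reference category *never*) supporting equality constraints
that tie a predictor's coefficient across the acute and persistent
equations; `constrained_lrt()` compares constrained vs unconstrained fits
(statistic clamped at 0, df = number of tied design columns). Separation
(any standardized coefficient beyond 15) triggers a warning and a
ridge-stabilized refit flagged in the output. With two outcome categories
the fitter agrees with binary logistic regression to numerical precision,
and its likelihood matches a direct-optimizer oracle -- both are tested.

Persistence Models 1--3 (`fit_persistence_logistic()`) are logistic
regressions among acute + persistent participants: Model 1 adds the other
disorder's acute severity to the risk factors, Model 2 both severities,
Model 3 depression severity plus the B/C/D cluster severities. Odds ratios
are reported per 5 points (depression, clusters) and per 15 points (total
PTSD), implemented by pre-scaling the columns so pooled coefficients are
already per-increment. Study effects enter all inferential models as fixed
dummies, mirroring the imputation design; the random-intercept variant
exists in the calibration module. Delayed-onset (wave-2-only) cases are rare
bookkeeping labels excluded from the primary models, and age enters per
year untransformed. No multiplicity correction is applied.

## 6. Calibration and sensitivity diagnostics

`bootstrap_calibration()` resamples participants with replacement, fits the
persistent-vs-rest logistic model (fixed study dummies, or random study
intercept by adaptive Gauss--Hermite quadrature, 15 nodes by default) on the
in-bag sample, and evaluates the out-of-bag participants -- those never
drawn, the standard reading of bootstrap leave-out (≈ 36.8% of the pool).
Reported per study and disorder: the expected/observed ratio `Σp / Σy`
(above 1 = over-prediction; undefined, not an error, when a study has no
events) and the Brier score `mean((p − y)^2)`. Statistics average over
replicates, then over imputations; everything is deterministic under a
fixed seed. B = 1000 reproduces the full design; tests use a few hundred.
Whether published per-study calibration tables derive from the fixed- or
random-effects model is not stated in the source literature, so the report
emits both.

`leave_one_study_out()` reruns the pooled risk models dropping each study;
`window_sensitivity()` redefines the persistent window (e.g. 270--456 days),
marks outside assessments unobserved, and reruns classification, imputation
and models. The identity window reproduces the primary run exactly.

## 7. Numerical choices and degenerate inputs

* Crosswalk rounding is half-up; sub-floor source scores clamp to the
  boundary; monotonicity enforced by a running maximum.
* TCC inversion by bisection on [−10, 10] (the TCC is strictly monotone).
* GRM M-steps use BFGS on (log a, b₁, log-spacings), guaranteeing positive
  discrimination and ordered thresholds; unobserved categories are collapsed
  with the mapping logged.
* Polychoric correlations optimize the two-step profile likelihood on
  (−0.999, 0.999); constant variables after listwise deletion raise an
  undefined-correlation error.
* Correlation matrices that are not PSD are ridge-repaired before ULS.
* `rubin_pool()` returns infinite df (normal quantiles) when the
  between-imputation variance is numerically zero.
* Empty trajectory groups, all-missing windows, zero-variance imputation
  targets, non-finite latent traits, and out-of-range scores raise
  structured errors naming the offending input.

## 8. Known limitations

* The probit/linear conditional draws use asymptotic-normal parameter
  uncertainty, not a full Bayesian posterior; coverage is slightly
  conservative at very small n.
* Imputed continuous severities are not integer-rounded and may exceed the
  instrument range slightly; diagnosis flags are imputed separately, so the
  flag--severity link is stochastic, not deterministic, inside imputations.
* The generator's default effect sizes and prevalence intercepts are a
  stylized regime, not a fitted model of any real cohort.
* Mean/mean linking, Stocking--Lord, DIF analysis, random slopes, and
  predictive-mean matching are intentionally absent.

## 9. Pipeline

`run_pipeline()` chains the stages under a declarative config
(`validate_config()`; unknown keys rejected with nearest-key suggestions)
with per-stage seeds derived from the master seed, and writes CSV artifacts
(crosswalk, classified table, descriptives, OR tables, LRTs, calibration
report) each carrying the config checksum, plus a JSON manifest with file
checksums -- identical configs yield identical manifests. The demo
configuration in the README runs a few hundred participants per study with
m = 2--5 imputations and small bootstrap counts; full-scale settings are a
config change, not a code change.
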
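---
title: "Modelling spatial variation of coarse PM from snapshot campaigns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spatial variation of coarse PM from snapshot campaigns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coarselur)
library(dplyr)
```

## The model

Coarse particulate matter (PM10-2.5, 2.5-10 µm) is estimated as the
difference of collocated two-week PM10 and PM2.5 filter measurements taken
simultaneously at many residential sites in a city, in two seasons. For an
outcome $y_i$ (coarse mass, or a species concentration) at site-season row
$i$, the land-use regression (LUR) mean model is

$$ y_i = \beta_0 + \sum_j \beta_j x_{ij} + \gamma\,\mathrm{summer}_i +
   \sum_j \delta_j x_{ij}\,\mathrm{summer}_i \;[+\; \text{city terms}] +
   \varepsilon_i, $$

where the $x_{ij}$ are geographic covariates (land-use percentages, road
lengths, population density, vegetation indices, emissions, distances)
summarized in circular buffers around the site. Universal kriging (UK) adds
a spatially structured component: we model the LUR residuals as a mean-zero
Gaussian field with exponential covariance
$C(d) = \sigma^2_{\text{psill}}\, e^{-d/\phi}$ plus a nugget, and predict at
new locations by simple kriging of the training residuals. This two-stage
formulation (OLS mean, then kriged residuals) is an approximation to
simultaneous GLS estimation; at campaign sample sizes (30-60 locations per
city) it is statistically indistinguishable from the joint fit and keeps
cross-validation folds simple, because refitting is just OLS plus one
variogram per training fold.

Season enters both as an additive offset and as an effect modifier of
covariates; in models pooled over cities, city enters the same way. No
covariate-by-covariate interactions are considered.

## The selection procedure

The covariate library is large (hundreds of columns; the default synthetic
schema has 242) relative to the number of samples, so selection is staged:

1. **Variability filter.** A column is dropped when its 85th percentile
   equals its 15th percentile on the analysis rows. Quantiles use the
   linear-interpolation convention (`stats::quantile` type 7); the equality
   is exact, which makes the rule deterministic and scale-invariant.
2. **Buffer selection.** Within each buffered category we keep at most one
   short-range buffer (50-500 m) and one long-range buffer, chosen by the
   largest absolute Pearson correlation with the outcome. We treat the long
   range as open-ended (> 500 m) rather than capped at 5 km because several
   categories (population density, truck routes, emissions, dispersion-model
   surrogates) are only defined at kilometer scales and would otherwise be
   silently discarded. Absolute rather than signed correlation is used: a
   strongly protective buffer is as informative as a strongly adverse one.
   Ties break toward the smaller radius, then lexicographic name, so runs
   are reproducible.
3. **Correlation pruning.** Pairs with $|\rho| > 0.85$ form a graph; each
   connected component is resolved greedily (keep the best remaining member,
   delete its neighbours, repeat). "Best" applies preference class first —
   positional coordinates are excluded preferentially, and recent
   raster-derived land use is preferred over 1970s-era aerial photography —
   then the larger $|r|$ with the outcome. Preference outranks correlation
   strength because coordinates predict by location rather than mechanism,
   and dated land use is a validity concern regardless of its in-sample
   correlation.
4. **LASSO shortlist.** The survivors, their season (and city) interactions
   and the season/city indicators enter an L1 path of 100 log-spaced
   penalties, from the smallest penalty that zeroes every coefficient down
   to $10^{-4}$ of it. Covariates are standardized inside the penalized fit.
   We take the support of the largest-support solution with at most 15
   terms. The LASSO is used purely as a screen; its shrunken coefficients
   are discarded.
5. **Exhaustive search.** Every subset of the shortlist with at most 6
   parameters (intercept free; each main effect, indicator, or interaction
   term counts one) is fit by OLS and scored by 10-fold cross-validated
   RMSE. One fold assignment is drawn per selection run and shared across
   all candidates so their CV errors are comparable; fold sizes differ by at
   most one. A subset containing an interaction without its main effects is
   repaired by forcing the main effects in — the repair may exceed the
   6-parameter cap, which is applied to the subset as enumerated. Ties
   (ΔRMSE < 1e-10) go to fewer parameters, then the lexicographically
   smaller term set. Rank-deficient candidates are discarded and counted.

## Evaluation metrics

Held-out predictions are assembled over all folds before computing metrics
(the pooled-residual convention — the alternative, averaging per-fold
metrics, is noisier at these sample sizes and was not used). CV RMSE is
$\sqrt{\mathrm{mean}((y-\hat y)^2)}$ and CV $R^2 = 1 - SSE/SS_{\text{mean}}$.
For pooled multi-city models the within-city explanatory power is computed
against each city's own mean, $1 - SSE_c / \sum_{i \in c}(y_i - \bar y_c)^2$,
and negative values are reported as 0 (the raw value is retained in the
report). The squared correlation between observations and predictions is
reported separately as a diagnostic; it is not the selection metric. For UK,
the variogram is refit inside every training fold so the held-out tenth is
never touched.

## Quality control

A sample is voided for: duration < 9 days; absolute flow deviation > 20%; a
damaged filter; coarse concentration more than 5 SDs from its city-season
mean; or coarse-fraction sulfur > 0.2 µg/m³ (sulfur lives almost entirely in
the fine fraction, so coarse sulfur marks a failed size cut). Two choices
the rules leave open are fixed as follows:

* The 5 SD screen is single-pass: the stratum mean and SD are computed once
  on the full candidate stratum, not recomputed after each removal. This is
  the conservative reading and makes the rule order-independent.
* When several rules match, the recorded reason follows the fixed order
  duration, flow, damage, outlier, sulfur, so reports are deterministic.
* The screen applies to coarse mass by default; `qc_rules(outlier_on =
  "mass_and_species")` extends it to the species columns.

Negative coarse values (PM2.5 exceeding PM10) are retained but flagged as
invalid pairs; they are not a voiding reason. The separate 3 SD exclusion is
a modelling-time sensitivity switch (`apply_sensitivity()`), not a QC rule,
as is the natural-log transform; with both switches off the pipeline output
is bit-identical to the primary run.

## The synthetic-campaign generator

The generator exists so that every stage has a testable oracle without any
field data. It emulates:

* **Site placement**: uniform over a rectangular projected-coordinate
  domain, default 30 × 30 km with ~40 sites per city in three cities and a
  central urban core — the scale of a residential snapshot campaign. (Real
  campaigns select homes purposively to spread geography and covariate
  contrast; the uniform draw is a neutral stand-in, since the actual
  selection rule of any given study is unpublished.)
* **Covariates**: each category is a latent Gaussian surface (150 random
  knots, unit-normal values); the covariate at buffer radius $r$ is a
  Gaussian-kernel average with bandwidth $\max(r, 300\,\mathrm{m})$, then an
  affine/monotone transform into plausible units (percent cover via a
  logistic map, road lengths and densities via a lognormal map). Nested
  buffers of a category therefore share structure, with correlation decaying
  as radii separate — the property that makes buffer selection and
  correlation pruning non-trivial. Calibration constants come from a fixed
  reference lattice, so surfaces evaluate identically at monitoring sites
  and later prediction grids (`covariates_at()`).
* **Concentrations**: intercept + sparse linear signal on campaign-
  standardized covariates (so coefficients read as µg/m³ per SD) + per-city
  summer offsets and covariate-by-season interactions + a smooth spatial
  residual field (exponential covariance, default range 2 km, sill 0.5)
  shared by both seasons + independent nugget variation (default 0.2) +
  multiplicative lognormal measurement noise (default sdlog 0.08; additive
  Gaussian available). The smooth field persists across seasons because it
  represents unmeasured long-term spatial structure — exactly the component
  kriging can exploit; the nugget is per-sample. Negative concentrations are
  truncated at zero and counted in the ledger.
* **PM10 construction**: PM10 = PM2.5 + coarse, exactly, so the QC
  subtraction recovers the generated coarse mass.
* **QC defects**: per-sample Bernoulli draws for short durations (5-8 days),
  out-of-range flows (25-40%), high coarse sulfur (0.25-0.5 µg/m³) and
  damaged filters, on disjoint samples, all recorded in a truth ledger.

**Extreme-concentration injection** deserves its own note. The z-score of a
single point among $n$ is bounded by $(n-1)/\sqrt{n}$, so a > 5 SD extreme is
only *possible* in strata with $n \ge 27$, and two equal spikes in one
stratum can never both exceed 5 SDs (the attainable maximum is
$(1-k/n)\sqrt{n/k} < 5$ for $k = 2$ at campaign sizes). The generator
therefore injects at most one extreme per city-season stratum, at stratum
mean + 25 SD, and only in strata with $n \ge 30$. For the same reason,
season-thinning (`repeat_fraction`) happens *before* defect injection:
defects belong to the samples actually collected, and an extreme injected
into a stratum that is subsequently halved could become undetectable by any
SD rule.

What the generator does **not** emulate: real GIS geometry (road networks,
rasters, dispersion models), purposive site selection, seasonal meteorology
beyond a mean shift, correlated measurement error between collocated
PM10/PM2.5 filters, and spatial nonstationarity. Passing tests therefore
demonstrate that the *statistical machinery* is correct and recovers known
truth under the stated generating process — not that any particular real
campaign satisfies that process.

## Numerical choices

* **Variogram**: ~12 equal-pair-count lag bins up to half the maximum
  pairwise distance; exponential model fit by weighted least squares with
  pair counts as weights, from three starts (L-BFGS-B, parameters bounded
  non-negative). The effective range of the exponential (95% of sill) is
  3× the range parameter. Range recovery from a single realization of 500
  points has a median relative error around 15-30% depending on the seed —
  alternative estimators we examined (equal-width or sqrt-spaced bins, the
  variogram cloud, Cressie's relative weights) were no more accurate here,
  so the simple pair-count WLS is kept.
* **Kriging**: covariance from the fitted variogram; the nugget sits on the
  diagonal only, so prediction at a training site reproduces the observation
  exactly when the nugget is zero and smooths toward the regression surface
  otherwise. Residuals at exactly duplicated coordinates are averaged before
  solving (duplicates make the system singular at zero nugget); a residual
  singularity is handled with a ridge of $10^{-8} \times$ sill and a
  warning. Multi-city UK fits a variogram per city, falling back to the
  pooled variogram below 20 residuals per city (`pooled_variogram = TRUE`
  forces sharing). With a zero partial sill UK predictions equal LUR
  predictions exactly.
* **Field simulation**: multivariate normal via Cholesky; a numerically
  non-positive-definite covariance is jittered on the diagonal (escalating
  ×10 from $10^{-10}$) and the retry reported.
* **Predictions are not truncated at zero** by default, preserving model
  linearity for evaluation; grid exports accept `clip_zero = TRUE` for maps.
* **Determinism**: every stochastic stage takes a seed; `run_pipeline()`
  derives per-stage seeds from the master seed by fixed offsets and records
  them in the manifest; rerunning a configuration reproduces identical
  numeric artifacts.

## Problem sizes used in the tests

Monte-Carlo tests use 20 seeds (50 for coefficient-recovery coverage) at the
scales the procedures target: ~60-sample campaigns for selection sanity
(5 true predictors among 12 candidates, residual variance set so the
generator's oracle CV R² is about 0.6), 500 points for variogram and
coefficient recovery, 45-60 sites for QC and UK/LUR comparisons. The full
suite runs in about two minutes; `scripts/acceptance.R` recomputes the
headline quantities in about one.

## Known limitations

* The exponential is the only variogram family; campaigns with long-memory
  or anisotropic residual structure are outside the model.
* The two-stage UK ignores the uncertainty of the estimated mean model when
  kriging residuals; kriging variances are not reported.
* Screening decisions are made on the pooled analysis rows of the model
  being built; they are data-dependent and inherit cross-validation optimism
  from being outside the CV loop (as in the procedure modelled).
* The exhaustive search is limited to 15 shortlisted terms (32,768 raw
  subsets); larger shortlists must rely on the LASSO stage more heavily.
* Grid exports use the winter (reference-season) surface of season-
  interacted models; a long-term average surface would need both seasons'
  predictions averaged.
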
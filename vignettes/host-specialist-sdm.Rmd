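---
title: "Modelling host-dependent range dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling host-dependent range dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the two-stage
model, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the numerical and design choices made where the
procedure was genuinely open.

## The two-stage model

The analysis targets systems where a specialist consumer is obligately
tied to a single host species. Stage one fits an ensemble species
distribution model (SDM) for the host from presence records and
environmental layers, and projects a continuous habitat-suitability map
in [0, 1] under each climate scenario. Stage two appends the
scenario-matched host suitability map to each specialist's predictor
stack as a layer named `host_suitability` and runs the identical
selection–ensemble–binarization path. Host availability thereby competes
with climate on equal footing in the specialist models, and its jackknife
importance measures how strongly the specialist tracks its host.

Each species' model is a gated committee. For every repeated split, a
learner is fitted on the training rows and scored on the held-out rows;
members enter the ensemble only if held-out TSS ≥ 0.6 **and** AUC ≥ 0.8,
and the ensemble prediction is the TSS-proportional weighted mean of the
included members' scores. The TSS of a member is evaluated at its own
held-out maximum sensitivity–specificity (MSS) threshold. Suitability maps
are binarized into potential ranges at the species-level MSS threshold
computed from the ensemble's scores at the training rows. Range shifts are
summarized by the range expansion ratio (RER = RF/RC), the index of range
similarity (IRS = 2·RS/(RC+RF)), the expanding range (future AND NOT
current), and for specialists the percentage of range overlap with the
host (POR = S/RH), all on spherical cell areas (band formula, R = 6371 km).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| uncertainty filter | 5000 | m | drop records located more coarsely than the analysis grid; strictly "greater than", so 5000 m survives and missing uncertainty passes |
| thinning cell | 5000 | m | one record per cell in a cylindrical equal-area projection, removing density artefacts of uneven recording effort |
| pseudo-absence floor | 1000 | points | 1000 background points for rare species; one per presence when presences exceed 1000 |
| CV repetitions | 5 | — | five independent stratified 70/30 splits |
| test fraction | 0.3 | — | held-out share per class, within one row per class |
| TSS gate | 0.6 | — | member inclusion floor |
| AUC gate | 0.8 | — | member inclusion floor |
| collinearity threshold | 0.7 | \|Pearson r\| | iterative pruning, lower-importance member of the worst pair dropped first |
| ridge penalty λ | 1e-6 | — | numerical stabilizer for the logistic member on standardized predictors; not a tuned regularizer |

## The synthetic-data generator

The generator stands in for real occurrence and climate extracts so that
the whole cascade can be validated against a known truth.

* **Landscapes** are Gaussian-smoothed white-noise fields on a torus
  (FFT convolution), standardized to zero mean and unit variance;
  `smoothness` is the kernel standard deviation in cells and controls
  spatial autocorrelation. The default grid is 2.5 arc-minute cells
  anchored at 55° N so cell areas vary realistically with latitude.
* **Virtual species** have logistic true suitability
  `plogis(intercept + Σ coef·layer + host_weight·host_suitability)`.
  The default host (`intercept −8`, `clim1 +6`, `clim2 −4`, `soil1 +3`)
  occupies roughly 15% of the landscape with a sharp niche edge, so that
  fitted members reach the held-out discrimination (AUC ≳ 0.88,
  TSS ≳ 0.69) characteristic of well-performing presence/background
  ensembles; a diffuse niche would be inadmissible to a gated ensemble by
  construction, which is a property of gating, not of the landscape.
* **The cascade** gives the specialist a dominant host term
  (`host_weight 16` vs a single direct climate coefficient of 2). Two
  soil-like layers are candidate predictors **only for the host**,
  mirroring designs where edaphic variables constrain the plant but are
  not offered to insect models. This matters mechanically: the host map
  then carries information that no other specialist predictor contains,
  so leave-one-out importance cannot compensate for its removal. If every
  host driver were also a specialist candidate predictor, host
  suitability would be numerically reconstructible from them and its
  jackknife importance would be deflated — an identifiability limit of
  leave-one-out importance worth remembering with real data.
* **Scenarios** are additive scalar offsets on named layers (default:
  +0.25 to +0.8 standard deviations on `clim1`, whose host coefficient is
  positive), so true suitability rises monotonically with scenario
  severity and ranges should expand.
* **Presences** are drawn without replacement with probability
  proportional to true suitability, at cell centres.

What the generator does **not** emulate: real geography and coastlines
(no nodata structure by default), sampling bias and detection covariates
(a presence is exactly proportional to suitability), non-logistic or
interaction-driven niches, temporally autocorrelated climate change
(shifts are spatially uniform), and multi-algorithm committee diversity.
Passing the validation experiment therefore shows the *pipeline* is
correct and identifiable under its own assumptions — not that any real
species obeys them.

## Numerical choices

* **Bioclim derivation**: monthly mean temperature is `(tmin + tmax)/2`;
  bio4 is the population standard deviation × 100; bio15 uses
  `sd/(1 + mean) × 100`; quarters are 3-month wrap-around windows with
  ties resolved to the earliest starting month; temperatures stay in °C.
  bio3 is set to nodata where the annual range (bio7) is zero, and any
  nodata among a cell's 36 inputs blanks all 19 outputs there.
* **Raster conventions**: the origin is the upper-left corner of the
  upper-left cell, rows grow southward, and cell membership is half-open
  `[edge, edge + cell_size)`. Continuous resampling is bilinear between
  cell centres, categorical nearest-neighbour, and any nodata contributor
  makes the output cell nodata (never fabricate values at coastlines).
* **Thinning** works in a cylindrical equal-area projection anchored at
  (0°, 0°) so 5-km cells have constant area at all latitudes; within a
  bucket the record with the smallest stated uncertainty survives, ties
  to the earliest input record, and missing uncertainty ranks last.
* **MSS threshold**: candidates are the distinct observed scores; ties go
  to the smallest threshold. Binarization uses ≥, so a cell exactly at
  the threshold is presence. One MSS threshold per species, computed from
  the current-scenario ensemble scores at the training rows, is applied
  to all scenario maps — future scenarios provide no labelled data from
  which a separate threshold could be estimated honestly.
* **Ridge-logistic member**: IRLS on standardized predictors, penalty
  1e-6 (intercept unpenalized), converged when the largest coefficient
  change is below 1e-8, at most 100 iterations; non-convergence flags the
  member for exclusion rather than raising.
* **Importance**: reported jackknife importance is computed on the
  *formal* (post-pruning) predictor set — the preliminary all-predictor
  importance is used only to decide which member of a collinear pair to
  drop. Raw importance is the drop in mean held-out AUC when the
  predictor is removed, floored at zero; standardization is max–min. A
  permutation variant exists behind `method = "permutation"`.
* **Degenerate inputs**: zero-variance predictors yield NA correlations
  with a warning; all-equal importances standardize to zero with a
  warning; an empty current range flags RER undefined (not infinity); an
  empty specialist range flags POR undefined; zero-variance paired
  differences flag the t-test degenerate.

## Open design decisions taken

* The repeated-validation scheme is five repetitions of stratified 70/30
  random splits — the conventional reading of a "5-repetition, 7:3"
  ensemble protocol.
* The committee is pluggable; the package natively implements one member
  (penalized logistic regression) and the gating/combination logic, which
  is where the scientific contract lives. External learners can be
  supplied as `list(fit, predict)`.
* Pseudo-absences exclude presence cells, are drawn without replacement,
  and are drawn once per species run (shared across repetitions) so
  splits remain comparable.
* Specialists use the continuous host suitability map, not a binarized
  range, as their host-availability predictor, and always the host map of
  their own scenario.
* IRS is computed on areas (km²), not cell counts — identical on
  equal-area grids, correct on lon/lat grids.

## Problem sizes

The validation experiment runs on a 200 × 200 landscape (40 000 cells)
with six layers, smoothness 10, 500 presences per species and five
scenarios; pipeline unit tests use a 100 × 100 landscape with 300
presences; the importance-ranking sweep repeats the full two-stage
experiment across 100 seeds; metric oracles are checked on 1000 random
instances each. These sizes were chosen so the entire validation runs on
a laptop in minutes while leaving every stage statistically identifiable.

## Known limitations

* Importance of a predictor that is reconstructible from others is
  structurally deflated (see above); collinearity pruning mitigates but
  does not remove this.
* One native learner means no committee diversity by default; gating and
  weighting are exercised, algorithmic variance is not.
* The MSS threshold is estimated once per species on current-scenario
  data; per-scenario thresholds would require labelled future data.
* Raster I/O is ESRI ASCII grid only, single band; there is no general
  projection support beyond the fixed equal-area transform used for
  thinning and the spherical band areas.
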
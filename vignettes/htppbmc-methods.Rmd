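---
title: "Methods: phenotypic profiling distances and benchmark concentrations in 96-well plates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotypic profiling distances and benchmark concentrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

`htppbmc` analyzes high-throughput phenotypic profiling (Cell Painting)
screens run in 96-well plates. The input is a long-format table of per-cell
morphological features (one row per segmented cell; typically ~1,300 features
grouped into 49 biologically meaningful categories), a plate map assigning
each well a chemical, a concentration in µM, and a role (vehicle, test,
cytotoxic control, negative control). The output is, per chemical, a
benchmark concentration (BMC): the concentration at which a multivariate
distance from the solvent-control phenotype crosses a benchmark response
(BMR), with bootstrap confidence limits, a continuous hitcall, and exclusion
flags.

The pipeline follows the now-standard Mahalanobis-distance workflow for
Cell Painting bioactivity screening:

1. **Batch assembly.** All plates of one experiment are merged and treated
   as one batch; all reference statistics are computed batch-wide. A
   per-plate mode exists for sensitivity analysis (each plate its own
   batch), which is known to give noisier covariance estimates in this
   format.
2. **Well-level QC.** Wells with fewer than 100 analyzable cells, or with a
   cell-count reduction greater than 50% relative to the *median count of
   the batch's vehicle wells*, are excluded. Both inequalities are strict:
   exactly 100 cells or exactly 50% reduction is retained.
3. **Three-step normalization.** For every feature *f*: (i) cell-level
   robust z-scores against all cells of all vehicle wells of the batch,
   `z = (x − med_f) / (1.4826 · MAD_f)`; (ii) aggregation to well medians;
   (iii) division by the standard deviation (n−1 denominator) of those well
   medians over the vehicle wells. Vehicle wells pass through the same
   transform — their normalized profiles define the distance reference and
   the BMR.
4. **Dimensionality reduction.** PCA on the normalized well × feature matrix
   (columns centered and unit-scaled), retaining the smallest number of
   leading components whose cumulative explained variance reaches 95%.
5. **Mahalanobis distances.** The covariance of the retained scores over
   *all* wells of the batch is inverted with the Moore–Penrose generalized
   inverse, and each well's squared Mahalanobis distance from the mean score
   of the vehicle wells is computed. A per-category mode treats each feature
   category as an independent dataset (own PCA, own distances).
6. **Concentration–response.** The BMR is one MAD (scaled by the same 1.4826
   constant) above the median distance of the vehicle wells. Each chemical's
   per-well distances are fitted with a ten-model family (constant, poly1,
   poly2, power, hill, gain–loss, exp2–exp5) by maximum likelihood under a
   Student-t(4) error model; the lowest-AIC converged model wins; the BMC is
   the smallest concentration at which the winning curve crosses the BMR;
   confidence limits come from a seeded bootstrap. BMCs are excluded when
   the hitcall is below 0.9, the BMC exceeds the highest tested
   concentration, or a confidence limit is missing.

## Numerical and design choices

Choices the underlying method descriptions leave open, and what this package
does:

* **Centering before curve fitting.** The model family has no intercept
  (every curve passes through 0 at concentration 0), while raw squared
  distances have a positive baseline roughly equal to the retained component
  count. Responses are therefore centered by the vehicle-well median
  distance and the crossing threshold becomes `BMR − median = 1.4826 · MAD`.
  The crossing concentration is identical to fitting raw distances against
  the raw BMR; only the constant model becomes meaningful.
* **MAD scale constant.** Defaults to 1.4826 (normal-consistency, the
  convention of `stats::mad`) in both the normalization and the BMR;
  configurable to 1. Zero-MAD or zero-SD features are dropped with a log
  entry by default (`drop_feature`); `fallback_sd` substitutes a non-robust
  SD where one exists.
* **Distance convention.** Squared Mahalanobis form, the scale produced by
  `stats::mahalanobis`; a square-root option exists. The covariance is
  estimated from all wells (not vehicle wells only) with the n−1
  denominator, so strong actives inflate variance along their own shift
  direction and partially self-normalize — a property of the published
  workflow that both the pipeline and the simulation oracle reproduce.
* **Error model.** Student-t with 4 degrees of freedom and a fitted scale, a
  robust likelihood that tolerates occasional outlier wells; Gaussian by
  config. The scale has a small positive floor so that noise-free fixtures
  remain finite.
* **Continuous hitcall.** `hitcall = P1 · P2 · P3` with: P1, the probability
  that at least one concentration's median response exceeds the cutoff
  (t(4) tail using the winner's error scale over the per-concentration
  median's standard error); P2, the probability that the winner's top
  exceeds the cutoff (delta-method standard error of the top from the
  numerical Hessian at the optimum, with the fitted scale as fallback); P3,
  one minus the Akaike weight of the constant model against the best
  converged non-constant model. The published workflow's 0.9 threshold is
  applied to this product.
* **BMC root finding.** Log-grid scan (1,000 points) from a search floor of
  (lowest tested concentration)/100 to the top concentration, refined by
  `uniroot` to ~1e−7 relative tolerance. A curve already above the BMR at
  the floor reports the floor with flag `below_search_floor` rather than
  extrapolating further; no crossing reports an absent BMC.
* **Bootstrap CIs.** Nonparametric resampling of wells within concentration
  groups, 500 resamples by default, winner-only warm-started refits,
  percentile 95% limits. A resample without a crossing contributes a
  missing value; more than 50% missing makes the limit absent, which then
  triggers the missing-CI exclusion. Fully seeded.
* **Tie-breaks.** Equal AICs resolve in the fixed family order, making
  selection invariant to the order models were fitted in.

## The synthetic plate generator

The generator states the experimental world the analysis assumes, with
implanted ground truth, so every stage is verifiable at desk scale:

* **Layout** (per plate): columns 1–3, 4–6, 7–9 hold three test chemicals in
  triplicate (adjacent replicate columns); column 10 an inert
  negative-control series ("sorbitol-like", top 25 µM); column 11 a
  cytotoxic-control series ("staurosporine-like", top 0.5 µM); column 12
  eight solvent wells. Eight concentrations per series, spaced by a half-log
  unit with the top in row A — 8 + 8 + 8 + 72 = 96 wells. A default batch is
  four such plates with twelve distinct test chemicals.
* **Counts.** Negative binomial (size 60, giving ~13% CV) around a mean of
  1,200 cells in a row-A vehicle well, declining 3% per row from A to H —
  the systematic seeding gradient manual multichannel pipetting produces.
  Cytotoxicity multiplies the expectation by a declining Hill survival
  factor and affects counts only.
* **Features.** Category-block equicorrelated normals (default 120 features
  in 49 categories, within-category correlation ρ = 0.5; a heavy-tail t(5)
  option exists for robustness checks). Active chemicals shift their
  affected features by `E · c^h / (AC50^h + c^h)` in units of the cell-level
  noise SD. Defaults implant, per plate, one strong active (E = 1, three
  categories), one moderate active (E = 0.4, two categories) and one inert
  test chemical, with AC50s varying across plates and disjoint affected
  categories.
* **Density–morphology coupling.** All features of a well are shifted by
  `0.15 · log(n_w / 1200)`: wells with fewer cells look systematically
  different, the mechanism the background-variability study probes. This
  also means cytotoxic series acquire a real phenotype through their count
  reduction — deliberately, since partially toxic wells do look different;
  the implanted-inert test chemicals and the negative control have no such
  coupling to concentration and remain true negatives.

What the generator does **not** emulate: spatial heterogeneity within a
well, batch/plate random effects, non-Gaussian feature marginals beyond the
t(5) option, feature-specific variances, or edge effects. A green test
therefore establishes correctness of the computational pipeline under its
own stated assumptions, not robustness to every artifact of real screens.

## The analytic BMC oracle

Acceptance-level verification compares the full pipeline against an
independent implementation that never touches the production code path. The
oracle pushes the *expected* generated data through the normalization and
distance geometry in closed form:

* the sampling SD of a well median of *n* cells is `sqrt(π/(2n))` cell-SDs,
  which fixes the expected DMSO-SD divisor;
* well-median correlations within a category are `(2/π)·asin(ρ)`
  (asymptotic correlation of sample medians of equicorrelated normals);
* squared Mahalanobis distance is affine-invariant, so PCA (which retains
  essentially all variance) can be bypassed: with `S` = covariance of the
  expected well profiles plus the average null covariance, a well with
  expected normalized shift `s` has expected elevation `sᵀ S⁻¹ s`;
* null distances are approximated by a Satterthwaite-scaled chi-square
  matched to `tr(S⁻¹V)` and `2·tr((S⁻¹V)²)`, from which the median and MAD
  give the analytic BMR;
* the oracle BMC is the bisection root of elevation = BMR − median on a
  ≥500-point log grid (relative tolerance 1e−6).

Across 20 seeded default batches the median ratio of the pipeline's BMC to
the oracle BMC for implanted actives must lie in [0.5, 2], and implanted
inerts must yield no retained BMC in at least 90% of series; both are
asserted in `tests/testthat/test-acceptance.R`. One stated scale-equivariance
property deserves a note: doubling a chemical's AC50 doubles its oracle BMC
only when the tested concentration range is rescaled with it, because the
covariance is estimated from all wells and therefore depends on where the
tested grid samples the Hill curve. The tests rescale the world accordingly.

## Background variability of a DMSO-only plate

To reproduce the reference-placement study, a plate treated only with
solvent is re-normalized 21 times: once with all 96 wells as the reference
("whole plate", centroid = plate mean) and once for each of the 8 rows and
12 columns designated as the solvent control. PCA is refitted within every
iteration (each is a full re-normalization), distances are recomputed from
the reference centroid, and distance is regressed on per-well cell count by
OLS. Under the generator's count gradient and density coupling the
whole-plate reference shows a significantly negative slope (wells with
fewer cells look like phenotypic outliers), while localized row/column
references absorb most of the positional signal: the pooled 20-iteration
adjusted R² falls below the whole-plate value. Both directions are asserted
in the acceptance suite. With squared distances the relationship is
heteroscedastic and mildly nonlinear; OLS is retained as the method under
study, not as the optimal estimator.

## Runtime notes

The 20-batch recovery criterion runs the full pipeline on ~1.6M simulated
cells per batch; to stay inside its stated 10-minute budget the acceptance
test uses 100 bootstrap resamples instead of the default 500 (the CIs feed
only the exclusion rules there). `normalize_batch()` exploits the fact that
a positive-slope affine transform commutes with the median: raw cells are
aggregated to well medians once and the cell-level normalization is applied
to the medians, which is exactly equivalent to the operation-by-operation
path (asserted in the suite) and an order of magnitude faster.

## Known limitations

* The hitcall components are this package's concrete reading of the
  published continuous-hitcall construction; absolute hitcall values near
  the 0.9 threshold may differ from other implementations even when BMCs
  agree.
* Categorical BMCs are supported but default off; the 96-well study is
  global-distance first.
* No administered-equivalent-dose extrapolation, no feature-level
  concentration–response modeling, no plate-position correction factors —
  all are out of scope.
* With a single 96-well plate per batch the covariance of the retained
  scores rests on 96 observations; the per-plate mode exists to study
  exactly this instability, not to recommend it.
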
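# htppbmc

Phenotypic profiling distances and benchmark concentrations for 96-well
Cell Painting screens.

## The problem

High-throughput phenotypic profiling (HTPP / Cell Painting) measures ~1,300
morphological features per cell after chemical exposure and asks, per
chemical, *at what concentration does the cell phenotype depart from the
solvent-control phenotype?* In large screening facilities this is done in
384-well plates with automated dispensing; medium-throughput labs run the
same assay in 96-well plates with manual pipetting, which brings smaller
batches, fixed (non-randomized) plate layouts, and visible positional
effects such as a declining cell-count gradient across rows. `htppbmc`
implements the complete computational side of that workflow for analysts
working with per-cell feature exports:

* plate-map / cell-table / feature-catalog ingestion (plain CSV);
* well-level QC (≥100 analyzable cells; ≤50% count reduction vs. the median
  of the vehicle wells, strict inequalities);
* three-step DMSO-referenced normalization
  `z = (x − med_f)/(1.4826·MAD_f)` → well medians `m_{w,f}` → division by the
  vehicle-well SD, giving the normalized profile `m̃_{w,f}`;
* PCA (centered, unit-scaled) keeping the components that explain 95% of the
  variance, and squared Mahalanobis distances
  `D_w = (t_w − μ)ᵀ Σ⁺ (t_w − μ)` from the DMSO centroid `μ`, with `Σ`
  estimated from all wells and inverted by generalized inverse — globally or
  per feature category;
* concentration–response modeling of `D_w` with the ten-model family
  (constant, poly1, poly2, power, hill, gain–loss, exp2–exp5) under a
  robust t(4) likelihood, AIC winner selection, continuous hitcall,
  benchmark concentration at the BMR
  `median(D_DMSO) + 1.4826·MAD(D_DMSO)`, bootstrap 95% confidence limits,
  and the standard exclusion rules (hitcall < 0.9, BMC above the top tested
  concentration, missing confidence limit);
* a background-variability study for DMSO-only plates: 20 row/column
  reference re-normalizations plus the whole-plate reference, and OLS
  regression of distance on per-well cell count;
* a synthetic plate generator with implanted ground truth (Hill-shaped
  feature shifts, cytotoxic count reduction, row count gradient,
  density–morphology coupling) and an independent analytic oracle for the
  true BMC.

See `vignettes/htppbmc-methods.Rmd` for the model, assumptions, and every
numerical choice.

## Worked example

Simulate a default four-plate batch (twelve test chemicals, two controls,
~1,200 cells per vehicle well, 120 features in 49 categories) and run the
pipeline:

```r
library(htppbmc)

cfg  <- sim_config(seed = 42)
gen  <- generate_batch(cfg)
nb   <- normalize_batch(gen$batch)            # QC + 3-step normalization
sp   <- fit_pca(nb$profile)                   # 95% variance PC space
d    <- mahalanobis_distances(sp, nb$profile) # squared distances vs DMSO
fits <- fit_batch_distances(d, n_boot = 100, seed = 42)

print(sp)
fits[chemical %in% c("chem01", "chem02", "chem03", "sorbitol", "staurosporine"),
     .(chemical, model, hitcall = round(hitcall, 2), bmr = round(bmr, 1),
       bmc = signif(bmc, 3), bmcl = signif(bmcl, 3), bmcu = signif(bmcu, 3),
       excluded, reason)]
```

```
<pc_space> 376 wells x 120 features; k = 62 (95.2% variance)
        chemical    model hitcall   bmr    bmc    bmcl   bmcu excluded      reason
1:        chem01     exp5    0.96  66.1 0.9470 0.78100 1.0100    FALSE        <NA>
2:      sorbitol constant    0.04  66.1     NA      NA     NA     TRUE low_hitcall
3:        chem02     exp4    0.99  66.1 0.4540 0.00287 1.4300    FALSE        <NA>
4:        chem03     exp4    0.30  66.1     NA      NA     NA     TRUE low_hitcall
5: staurosporine    poly1    0.97  66.1 0.0221 0.01200 0.0298    FALSE        <NA>
```

Reading this: 376 of 384 wells passed QC (the cytotoxic control kills the
high-concentration wells); 62 principal components carry 95% of the
variance, so a vehicle well's squared distance sits near 62 and the BMR of
66.1 is one scaled MAD above the vehicle median. `chem01` — implanted as a
strong active with AC50 1 µM — gets a winning curve crossing the BMR at
0.95 µM (CI 0.78–1.01); its analytic oracle BMC is 0.96 µM
(`oracle_bmc(cfg)`). The implanted-inert `chem03` and the sorbitol-like
negative control are excluded on hitcall, while the staurosporine-like
cytotoxic control is flagged active at 0.022 µM through the
density–morphology coupling of its surviving, partially depleted wells.

The background study on a DMSO-only plate:

```r
g  <- generate_dmso_plate(sim_config(seed = 500))
bg <- background_variability(g$batch)
bg$whole_plate$t_value       # negative: fewer cells => larger distance
bg$pooled$adj_r_squared      # < bg$whole_plate$adj_r_squared
```

## Command line

```sh
Rscript inst/cli/htpp.R simulate  --out-dir sim --seed 7
Rscript inst/cli/htpp.R run-all   --out-dir out --seed 7      # simulate+analyze
Rscript inst/cli/htpp.R fit       --platemap sim/platemap.csv \
        --cells sim/cells_plate1.csv,sim/cells_plate2.csv --out-dir out
Rscript inst/cli/htpp.R background --platemap dmso_map.csv --cells dmso_cells.csv --out-dir bg
```

Outputs are CSVs (normalized profiles, exclusion log, distances, fit table,
heatmap grids) plus a `manifest.json` recording the fully resolved, seeded
configuration. Exit codes: 0 ok, 1 user error, 2 internal error.

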
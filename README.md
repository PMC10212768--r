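# mmpt — ex vivo drug-response profiling for multiple myeloma

`mmpt` is an R package for the analysis layer of image-based ex vivo drug
screening (pharmacoscopy) of multiple myeloma bone-marrow samples. Patient
bone-marrow mononuclear cells are seeded on 384-well plates coated with a
clinical drug panel, imaged, and segmented into single cells with class
labels (plasma/myeloma, T cell, monocyte, other), marker intensities,
positions and CNN latent features. From such single-cell tables and plate
layouts the package computes:

- **Drug-response scores.** For target population *X*,
  `RCF = f_X(well) / mean f_X(matched controls)` and
  `PCY = 1 − mean(RCF over replicates)`; positive PCY is on-target
  depletion. Includes replicate QC, cross-validated LASSO imputation of
  missing responses (visualization only, masked downstream) and elastic-net
  (α = 0.5) protein predictor rankings.
- **PhenoGroups.** Bone-marrow composition modes from spectral clustering
  (k = 15) of selected latent features, k-NN label propagation,
  control-well composition vectors, correlation similarity and a
  3-group dendrogram cut (PG1 = most myeloma-rich).
- **Proteotype integration.** Discovery Spearman associations of protein
  abundance with myeloma morphology abundance (signed log10 p, Storey
  q-values), paired big/small validation fold changes, the quadrant
  signature (p < 0.05, |log2FC| > 0.3) with Fisher concordance,
  hypergeometric gene-set enrichment, and residualized drug–protein
  correlation networks (|ρ| > 0.585, p < 0.05, top-2/bottom-2 per drug).
- **scRNA-seq scoring.** QC (≥ 300 non-Ig UMIs, ≤ 50% mitochondrial, zero
  exclusion-marker counts) and per-cell big-like signature-ratio scores
  with per-patient fractions.
- **Cytokine panels.** Detection-limit handling and two-step z
  normalization.
- **Clinical outcomes.** Feature–drug ANOVA/t-test association networks
  with resampling stability, iPCY (sum of ex vivo scores matching the
  patient's next clinical regimen), mean-threshold sensitivity
  stratification, and Kaplan–Meier / log-rank / O-E hazard-ratio analysis
  of time to next treatment.
- **A synthetic cohort generator** (cells, plates, proteomes, scRNA
  counts, cytokines, clinical outcomes) with known ground truth, so the
  entire pipeline is testable without patient data.

See `vignettes/mmpt-methods.Rmd` for the models, assumptions, parameter
defaults and design decisions.

## Worked example

```r
library(mmpt)

co <- generate_cohort(cohort_config(
  n_samples = 4, n_cells_per_well = 1300, n_latent_features = 0,
  n_concentrations = 1, seed = 3))

drm <- drug_response_matrix(co$cells, co$layout)
round(drm$pcy[, 1:5], 2)
#>      BOR  CFZ  LEN  POM  DEX
#> S01 0.11 0.38 0.19 0.19 0.32
#> S02 0.20 0.44 0.23 0.19 0.26
#> S03 0.19 0.39 0.24 0.23 0.62
```

Each entry is a PCY score: sample S03's myeloma cells are depleted ~62%
relative to DMSO controls by dexamethasone ex vivo, S02's only ~26%. The
fourth sample was drawn from the myeloma-poor composition mode and is
excluded by replicate QC (low tumor content makes its replicates
discordant), mirroring the real exclusion criterion. The closed-form
oracle for the generator's planted kill fractions,
`expected_pcy_matrix(co$config, co$truth$true_kill_fraction)`, reproduces
the measured matrix with mean absolute deviation 0.02 at 1,300 cells/well
— exactly what acceptance criterion 2 asserts.

Integrated ex vivo sensitivity per patient (sum of scores matching the
next clinical regimen; imputed entries never contribute):

```r
clin <- co$clinical
ipcy <- vapply(seq_len(nrow(clin)), function(i) {
  s <- clin$sample_id[i]
  if (!s %in% rownames(drm$pcy)) return(NA_real_)
  compute_ipcy(drm$pcy[s, ], clin$next_regimen[i],
               co$config$drug_panel, drm$imputed[s, ])$ipcy
}, numeric(1))
round(ipcy, 2)
#> [1] 0.52 0.74 0.43   NA
```

At cohort scale, `stratify_by_ipcy()` labels patients sensitive/resistant
around the subcohort mean iPCY and `km_logrank()` returns the Kaplan–Meier
curves, log-rank p and O/E hazard ratio for time to next treatment; the
generator plants a true hazard ratio of 4 on centered iPCY by default, and
the calibration test (acceptance criterion 6) recovers median O/E
estimates near 3.1 with ≥ 75% log-rank power at n = 34.

## Command line

```sh
Rscript inst/cli/mmpt.R simulate --config cohort.json --out DIR --seed 7
Rscript inst/cli/mmpt.R run-all  --config cohort.json --out DIR
```
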
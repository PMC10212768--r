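---
title: "Methods and design of the mmpt pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the mmpt pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mmpt` implements the analysis layer of an image-based ex vivo drug-response
(pharmacoscopy) study of multiple myeloma bone marrow: single-cell phenotype
tables from 384-well screening plates are turned into drug-response scores,
cohort-level bone-marrow composition modes, proteotype associations, scRNA
signature scores, cytokine profiles and survival stratifications. Raw image
segmentation and the CNN classifiers that produce cell classes at full scale
are out of scope; the package consumes their *outputs* (class labels with
confidences, latent features, marker intensities) and provides a
marker-gating + size-cutoff stand-in classifier for feature tables that lack
CNN labels.

Because the patient cohort itself is not distributable, the package ships a
synthetic cohort generator with known ground truth. Every downstream claim
the test suite makes is therefore a claim about recovery of *planted*
structure, not about reproducing the original cohort's numbers.

# The drug-response model

For a treated well and a target population $X$ (myeloma cells by default),
the relative cell fraction is

$$\mathrm{RCF} = \frac{f_X(\text{well})}{\overline{f_X}(\text{controls})},$$

where the controls are the same-plate isotype wells for pure antibody
treatments and the DMSO wells for everything else (including antibody-drug
combinations). The PCY score per treatment is $1 - \overline{\mathrm{RCF}}$
over technical replicates; positive values mean on-target depletion.

Two consequences of this definition are worth spelling out because the test
oracles rely on them:

* Control wells evaluated against their own mean have mean RCF exactly 1,
  so the PCY of the control condition is identically 0.
* On-target killing shrinks the well total, which *raises* the surviving
  target fraction: with composition $m$ and per-subpopulation survival
  $s$, the expected PCY is $1 - s_X / \sum_j m_j s_j$, which is *below*
  the kill fraction $1 - s_X$ (e.g. 0.375 for a 50% kill at 40% myeloma
  content). `expected_pcy_matrix()` is this closed form and serves as the
  composition oracle.

The reported concentration defaults to the middle of the tested series; the
per-concentration table is retained. Replicate QC computes the mean pairwise
Pearson correlation of replicate-wise $1-\mathrm{RCF}$ vectors across
treatments (replicate pairs sharing fewer than five treatments are ignored)
and excludes samples below 0.5 — the source protocol excludes samples for
"too high technical variability" without printing a cutoff, so the threshold
is configurable.

# Imputation and predictor ranking

Missing PCY entries can be inferred for visualization by LASSO on the
measured drug columns (or a proteome), with a 100-value $\lambda$ scan
minimizing 10-fold cross-validated Gaussian deviance; only models whose
training-set Pearson correlation reaches 0.8 impute anything. Imputed
entries carry a mask and are excluded from every downstream statistic
(associations, networks, ANOVA, iPCY, survival) — the mask-propagation test
poisons imputed entries with absurd values and asserts bit-identical
downstream results. Elastic net ($\alpha = 0.5$, same CV machinery) ranks
protein predictors per drug; the top-three positive and negative nonzero
coefficients are reported.

# PhenoGroups

Latent-feature clustering proceeds as: (1) feature selection by PCA on
standardized features, scoring feature $j$ with the variance-weighted
absolute loadings $\lambda_1 |l_{1j}| + \lambda_2 |l_{2j}|$ and keeping the
top 100 — the source describes "highest contribution in PC1 and PC2" without
a formula, and variance weighting is the standard contribution analog;
(2) spectral clustering (symmetrized 15-NN graph, normalized-Laplacian
embedding via ARPACK, seeded k-means, $k = 15$) of a training subsample
balanced per sample and class; (3) k-NN propagation ($k = 15$, standardized
Euclidean distance, ties broken by the nearest neighbor) to all control
cells; (4) per-sample composition over subclusters from DMSO wells only;
(5) Pearson correlation of composition rows, average-linkage clustering of
$1 - \mathrm{cor}$, dendrogram cut into 3 groups. Groups are labelled
PG1..PG3 by descending myeloma-subcluster load so PG1 is always the
myeloma-rich mode. Training standardization parameters are reused at
propagation time (the source leaves this open; standardizing once avoids
leaking held-out moments into the model).

# Proteotype integration

Raw abundances are log10-transformed, each protein's lowest 5% of values is
masked as "low-abundant" (the source sets low-abundant values to NaN without
defining the floor; a per-protein quantile is robust to global abundance
differences), then z-scored across proteins and across samples, in that
order. Discovery associations are Spearman correlations of protein
abundance with the fraction of big cells among plasma cells; p-values use
exact permutation enumeration for $n \le 8$ and the t approximation
otherwise, with Storey q-values (smoother-based $\pi_0$ over
$\lambda = 0.05..0.95$). The validation arm is the paired big/small
fold-change analysis with a paired t-test. The signature quadrant rule is:
discovery $p < 0.05$ with matching sign *and* validation
$|\log_2 FC| > 0.3$ (strict) — the source sentence assigns both cutoffs to
the validation cohort, an evident typo contradicted by its own figure-axis
annotations, so the p cutoff is applied to discovery. Fisher's exact test on
the discovery-sign x validation-sign table of cutoff passers quantifies
concordance. Drug-protein networks use residual expression after per-protein
OLS regression on myeloma content, select nodes at $|\rho| > 0.585$,
$p < 0.05$ plus each drug's top-two/bottom-two, restrict edges to a
user-supplied interaction list, and drop isolated nodes.

# scRNA and cytokines

QC keeps cells with $\ge 300$ non-immunoglobulin UMIs, $\le 50\%$
mitochondrial content and zero counts on the seven exclusion markers
(S100A8, CD14, CD3D, CD3E, TRAC, COL1A2, C1QA). The score-based cell-type
filtering of the original workflow is *not* reproduced: its gene sets and
score cutoffs are not quantified in the source, while the marker rule is —
so the marker rule alone is implemented, which is the conservative subset.
The big-like score is the ratio of mean up-signature to mean down-signature
expression on CP10K log1p values (the source does not state its per-cell
normalization; library-size normalization is the field default and is
recorded in output metadata), with a $10^{-9} \cdot$ (global mean)
pseudocount. Cells are big-like above the *median* score by default; the
fixed ratio > 5 used in one figure is available as `rule = "fixed_ratio"`
because the two rules genuinely disagree in the source and neither can be
declared canonical. Cytokines: below-LOD entries become missing, above-max
entries take the cytokine's cohort maximum, then log10, z per cytokine
across samples, z per sample across cytokines.

# Clinical outcomes

Feature-drug association edges require one-way ANOVA *and* a two-group
t-test (extreme-mean levels for multi-level features) both below 0.01, with
stability measured over 100 seeded leave-20%-out resamples. iPCY sums the
non-imputed PCY scores of every tested treatment whose component set is a
subset of the patient's next clinical regimen (so a tested combination
counts in addition to its singles, matching the multi-row-per-patient
bookkeeping of the source; exact-set matching is available), after alias
normalization (corticosteroid synonyms map to the tested steroid token).
Patients are `sensitive` iff iPCY strictly exceeds their subcohort mean.
Kaplan-Meier curves come from the product-limit estimator; the log-rank p
from the Mantel-Cox chi-square; the hazard ratio is the O/E form
$\mathrm{HR} = (O_1/E_1)/(O_2/E_2)$ with CI
$\exp(\log \mathrm{HR} \pm 1.96\sqrt{1/E_1 + 1/E_2})$. The O/E estimator is
known to shrink large effects toward the null (a true HR of 4 yields a
median estimate near 3.1 in the calibration tests); the Cox model is the
cross-check used to validate the *generator* itself.

# The synthetic world

The generator draws, per sample, a 384-well plate (randomized well
positions; three compound / four antibody replicates; DMSO and isotype
controls), Poisson well occupancies around 1,300 cells (a 10x reduction of
the full-scale seeding density, keeping the default suite inside minutes),
multinomial subcluster compositions from one of three planted modes, and
binomial drug survival per subcluster. Latent features are Gaussian
mixtures with one component per subcluster, centroids mutually orthogonal
at distance 6 (in within-cluster-sd units); marker log-intensities sit 1.5
log10 units (6 sd at sd 0.25) above background for positive channels.
Diameters are 14 ± 1 um (big/myeloma) vs 8.5 ± 1 um (small). The proteome
plants signature proteins at population correlation 0.8 with the myeloma
fraction and ±0.8 log2 validation fold changes over 4 pairs with 10% MCAR
missingness; survival times are exponential with log-hazard linear in
centered iPCY and independent exponential censoring at 20%.

What the generator does **not** emulate: staining batch effects, spatial
well-edge artifacts, segmentation errors, cell-cycle or doublet structure in
scRNA counts, protein-protein correlation beyond the planted axes, or
informative censoring. A green suite therefore establishes that the
implementation recovers planted structure at realistic sizes and noise —
not that it reproduces any clinical cohort's numbers.

# Numerical choices and edge cases

* Positivity thresholds: KDE valley between the two main modes of the
  log10-intensity density, falling back to mean + 2 sd (flagged) when the
  density is effectively unimodal (a valley is accepted only if it dips
  below 80% of the lower mode).
* Gating needs marker modes well clear of the cutoff: with modes 6 sd
  apart and the cutoff at the midpoint, ~0.1% of cells still cross, so the
  exact-recovery test uses 6 sd from cutoff to each mode.
* Spearman p floored at 1e-300 before signed log10.
* Undefined correlations (constant composition rows) become 0 with a
  warning; degenerate Fisher tables return p = 1 with a warning; an
  all-zero paired-difference vector reports p = 1.
* Contact scoring uses center-to-center distance <= 15 um by default (about
  the sum of two typical cell radii); the grid spatial index is asserted
  exactly equal to the brute-force pairwise check.
* All CV fold assignments, subsamples, spectral embeddings and k-means runs
  consume explicit seeds; reruns of the pipeline are byte-identical.
* The pipeline configuration is JSON (no YAML parser is available in the
  supported dependency set); the contract — defaults filled, range
  validation with field paths, unknown keys preserved — is unchanged.

# Known limitations

The stand-in gating classifier cannot reproduce CNN-grade morphology
classification on real images; it exists to keep the pipeline runnable on
plain feature tables. The acceptance suite's tolerance bands are properties
of the planted world (sampling noise at 1,300 cells/well, 3 replicates),
not instrument specifications. Survival analysis is two-group only; no
covariate-adjusted Cox modeling is exposed.
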
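# Shared fixture builders. Everything is generated in code at test time;
# sizes are desk-scale (see the methods vignette on scaling).

# A small cohort with a one-drug panel, used where drug identity is
# irrelevant (phenotyping / phenogroup tests).
tiny_panel <- function() {
  data.frame(treatment = "BOR", drug_class = "compound", components = "BOR",
             stringsAsFactors = FALSE)
}

small_cohort <- function(n_samples = 4, n_cells_per_well = 400,
                         n_latent_features = 0, seed = 1, ...) {
  generate_cohort(cohort_config(
    n_samples = n_samples, n_cells_per_well = n_cells_per_well,
    n_latent_features = n_latent_features, n_concentrations = 1,
    n_proteins = 60, n_signature_proteins = 10, n_dmso_wells = 4,
    seed = seed, ...))
}

# Gaussian blobs with known labels, for clustering tests.
make_blobs <- function(k, n_per, dim, sep = 6, seed = 1) {
  set.seed(seed)
  mu <- matrix(rnorm(k * dim), k)
  if (dim >= k) mu <- t(qr.Q(qr(t(mu)))[, seq_len(k)])
  else mu <- mu / sqrt(rowSums(mu^2))
  mu <- mu * sep / sqrt(2)
  X <- mu[rep(seq_len(k), each = n_per), ] +
    matrix(rnorm(k * n_per * dim), k * n_per)
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

# Minimal well of cells with positions and subtype labels, for interaction
# scoring.
make_well_cells <- function(n_tumor, n_effector, seed = 1, size = 1000) {
  set.seed(seed)
  n <- n_tumor + n_effector
  data.frame(
    sample_id = "S01", well_id = "A01",
    x_um = runif(n, 0, size), y_um = runif(n, 0, size),
    cell_class = rep(c("plasma", "t_cell"), c(n_tumor, n_effector)),
    plasma_subtype = rep(c("myeloma", "none"), c(n_tumor, n_effector)),
    t_subtype = rep(c("none", "activated"), c(n_tumor, n_effector)),
    stringsAsFactors = FALSE
  )
}
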
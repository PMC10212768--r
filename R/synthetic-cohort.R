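#' Default subcluster catalogue for the synthetic cohort
#'
#' Eight phenotypic subclusters nested within the four exclusive cell
#' classes used by the imaging pipeline (plasma, T cell, monocyte, other).
#' The two plasma subclusters carry the big (myeloma) / small morphology
#' split; the two T-cell subclusters carry the activated / conventional
#' split. The `kill_class` column is the resolution at which drug effects
#' act (myeloma and small plasma cells can be depleted differentially).
#'
#' @param n_per_class Named integer vector: subclusters per cell class
#'   (default 2 each, 8 total). Within plasma, odd subclusters are
#'   `myeloma` (big) and even ones `small`; within T cells the first is
#'   `activated`, the rest `conventional`.
#' @return data.frame with columns `subcluster`, `cell_class`,
#'   `plasma_subtype`, `t_subtype`, `kill_class`.
#' @export
subcluster_catalogue <- function(n_per_class = c(plasma = 2L, t_cell = 2L,
                                                 monocyte = 2L, other = 2L)) {
  stopifnot(all(n_per_class >= 1),
            setequal(names(n_per_class),
                     c("plasma", "t_cell", "monocyte", "other")))
  cls <- rep(c("plasma", "t_cell", "monocyte", "other"),
             n_per_class[c("plasma", "t_cell", "monocyte", "other")])
  within_idx <- unlist(lapply(
    n_per_class[c("plasma", "t_cell", "monocyte", "other")], seq_len))
  plasma_subtype <- ifelse(cls != "plasma", "none",
                           ifelse(within_idx %% 2L == 1L, "myeloma", "small"))
  t_subtype <- ifelse(cls != "t_cell", "none",
                      ifelse(within_idx == 1L, "activated", "conventional"))
  data.frame(
    subcluster = seq_along(cls),
    cell_class = cls,
    plasma_subtype = plasma_subtype,
    t_subtype = t_subtype,
    kill_class = ifelse(plasma_subtype == "myeloma", "myeloma",
                 ifelse(plasma_subtype == "small", "small_plasma", cls)),
    stringsAsFactors = FALSE
  )
}

#' Default bone-marrow composition modes
#'
#' Three sample-level composition modes over the eight subclusters,
#' emulating the myeloma-rich, T-cell-rich and heterogeneous bone-marrow
#' states the cohort-level clustering recovers. Rows sum to 1.
#' @return numeric matrix, modes x subclusters.
#' @export
default_phenogroup_modes <- function() {
  m <- rbind(
    mode1 = c(0.40, 0.10, 0.08, 0.12, 0.08, 0.07, 0.08, 0.07),
    mode2 = c(0.10, 0.10, 0.20, 0.25, 0.10, 0.10, 0.08, 0.07),
    mode3 = c(0.05, 0.10, 0.08, 0.07, 0.15, 0.15, 0.20, 0.20)
  )
  stopifnot(all(abs(rowSums(m) - 1) < 1e-12))
  m
}

#' Default ex vivo drug panel
#'
#' A small clinically motivated panel: proteasome inhibitors, IMiDs,
#' steroids, antibodies and one combination, with replicate counts per the
#' screening design (three for compounds, four for antibodies).
#' @return data.frame with `treatment`, `drug_class`, `components`.
#' @export
default_drug_panel <- function() {
  data.frame(
    treatment  = c("BOR", "CFZ", "LEN", "POM", "DEX", "VEN",
                   "DARA", "ELO", "BOR+DEX"),
    drug_class = c("compound", "compound", "compound", "compound",
                   "compound", "compound", "antibody", "antibody",
                   "combination"),
    components = c("BOR", "CFZ", "LEN", "POM", "DEX", "VEN",
                   "DARA", "ELO", "BOR+DEX"),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic-cohort configuration
#'
#' Collects and validates all parameters of the synthetic world: composition
#' modes, drug panel, per-(treatment, kill-class, sample) kill fractions,
#' marker/latent distributions, plate design, proteome, scRNA, cytokine and
#' survival settings. The seed fully determines every generated table.
#'
#' Defaults describe a desk-scale cohort: 1,300 cells per well (a 10x
#' reduction of the 13,000-cell seeding density, keeping runtime in minutes),
#' three concentrations, three compound / four antibody replicates, DMSO and
#' isotype controls on every plate.
#'
#' @param n_samples Number of bone-marrow samples.
#' @param n_cells_per_well Mean cells seeded per well (Poisson).
#' @param n_latent_features Latent feature dimensionality (0 disables latent
#'   feature columns; the full-scale CNN latent space has 512).
#' @param phenogroup_modes Matrix of composition vectors (modes x
#'   subclusters), rows summing to 1.
#' @param mode_assignment Integer vector of length `n_samples` mapping each
#'   sample to a mode row; default cycles through modes equally.
#' @param drug_panel data.frame as [default_drug_panel()].
#' @param n_concentrations Concentrations per treatment (default 3).
#' @param kill_fractions Either `NULL` (drawn from the defaults below), a
#'   matrix treatments x kill-classes (recycled across samples), or a 3-d
#'   array treatments x kill-classes x samples. Values in `[0, 1]`.
#' @param kill_sample_sd Per-sample logit-scale jitter applied when kill
#'   fractions are drawn automatically.
#' @param replicate_noise_sd Additional per-well logit-scale jitter on the
#'   realized kill fraction (0 = pure binomial sampling noise).
#' @param latent_separation Euclidean distance between subcluster centroids
#'   in within-cluster-sd units (default 6: cleanly separable).
#' @param marker_log_shift Log10 shift of positive vs negative marker
#'   channels (default 1.5 at sd 0.25, i.e. 6 sd separation).
#' @param contact_fraction Fraction of activated T cells placed within
#'   contact range of a myeloma cell in control wells.
#' @param treatment_contact_fraction Named vector overriding
#'   `contact_fraction` for specific treatments.
#' @param n_dmso_wells,n_isotype_wells Control wells per plate.
#' @param n_proteins,n_signature_proteins,proteome_effect,proteome_missing_rate,
#'   proteome_noise_sd,validation_log2fc,validation_pair_sd,n_drug_assoc_proteins
#'   Proteome generator settings (see [generate_proteome()]).
#' @param scrna List of scRNA generator settings or `NULL` to skip (see
#'   [generate_scrna()]).
#' @param cytokines List of cytokine generator settings or `NULL` to skip.
#' @param hazard_model List with `baseline_rate` (events/day) and `coef`
#'   (log-hazard decrease per unit of centered iPCY).
#' @param censoring_rate Expected fraction of censored patients.
#' @param catalogue Subcluster catalogue ([subcluster_catalogue()]);
#'   its row count must match the composition-vector length.
#' @param seed Integer seed; determines all outputs.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 12L,
                          n_cells_per_well = 1300L,
                          n_latent_features = 512L,
                          phenogroup_modes = default_phenogroup_modes(),
                          mode_assignment = NULL,
                          drug_panel = default_drug_panel(),
                          n_concentrations = 3L,
                          kill_fractions = NULL,
                          kill_sample_sd = 0.3,
                          replicate_noise_sd = 0,
                          latent_separation = 6,
                          marker_log_shift = 1.5,
                          contact_fraction = 0,
                          treatment_contact_fraction = NULL,
                          n_dmso_wells = 6L,
                          n_isotype_wells = 4L,
                          n_proteins = 2000L,
                          n_signature_proteins = 100L,
                          proteome_effect = 0.8,
                          proteome_missing_rate = 0.1,
                          proteome_noise_sd = NULL,
                          validation_log2fc = 0.8,
                          validation_pair_sd = 0.2,
                          n_drug_assoc_proteins = 30L,
                          scrna = NULL,
                          cytokines = NULL,
                          hazard_model = list(baseline_rate = 1 / 365,
                                              coef = log(4)),
                          censoring_rate = 0.2,
                          catalogue = subcluster_catalogue(),
                          seed = 1L) {
  phenogroup_modes <- as.matrix(phenogroup_modes)
  if (any(abs(rowSums(phenogroup_modes) - 1) > 1e-8)) {
    stop("configuration error: phenogroup_modes rows must sum to 1")
  }
  if (ncol(phenogroup_modes) != nrow(catalogue)) {
    stop("configuration error: composition vectors must have one entry per subcluster")
  }
  if (is.null(mode_assignment)) {
    mode_assignment <- rep_len(seq_len(nrow(phenogroup_modes)), n_samples)
    mode_assignment <- sort(mode_assignment)
  }
  stopifnot(length(mode_assignment) == n_samples)
  if (!is.null(kill_fractions)) {
    if (any(kill_fractions < 0 | kill_fractions > 1, na.rm = TRUE)) {
      stop("configuration error: kill fractions must lie in [0, 1]")
    }
  }
  if (n_signature_proteins > n_proteins) {
    stop("configuration error: n_signature_proteins > n_proteins")
  }
  if (hazard_model$baseline_rate <= 0) {
    stop("configuration error: baseline hazard rate must be positive")
  }
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_cells_per_well = as.integer(n_cells_per_well),
    n_latent_features = as.integer(n_latent_features),
    phenogroup_modes = phenogroup_modes,
    mode_assignment = as.integer(mode_assignment),
    drug_panel = drug_panel,
    n_concentrations = as.integer(n_concentrations),
    kill_fractions = kill_fractions,
    kill_sample_sd = kill_sample_sd,
    replicate_noise_sd = replicate_noise_sd,
    latent_separation = latent_separation,
    marker_log_shift = marker_log_shift,
    contact_fraction = contact_fraction,
    treatment_contact_fraction = treatment_contact_fraction,
    n_dmso_wells = as.integer(n_dmso_wells),
    n_isotype_wells = as.integer(n_isotype_wells),
    n_proteins = as.integer(n_proteins),
    n_signature_proteins = as.integer(n_signature_proteins),
    proteome_effect = proteome_effect,
    proteome_missing_rate = proteome_missing_rate,
    proteome_noise_sd = proteome_noise_sd,
    validation_log2fc = validation_log2fc,
    validation_pair_sd = validation_pair_sd,
    n_drug_assoc_proteins = as.integer(n_drug_assoc_proteins),
    scrna = scrna,
    cytokines = cytokines,
    hazard_model = hazard_model,
    censoring_rate = censoring_rate,
    catalogue = catalogue,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  cfg
}

kill_classes <- function(catalogue = subcluster_catalogue()) {
  unique(catalogue$kill_class)
}

# Resolve kill fractions to a treatments x kill-classes x samples array.
resolve_kill_fractions <- function(config) {
  trt <- config$drug_panel$treatment
  kc <- kill_classes(config$catalogue)
  ns <- config$n_samples
  arr <- array(0, dim = c(length(trt), length(kc), ns),
               dimnames = list(trt, kc, paste0("S", seq_len(ns))))
  kf <- config$kill_fractions
  if (is.null(kf)) {
    # Drugs mostly deplete myeloma, with weaker effects elsewhere;
    # per-sample heterogeneity on the logit scale.
    base <- matrix(0.05, length(trt), length(kc), dimnames = list(trt, kc))
    base[, "myeloma"] <- stats::runif(length(trt), 0.15, 0.65)
    base[, "small_plasma"] <- base[, "myeloma"] / 2
    for (s in seq_len(ns)) {
      jit <- stats::rnorm(length(trt), 0, config$kill_sample_sd)
      mat <- stats::plogis(stats::qlogis(pmin(pmax(base, 1e-4), 1 - 1e-4)) + jit)
      arr[, , s] <- mat
    }
  } else if (length(dim(kf)) == 3L) {
    arr[] <- kf
  } else {
    kf <- as.matrix(kf)
    stopifnot(nrow(kf) == length(trt), ncol(kf) == length(kc))
    for (s in seq_len(ns)) arr[, , s] <- kf
  }
  arr
}

well_ids_384 <- function() {
  as.vector(outer(LETTERS[1:16], sprintf("%02d", 1:24), paste0))
}

# One plate layout per sample: treatment wells (replicates x concentrations)
# plus DMSO and isotype control wells, positions randomized on A01..P24.
build_plate_layout <- function(config, sample_id) {
  panel <- config$drug_panel
  rows <- list()
  for (i in seq_len(nrow(panel))) {
    n_rep <- if (panel$drug_class[i] == "antibody") 4L else 3L
    for (conc in seq_len(config$n_concentrations)) {
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = panel$treatment[i],
        drug_class = panel$drug_class[i],
        concentration = conc,
        concentration_unit = "rel",
        replicate_index = seq_len(n_rep),
        control_type = "none",
        stringsAsFactors = FALSE
      )
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    treatment = "DMSO", drug_class = "control", concentration = 0,
    concentration_unit = "rel",
    replicate_index = seq_len(config$n_dmso_wells),
    control_type = "dmso", stringsAsFactors = FALSE
  )
  rows[[length(rows) + 1L]] <- data.frame(
    treatment = "ISO", drug_class = "control", concentration = 0,
    concentration_unit = "rel",
    replicate_index = seq_len(config$n_isotype_wells),
    control_type = "isotype", stringsAsFactors = FALSE
  )
  layout <- do.call(rbind, rows)
  ids <- well_ids_384()
  if (nrow(layout) > length(ids)) {
    stop("plate design exceeds 384 wells; shrink the panel")
  }
  layout$well_id <- sample(ids, nrow(layout))
  layout$sample_id <- sample_id
  layout[, c("sample_id", "well_id", "treatment", "drug_class",
             "concentration", "concentration_unit", "replicate_index",
             "control_type")]
}

# Subcluster centroids in latent space: mutually orthogonal random
# directions (when the dimension allows) scaled so that any two centroids
# sit exactly `separation` apart (within-cluster sd = 1).
latent_centroids <- function(n_sub, n_feat, separation) {
  if (n_feat == 0L) return(NULL)
  m <- matrix(stats::rnorm(n_sub * n_feat), n_sub, n_feat)
  if (n_feat >= n_sub) {
    m <- t(qr.Q(qr(t(m)))[, seq_len(n_sub)])
  } else {
    m <- m / sqrt(rowSums(m^2))
  }
  m * separation / sqrt(2)
}

marker_channels <- function() c("CD138", "CD319", "CD3", "CD14", "DAPI")

# Per-subcluster mean log10 intensities. Positive channels sit
# `marker_log_shift` above background (sd 0.25 => 6 sd at the default).
marker_means <- function(shift, cat_ = subcluster_catalogue()) {
  mm <- matrix(0, nrow(cat_), 5, dimnames = list(NULL, marker_channels()))
  mm[, "DAPI"] <- shift
  plasma <- cat_$cell_class == "plasma"
  mm[plasma, "CD138"] <- shift
  mm[cat_$plasma_subtype == "myeloma", "CD319"] <- shift  # big cells double-positive
  mm[cat_$cell_class == "t_cell", "CD3"] <- shift
  mm[cat_$cell_class == "monocyte", "CD14"] <- shift
  mm
}

diameter_params <- function(cat_ = subcluster_catalogue()) {
  mu <- ifelse(cat_$plasma_subtype == "myeloma", 14,
        ifelse(cat_$plasma_subtype == "small", 8.5,
        ifelse(cat_$cell_class == "t_cell", 8,
        ifelse(cat_$cell_class == "monocyte", 11, 9))))
  list(mu = mu, sd = rep(1, nrow(cat_)))
}

#' Generate a synthetic pharmacoscopy cohort
#'
#' Draws the full synthetic world described by a [cohort_config()]: per-sample
#' 384-well plates with DMSO/isotype controls, per-well single-cell tables
#' (classes, confidences, marker intensities, positions, diameters, latent
#' features with subcluster structure), a proteome with planted
#' myeloma-fraction associations, optional scRNA counts and cytokine panel,
#' and a clinical table with exponential time-to-next-treatment whose hazard
#' is linear in centered iPCY. All randomness is governed by `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `cells` (data.frame, one row per cell),
#'   `layout` (plate layouts for all samples), `proteome`, `validation`,
#'   `scrna`, `cytokines`, `clinical`, `config` and `truth` (ground-truth
#'   record: per-sample mode, per-(sample, treatment, class) kill fractions,
#'   signature proteins, big-like flags, hazard groups).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    cat_ <- config$catalogue
    n_sub <- nrow(cat_)
    sample_ids <- sprintf("S%02d", seq_len(config$n_samples))
    kf <- resolve_kill_fractions(config)
    centroids <- latent_centroids(n_sub, config$n_latent_features,
                                  config$latent_separation)
    mmeans <- marker_means(config$marker_log_shift, cat_)
    dpar <- diameter_params(cat_)

    layouts <- lapply(seq_along(sample_ids), function(s) {
      build_plate_layout(config, sample_ids[s])
    })
    layout <- do.call(rbind, layouts)
    rownames(layout) <- NULL

    cells_list <- vector("list", length(sample_ids))
    for (s in seq_along(sample_ids)) {
      sid <- sample_ids[s]
      mode_vec <- config$phenogroup_modes[config$mode_assignment[s], ]
      lay <- layouts[[s]]
      per_well <- vector("list", nrow(lay))
      for (w in seq_len(nrow(lay))) {
        n0 <- stats::rpois(1, config$n_cells_per_well)
        counts0 <- stats::rmultinom(1, n0, mode_vec)[, 1]
        trt <- lay$treatment[w]
        if (lay$control_type[w] == "none") {
          surv <- 1 - kf[trt, cat_$kill_class, s]
          if (config$replicate_noise_sd > 0) {
            kill_w <- 1 - surv
            kill_w <- pmin(pmax(kill_w, 1e-6), 1 - 1e-6)
            kill_w <- stats::plogis(stats::qlogis(kill_w) +
              stats::rnorm(length(kill_w), 0, config$replicate_noise_sd))
            surv <- 1 - kill_w
          }
          counts <- stats::rbinom(n_sub, counts0, surv)
        } else {
          counts <- counts0
        }
        if (sum(counts) == 0L) next
        sub_idx <- rep.int(seq_len(n_sub), counts)
        per_well[[w]] <- data.frame(
          well_id = lay$well_id[w],
          true_subcluster = sub_idx,
          stringsAsFactors = FALSE
        )
      }
      dfw <- do.call(rbind, per_well)
      n <- nrow(dfw)
      sub_idx <- dfw$true_subcluster
      cells <- data.frame(
        sample_id = sid,
        well_id = dfw$well_id,
        cell_id = sprintf("%s_c%07d", sid, seq_len(n)),
        cell_class = cat_$cell_class[sub_idx],
        class_confidence = stats::rbeta(n, 8, 1),
        plasma_subtype = cat_$plasma_subtype[sub_idx],
        t_subtype = cat_$t_subtype[sub_idx],
        diameter_um = pmax(stats::rnorm(n, dpar$mu[sub_idx], dpar$sd[sub_idx]), 2),
        x_um = stats::runif(n, 0, 1000),
        y_um = stats::runif(n, 0, 1000),
        true_subcluster = sub_idx,
        stringsAsFactors = FALSE
      )
      for (ch in marker_channels()) {
        cells[[ch]] <- 10^(mmeans[sub_idx, ch] + stats::rnorm(n, 0, 0.25))
      }
      cells <- plant_contacts(cells, layouts[[s]], config)
      if (config$n_latent_features > 0L) {
        lat <- centroids[sub_idx, , drop = FALSE] +
          matrix(stats::rnorm(n * config$n_latent_features), n)
        colnames(lat) <- sprintf("latent_%03d", seq_len(config$n_latent_features))
        cells <- cbind(cells, as.data.frame(lat))
      }
      cells_list[[s]] <- cells
    }
    cells <- do.call(rbind, cells_list)
    rownames(cells) <- NULL

    truth <- list(
      true_phenogroup = stats::setNames(config$mode_assignment, sample_ids),
      true_kill_fraction = kf,
      subcluster_catalogue = cat_
    )

    proteome <- generate_proteome(
      myeloma_fraction = true_fraction_big(config),
      kill_fractions = kf,
      n_proteins = config$n_proteins,
      n_signature = config$n_signature_proteins,
      effect = config$proteome_effect,
      missing_rate = config$proteome_missing_rate,
      noise_sd = config$proteome_noise_sd,
      validation_log2fc = config$validation_log2fc,
      validation_pair_sd = config$validation_pair_sd,
      n_drug_assoc = config$n_drug_assoc_proteins
    )
    truth$true_signature_proteins <- proteome$truth

    scrna <- NULL
    if (!is.null(config$scrna)) {
      scrna <- do.call(generate_scrna, config$scrna)
      truth$true_big_like <- scrna$truth$true_big_like
    }
    cytokines <- NULL
    if (!is.null(config$cytokines)) {
      cytokines <- do.call(generate_cytokines, config$cytokines)
    }

    clin <- generate_clinical(config, kf, sample_ids)
    truth$true_ipcy <- stats::setNames(clin$true_ipcy, clin$patient_id)
    truth$true_hazard_group <- stats::setNames(clin$true_hazard_group,
                                               clin$patient_id)
    clinical <- clin[, setdiff(names(clin), c("true_ipcy", "true_hazard_group"))]

    list(cells = cells, layout = layout, proteome = proteome$raw,
         proteome_validation = proteome$validation, scrna = scrna,
         cytokines = cytokines, clinical = clinical,
         config = config, truth = truth)
  })
}

# Ground-truth fraction of big (myeloma) cells among plasma cells per sample,
# from the sample's composition mode.
true_fraction_big <- function(config) {
  cat_ <- config$catalogue
  big <- cat_$plasma_subtype == "myeloma"
  small <- cat_$plasma_subtype == "small"
  vapply(config$mode_assignment, function(m) {
    v <- config$phenogroup_modes[m, ]
    sum(v[big]) / (sum(v[big]) + sum(v[small]))
  }, numeric(1))
}

# Move a fraction of activated T cells next to randomly chosen myeloma cells
# (within 0.6 * 15 um), inducing measurable cell-cell contacts.
plant_contacts <- function(cells, lay, config) {
  frac_for <- function(trt) {
    if (!is.null(config$treatment_contact_fraction) &&
        trt %in% names(config$treatment_contact_fraction)) {
      return(config$treatment_contact_fraction[[trt]])
    }
    config$contact_fraction
  }
  wells <- unique(cells$well_id)
  for (w in wells) {
    trt <- lay$treatment[match(w, lay$well_id)]
    f <- frac_for(trt)
    if (is.na(f) || f <= 0) next
    idx_w <- which(cells$well_id == w)
    eff <- idx_w[cells$t_subtype[idx_w] == "activated"]
    tum <- idx_w[cells$plasma_subtype[idx_w] == "myeloma"]
    if (length(eff) == 0L || length(tum) == 0L) next
    n_move <- round(f * length(eff))
    if (n_move == 0L) next
    mv <- sample(eff, n_move)
    anchor <- sample(tum, n_move, replace = TRUE)
    ang <- stats::runif(n_move, 0, 2 * pi)
    r <- stats::runif(n_move, 0, 9)
    cells$x_um[mv] <- cells$x_um[anchor] + r * cos(ang)
    cells$y_um[mv] <- cells$y_um[anchor] + r * sin(ang)
  }
  cells
}

#' Generate a synthetic CD138 proteotype matrix with planted structure
#'
#' Planted signature proteins covary with the per-sample myeloma fraction
#' (`abundance = effect * z(fraction) + sqrt(1 - effect^2) * noise` on the
#' log scale, i.e. `effect` is the population correlation), half up, half
#' down. A further subset covaries with the first treatment's myeloma kill
#' fraction (drug-sensitivity proteins for the network stage). Matching
#' big/small validation pairs are emitted on the log2 scale with planted
#' fold changes. Missingness is missing-completely-at-random.
#'
#' @param myeloma_fraction Per-sample fraction of big cells among plasma.
#' @param kill_fractions Optional treatments x classes x samples array.
#' @param n_proteins,n_signature Total and planted protein counts.
#' @param effect Population correlation of planted proteins with the
#'   myeloma fraction (0..1).
#' @param missing_rate MCAR missingness rate.
#' @param noise_sd Overrides the `sqrt(1-effect^2)` noise sd when non-NULL.
#' @param validation_log2fc Planted |log2 fold change| big vs small.
#' @param validation_pair_sd Per-pair noise sd (log2) in the validation set.
#' @param n_validation_pairs Number of FACS-sorted big/small pairs.
#' @param n_drug_assoc Number of planted drug-sensitivity proteins.
#' @return List: `raw` (proteins x samples, positive linear-scale, NA =
#'   missing), `validation` (list of log2-scale `big`/`small` matrices),
#'   `truth` (up/down/drug-associated protein ids).
#' @export
generate_proteome <- function(myeloma_fraction,
                              kill_fractions = NULL,
                              n_proteins = 2000L,
                              n_signature = 100L,
                              effect = 0.8,
                              missing_rate = 0.1,
                              noise_sd = NULL,
                              validation_log2fc = 0.8,
                              validation_pair_sd = 0.2,
                              n_validation_pairs = 4L,
                              n_drug_assoc = 30L) {
  if (n_signature > n_proteins) {
    stop("n_signature_proteins > n_proteins")
  }
  ns <- length(myeloma_fraction)
  prot_ids <- sprintf("P%04d", seq_len(n_proteins))
  n_up <- ceiling(n_signature / 2)
  up <- prot_ids[seq_len(n_up)]
  down <- prot_ids[n_up + seq_len(n_signature - n_up)]
  dir <- stats::setNames(rep(0, n_proteins), prot_ids)
  dir[up] <- 1; dir[down] <- -1

  z <- as.numeric(scale(myeloma_fraction))
  if (any(!is.finite(z))) z <- rep(0, ns)  # constant fraction: no signal axis
  a <- min(abs(effect), 1)
  nsd <- if (is.null(noise_sd)) sqrt(1 - a^2) else noise_sd
  signal <- outer(dir, z) * a * sign(effect + (effect == 0))
  if (effect == 0) signal[] <- 0
  logmat <- signal + matrix(stats::rnorm(n_proteins * ns, 0, 1), n_proteins) *
    ifelse(dir != 0, nsd, 1)

  drug_assoc <- character(0)
  if (!is.null(kill_fractions) && n_drug_assoc > 0) {
    free <- prot_ids[dir == 0]
    drug_assoc <- utils::tail(free, n_drug_assoc)
    kz <- as.numeric(scale(kill_fractions[1, "myeloma", ]))
    if (all(is.finite(kz))) {
      logmat[match(drug_assoc, prot_ids), ] <-
        0.8 * matrix(kz, length(drug_assoc), ns, byrow = TRUE) +
        0.6 * matrix(stats::rnorm(length(drug_assoc) * ns), length(drug_assoc))
    }
  }

  base_level <- stats::rnorm(n_proteins, 6, 1)  # log10 abundance baseline
  raw <- 10^(base_level + 0.25 * logmat)
  dimnames(raw) <- list(prot_ids, names(myeloma_fraction) %||%
                          sprintf("S%02d", seq_len(ns)))
  if (missing_rate > 0) {
    raw[stats::runif(length(raw)) < missing_rate] <- NA_real_
  }

  base2 <- stats::rnorm(n_proteins, 20, 2)  # log2 baseline, validation cohort
  half_fc <- dir * validation_log2fc / 2
  big <- matrix(base2, n_proteins, n_validation_pairs) + half_fc +
    matrix(stats::rnorm(n_proteins * n_validation_pairs, 0, validation_pair_sd),
           n_proteins)
  small <- matrix(base2, n_proteins, n_validation_pairs) - half_fc +
    matrix(stats::rnorm(n_proteins * n_validation_pairs, 0, validation_pair_sd),
           n_proteins)
  pair_ids <- sprintf("pair%d", seq_len(n_validation_pairs))
  dimnames(big) <- dimnames(small) <- list(prot_ids, pair_ids)

  list(raw = raw,
       validation = list(big = big, small = small),
       truth = list(up = up, down = down, drug_assoc = drug_assoc))
}

#' Generate synthetic plasma-cell scRNA-seq counts
#'
#' Emulates the structure of a public myeloma plasma-cell dataset: UMI
#' counts for per-patient plasma cells with immunoglobulin and mitochondrial
#' genes flagged, exclusion-marker genes present, and a planted big-like
#' subpopulation whose up-signature genes are elevated `big_fold`-fold.
#' QC violations (low-UMI, high-mito, marker-positive) are planted at
#' stated rates so the filter can be checked against exact set arithmetic.
#'
#' @param n_patients Patients; split between `relapse` and `refractory`.
#' @param cells_per_patient Mean cells per patient (Poisson).
#' @param n_genes Total genes (signature, Ig, mito, markers, background).
#' @param n_up,n_down Signature gene-list sizes.
#' @param big_fold Fold elevation of up genes in big-like cells.
#' @param big_fraction_relapse,big_fraction_refractory Mean per-patient
#'   big-like fractions per disease-state group.
#' @param frac_low_umi,frac_high_mito,frac_marker_pos Planted QC-violation
#'   rates (independent draws; overlaps arise naturally).
#' @param mean_umi Mean library size of a healthy cell.
#' @param seed Integer seed.
#' @return List: `counts` (genes x cells dgCMatrix), `genes` (flags),
#'   `cells` (patient, disease_state), `signature` (up/down gene lists),
#'   `truth` (`true_big_like` logical per cell, planted violation id sets).
#' @export
generate_scrna <- function(n_patients = 34L,
                           cells_per_patient = 300L,
                           n_genes = 600L,
                           n_up = 40L, n_down = 40L,
                           big_fold = 5,
                           big_fraction_relapse = 0.35,
                           big_fraction_refractory = 0.55,
                           frac_low_umi = 0.05,
                           frac_high_mito = 0.03,
                           frac_marker_pos = 0.02,
                           mean_umi = 2000,
                           seed = 1L) {
  with_seed(seed, {
    markers <- c("S100A8", "CD14", "CD3D", "CD3E", "TRAC", "COL1A2", "C1QA")
    n_ig <- 15L; n_mito <- 13L
    n_bg <- n_genes - n_up - n_down - n_ig - n_mito - length(markers)
    stopifnot(n_bg > 0)
    genes <- data.frame(
      gene = c(sprintf("UPG%03d", seq_len(n_up)),
               sprintf("DNG%03d", seq_len(n_down)),
               sprintf("IGHV%03d", seq_len(n_ig)),
               sprintf("MT-G%02d", seq_len(n_mito)),
               markers,
               sprintf("BG%04d", seq_len(n_bg))),
      is_immunoglobulin = rep(c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
                              c(n_up, n_down, n_ig, n_mito, length(markers), n_bg)),
      is_mitochondrial = rep(c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
                             c(n_up, n_down, n_ig, n_mito, length(markers), n_bg)),
      is_exclusion_marker = rep(c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
                                c(n_up, n_down, n_ig, n_mito, length(markers), n_bg)),
      stringsAsFactors = FALSE
    )
    g <- nrow(genes)
    up_idx <- seq_len(n_up)
    down_idx <- n_up + seq_len(n_down)
    mito_idx <- which(genes$is_mitochondrial)
    marker_idx <- which(genes$is_exclusion_marker)

    # Relative expression program of a normal plasma cell
    base_rate <- stats::rgamma(g, shape = 0.7, rate = 1) + 0.02
    base_rate[marker_idx] <- 0            # plasma cells never express these
    base_rate[mito_idx] <- base_rate[mito_idx] * 2
    base_rate[genes$is_immunoglobulin] <- base_rate[genes$is_immunoglobulin] * 20

    n_cells_pat <- stats::rpois(n_patients, cells_per_patient)
    patient_ids <- sprintf("PT%02d", seq_len(n_patients))
    state <- rep(c("relapse", "refractory"), length.out = n_patients)
    cols <- list(); cell_meta <- list(); truth_big <- list()
    cell_counter <- 0L
    for (p in seq_len(n_patients)) {
      nc <- n_cells_pat[p]
      target_big <- if (state[p] == "refractory") big_fraction_refractory
                    else big_fraction_relapse
      pf <- min(max(stats::rnorm(1, target_big, 0.08), 0.02), 0.98)
      is_big <- stats::runif(nc) < pf
      lib <- stats::rpois(nc, mean_umi)
      low <- stats::runif(nc) < frac_low_umi
      lib[low] <- stats::rpois(sum(low), 120)
      high_mito <- stats::runif(nc) < frac_high_mito
      mpos <- stats::runif(nc) < frac_marker_pos
      mat <- matrix(0L, g, nc)
      for (i in seq_len(nc)) {
        rate <- base_rate
        if (is_big[i]) rate[up_idx] <- rate[up_idx] * big_fold
        if (high_mito[i]) rate[mito_idx] <- rate[mito_idx] * 60
        if (mpos[i]) {
          mk <- sample(marker_idx, 1)
          rate[mk] <- mean(base_rate) * 5
        }
        mat[, i] <- stats::rmultinom(1, lib[i], rate)[, 1]
      }
      ids <- sprintf("cell%06d", cell_counter + seq_len(nc))
      cell_counter <- cell_counter + nc
      colnames(mat) <- ids
      cols[[p]] <- mat
      cell_meta[[p]] <- data.frame(
        cell = ids, patient = patient_ids[p], disease_state = state[p],
        planted_low_umi = low, planted_high_mito = high_mito,
        planted_marker_pos = mpos, stringsAsFactors = FALSE
      )
      truth_big[[p]] <- stats::setNames(is_big, ids)
    }
    counts <- Matrix::Matrix(do.call(cbind, cols), sparse = TRUE)
    rownames(counts) <- genes$gene
    meta <- do.call(rbind, cell_meta)
    cells <- meta[, c("cell", "patient", "disease_state")]
    list(counts = counts, genes = genes, cells = cells,
         signature = list(up = genes$gene[up_idx], down = genes$gene[down_idx]),
         truth = list(true_big_like = unlist(unname(truth_big)),
                      planted_low_umi = meta$cell[meta$planted_low_umi],
                      planted_high_mito = meta$cell[meta$planted_high_mito],
                      planted_marker_pos = meta$cell[meta$planted_marker_pos]))
  })
}

#' Generate a synthetic serum cytokine panel
#'
#' Lognormal concentrations with per-cytokine scales, a shared sample-level
#' input-abundance factor, and planted below-limit-of-detection /
#' above-maximum statuses at stated rates.
#'
#' @param n_samples,n_cytokines Panel dimensions (study scale: 48 x 64).
#' @param lod_rate,above_max_rate Status-planting rates.
#' @param seed Integer seed.
#' @return List with `concentration` (cytokines x samples) and `status`
#'   (character matrix: "ok", "below_lod", "above_max").
#' @export
generate_cytokines <- function(n_samples = 48L, n_cytokines = 64L,
                               lod_rate = 0.05, above_max_rate = 0.02,
                               seed = 1L) {
  with_seed(seed, {
    cyt <- sprintf("CYT%02d", seq_len(n_cytokines))
    smp <- sprintf("S%02d", seq_len(n_samples))
    scale_c <- stats::rnorm(n_cytokines, 2, 1)        # log10 pg/ml scales
    input_s <- stats::rnorm(n_samples, 0, 0.3)        # sample input factor
    logc <- outer(scale_c, input_s, "+") +
      matrix(stats::rnorm(n_cytokines * n_samples, 0, 0.5), n_cytokines)
    conc <- 10^logc
    dimnames(conc) <- list(cyt, smp)
    status <- matrix("ok", n_cytokines, n_samples, dimnames = dimnames(conc))
    status[stats::runif(length(conc)) < lod_rate] <- "below_lod"
    ok <- status == "ok"
    am <- stats::runif(length(conc)) < above_max_rate & ok
    status[am] <- "above_max"
    list(concentration = conc, status = status)
  })
}

# Analytic PCY for a treatment on the myeloma population: killed cells also
# shrink the well denominator, so PCY = 1 - s_my / sum_j m_j s_j.
analytic_pcy <- function(mode_vec, surv_by_subcluster, target_subclusters) {
  f_ctrl <- sum(mode_vec[target_subclusters])
  f_trt <- sum(mode_vec[target_subclusters] * surv_by_subcluster[target_subclusters]) /
    sum(mode_vec * surv_by_subcluster)
  1 - f_trt / f_ctrl
}

#' Analytic PCY scores implied by a cohort configuration
#'
#' Closed-form expected PCY per (sample, treatment) for a target population,
#' accounting for the compositional denominator (killed cells shrink the
#' total): used as the composition oracle in tests.
#'
#' @param config A [cohort_config()].
#' @param kill_fractions The resolved kill array (from the cohort `truth`).
#' @param target Kill-class of the scored population (default "myeloma").
#' @return Matrix samples x treatments of expected PCY.
#' @export
expected_pcy_matrix <- function(config, kill_fractions, target = "myeloma") {
  cat_ <- config$catalogue
  tgt <- which(cat_$kill_class == target)
  trt <- dimnames(kill_fractions)[[1]]
  out <- matrix(NA_real_, config$n_samples, length(trt),
                dimnames = list(sprintf("S%02d", seq_len(config$n_samples)), trt))
  for (s in seq_len(config$n_samples)) {
    mode_vec <- config$phenogroup_modes[config$mode_assignment[s], ]
    for (t in seq_along(trt)) {
      surv <- 1 - kill_fractions[t, cat_$kill_class, s]
      out[s, t] <- analytic_pcy(mode_vec, surv, tgt)
    }
  }
  out
}

# Clinical covariates + survival outcome for one patient per sample.
generate_clinical <- function(config, kf, sample_ids) {
  panel <- config$drug_panel
  singles <- panel$treatment[panel$drug_class != "combination"]
  regimens <- lapply(seq_along(sample_ids), function(i) {
    sample(singles, sample.int(min(3L, length(singles)), 1))
  })
  epcy <- expected_pcy_matrix(config, kf)
  ipcy <- vapply(seq_along(sample_ids), function(i) {
    matched <- match_regimen(panel, regimens[[i]])
    sum(epcy[i, matched])
  }, numeric(1))
  surv <- generate_survival(ipcy, config$hazard_model, config$censoring_rate)
  data.frame(
    patient_id = sprintf("PT%02d", seq_along(sample_ids)),
    sample_id = sample_ids,
    treatment_stage = sample(c("MM:0", "MM:1", "MM:2", "MM:3+"),
                             length(sample_ids), replace = TRUE),
    clonality = sample(c("kappa", "lambda"), length(sample_ids), replace = TRUE),
    del17p = stats::runif(length(sample_ids)) < 0.15,
    t_11_14 = stats::runif(length(sample_ids)) < 0.2,
    age = round(stats::rnorm(length(sample_ids), 65, 9)),
    active_clonal = TRUE,
    next_regimen = vapply(regimens, paste, character(1), collapse = "+"),
    subcohort = ifelse(vapply(regimens, function(r)
      any(r %in% panel$treatment[panel$drug_class == "antibody"]), logical(1)),
      "immunotherapy", "non_immunotherapy"),
    time_to_next_treatment = surv$time,
    event = surv$event,
    true_ipcy = ipcy,
    true_hazard_group = ifelse(ipcy > mean(ipcy), "sensitive", "resistant"),
    stringsAsFactors = FALSE
  )
}

#' Generate exponential time-to-next-treatment outcomes
#'
#' Event times are exponential with log-hazard linear in centered iPCY
#' (`rate = baseline * exp(-coef * (ipcy - mean(ipcy)))`: higher ex vivo
#' sensitivity means lower hazard of needing the next treatment line).
#' Censoring is independent exponential, calibrated so the expected
#' censored fraction is `censoring_rate`.
#'
#' @param ipcy Numeric vector of integrated PCY scores, one per patient.
#' @param hazard_model List with `baseline_rate` (> 0) and `coef`.
#' @param censoring_rate Expected fraction censored in `[0, 1)`.
#' @param seed Optional seed (NULL: use current RNG stream).
#' @return data.frame with `time` (days) and `event` (1 = next line started,
#'   0 = censored).
#' @export
generate_survival <- function(ipcy,
                              hazard_model = list(baseline_rate = 1 / 365,
                                                  coef = log(4)),
                              censoring_rate = 0.2,
                              seed = NULL) {
  if (hazard_model$baseline_rate <= 0) stop("negative or zero baseline rate")
  stopifnot(censoring_rate >= 0, censoring_rate < 1)
  draw <- function() {
    rate <- hazard_model$baseline_rate *
      exp(-hazard_model$coef * (ipcy - mean(ipcy)))
    t_event <- stats::rexp(length(ipcy), rate)
    if (censoring_rate > 0) {
      c_rate <- hazard_model$baseline_rate * censoring_rate / (1 - censoring_rate)
      t_cens <- stats::rexp(length(ipcy), c_rate)
    } else {
      t_cens <- rep(Inf, length(ipcy))
    }
    data.frame(time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

`%||%` <- function(a, b) if (is.null(a)) b else a
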
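#' Per-well fraction of a target cell population
#'
#' @param cells Cells of one sample.
#' @param target `"myeloma"`, `"small_plasma"`, `"plasma"`, `"t_cell"`,
#'   `"monocyte"`, `"other"` or `"activated_t"`.
#' @return Named numeric vector well_id -> fraction (NA for empty wells).
#' @export
well_class_fractions <- function(cells, target = "myeloma") {
  in_target <- switch(
    target,
    myeloma = cells$plasma_subtype == "myeloma",
    small_plasma = cells$plasma_subtype == "small",
    plasma = cells$cell_class == "plasma",
    t_cell = cells$cell_class == "t_cell",
    monocyte = cells$cell_class == "monocyte",
    other = cells$cell_class == "other",
    activated_t = cells$t_subtype == "activated",
    stop("unknown target class: ", target)
  )
  tot <- table(cells$well_id)
  hit <- tapply(in_target, cells$well_id, sum)
  frac <- as.numeric(hit[names(tot)]) / as.numeric(tot)
  stats::setNames(frac, names(tot))
}

#' Relative cell fraction (RCF)
#'
#' RCF = fraction of the target population in a treated well divided by the
#' mean fraction over matched control wells. By construction the mean RCF
#' over the control wells themselves is exactly 1.
#'
#' @param well_fraction Target-class fraction in the treated well.
#' @param control_fractions Target-class fractions of the matched control
#'   wells (isotype controls for antibody treatments, DMSO otherwise).
#' @return RCF, or NA when the control mean is zero or unavailable.
#' @export
compute_rcf <- function(well_fraction, control_fractions) {
  ctrl <- mean(control_fractions, na.rm = TRUE)
  if (!is.finite(ctrl) || ctrl == 0) return(NA_real_)
  well_fraction / ctrl
}

#' PCY drug-response scores for one sample
#'
#' Computes, per treatment and concentration, PCY = 1 - mean(RCF over
#' technical replicates) for the target population. Positive scores mean
#' on-target depletion, negative scores relative resistance. Antibody
#' treatments are normalized to the isotype controls, all other treatments
#' (including antibody-drug combinations) to DMSO. A designated reporting
#' concentration (default the middle one) is flagged.
#'
#' @param cells Cells of one sample (quality-filtered).
#' @param layout Plate layout rows for that sample.
#' @param target Target population (see [well_class_fractions()]).
#' @param reporting_concentration `"middle"` or a concentration value.
#' @return data.frame: `sample_id`, `treatment`, `drug_class`,
#'   `concentration`, `n_replicates`, `pcy`, `reported` (logical).
#' @export
pcy_scores <- function(cells, layout, target = "myeloma",
                       reporting_concentration = "middle") {
  frac <- well_class_fractions(cells, target)
  frac <- frac[layout$well_id]
  names(frac) <- layout$well_id
  dmso_mean <- mean(frac[layout$control_type == "dmso"], na.rm = TRUE)
  iso_mean <- mean(frac[layout$control_type == "isotype"], na.rm = TRUE)
  sid <- if (nrow(cells) > 0) cells$sample_id[1] else layout$sample_id[1]
  treated <- layout[layout$control_type == "none", , drop = FALSE]
  keys <- unique(treated[, c("treatment", "drug_class", "concentration")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- treated$treatment == keys$treatment[i] &
      treated$concentration == keys$concentration[i]
    ctrl <- if (keys$drug_class[i] == "antibody") iso_mean else dmso_mean
    rcf <- vapply(frac[treated$well_id[sel]], compute_rcf, numeric(1),
                  control_fractions = ctrl)
    n_ok <- sum(is.finite(rcf))
    data.frame(sample_id = sid, treatment = keys$treatment[i],
               drug_class = keys$drug_class[i],
               concentration = keys$concentration[i],
               n_replicates = n_ok,
               pcy = if (n_ok == 0) NA_real_ else 1 - mean(rcf, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$reported <- FALSE
  for (trt in unique(res$treatment)) {
    concs <- sort(unique(res$concentration[res$treatment == trt]))
    rep_conc <- if (identical(reporting_concentration, "middle")) {
      concs[ceiling(length(concs) / 2)]
    } else reporting_concentration
    res$reported[res$treatment == trt & res$concentration == rep_conc] <- TRUE
  }
  res
}

#' Drug-response matrix for a cohort
#'
#' Runs [pcy_scores()] per sample and assembles the samples x treatments
#' matrix of reported-concentration PCY scores, with an (all-FALSE) imputed
#' mask and replicate-QC flags.
#'
#' @param cells All cells (quality-filtered).
#' @param layout Full plate layout.
#' @param target Target population.
#' @param qc_threshold Minimum replicate concordance (see
#'   [replicate_qc()]); flagged samples are dropped from the matrix.
#' @param min_confidence Confidence filter applied before scoring.
#' @return List of class `drug_response_matrix`: `pcy` (matrix), `imputed`
#'   (logical matrix), `per_concentration` (long data.frame), `qc`
#'   (data.frame), `target`.
#' @export
drug_response_matrix <- function(cells, layout, target = "myeloma",
                                 qc_threshold = 0.5, min_confidence = 0.6) {
  cells <- filter_cells(cells, min_confidence)
  samples <- unique(layout$sample_id)
  long <- do.call(rbind, lapply(samples, function(s) {
    pcy_scores(cells[cells$sample_id == s, , drop = FALSE],
               layout[layout$sample_id == s, , drop = FALSE], target)
  }))
  qc <- replicate_qc(cells, layout, target, threshold = qc_threshold)
  keep <- qc$sample_id[!qc$flagged]
  rep_long <- long[long$reported & long$sample_id %in% keep, , drop = FALSE]
  trts <- unique(long$treatment)
  pcy <- matrix(NA_real_, length(keep), length(trts),
                dimnames = list(keep, trts))
  for (i in seq_len(nrow(rep_long))) {
    pcy[rep_long$sample_id[i], rep_long$treatment[i]] <- rep_long$pcy[i]
  }
  structure(list(pcy = pcy,
                 imputed = matrix(FALSE, nrow(pcy), ncol(pcy),
                                  dimnames = dimnames(pcy)),
                 per_concentration = long, qc = qc, target = target),
            class = "drug_response_matrix")
}

#' Replicate concordance QC
#'
#' For each sample, builds the treatment x replicate matrix of well-level
#' 1 - RCF values (reported concentration only is not enforced here; all
#' concentrations contribute as separate rows) and reports the mean
#' pairwise Pearson correlation between replicate columns. Samples below
#' the threshold are flagged for exclusion.
#'
#' @param cells Quality-filtered cells.
#' @param layout Plate layout.
#' @param target Target population.
#' @param threshold Concordance threshold (default 0.5).
#' @return data.frame: `sample_id`, `concordance`, `flagged`.
#' @export
replicate_qc <- function(cells, layout, target = "myeloma", threshold = 0.5) {
  samples <- unique(layout$sample_id)
  rows <- lapply(samples, function(s) {
    lay <- layout[layout$sample_id == s, , drop = FALSE]
    sub <- cells[cells$sample_id == s, , drop = FALSE]
    frac <- well_class_fractions(sub, target)[lay$well_id]
    dmso_mean <- mean(frac[lay$control_type == "dmso"], na.rm = TRUE)
    iso_mean <- mean(frac[lay$control_type == "isotype"], na.rm = TRUE)
    treated <- lay$control_type == "none"
    ctrl <- ifelse(lay$drug_class == "antibody", iso_mean, dmso_mean)
    resp <- 1 - frac / ctrl
    key <- paste(lay$treatment, lay$concentration)
    reps <- lay$replicate_index
    n_rep <- max(reps[treated])
    if (n_rep < 2L) {
      warning("single-replicate design for sample ", s, ": QC skipped")
      return(data.frame(sample_id = s, concordance = NA_real_,
                        flagged = FALSE, stringsAsFactors = FALSE))
    }
    ukey <- unique(key[treated])
    mat <- matrix(NA_real_, length(ukey), n_rep, dimnames = list(ukey, NULL))
    for (i in which(treated)) mat[key[i], reps[i]] <- resp[i]
    cc <- stats::cor(mat, use = "pairwise.complete.obs")
    # ignore replicate pairs sharing too few treatments (e.g. the fourth
    # replicate only exists for antibodies)
    shared <- crossprod(!is.na(mat))
    cc[shared < 5] <- NA
    conc <- mean(cc[upper.tri(cc)], na.rm = TRUE)
    if (!is.finite(conc)) conc <- NA_real_
    data.frame(sample_id = s, concordance = conc,
               flagged = is.finite(conc) && conc < threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Shared cv.glmnet wrapper: 100-point lambda scan minimizing gaussian
# deviance (CV mean-squared error) in 10-fold CV, folds seeded.
cv_glmnet_scan <- function(x, y, alpha, seed = 1L, nfolds = 10L) {
  nfolds <- min(nfolds, length(y))
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(nfolds), length(y)))
    glmnet::cv.glmnet(x, y, alpha = alpha, nlambda = 100,
                      family = "gaussian", foldid = foldid)
  })
}

#' Impute missing drug responses by cross-validated LASSO
#'
#' For each treatment column with missing entries, fits a LASSO
#' (`alpha = 1`) on the samples with measured responses, using either the
#' other measured drug columns or a supplied proteome as predictors, over a
#' 100-value lambda scan minimizing the deviance in 10-fold CV. Only models
#' whose predicted-vs-measured Pearson correlation on the training samples
#' is at least `train_cor_min` (default 0.8) impute anything; imputed
#' entries are flagged in the mask and are for visualization/export only,
#' never for downstream statistics.
#'
#' @param drm A `drug_response_matrix` (or bare numeric matrix).
#' @param predictors Optional predictor matrix samples x features (e.g. a
#'   normalized proteome transposed); default: the other drug columns,
#'   mean-imputed where missing.
#' @param train_cor_min Training-correlation filter (default 0.8).
#' @param min_train Minimum measured samples to attempt a model.
#' @param seed Seed for CV fold assignment.
#' @return The matrix object with imputed entries filled in `pcy` and
#'   flagged in `imputed`; attribute `models` records per-treatment status.
#' @export
lasso_impute <- function(drm, predictors = NULL, train_cor_min = 0.8,
                         min_train = 10L, seed = 1L) {
  bare <- !inherits(drm, "drug_response_matrix")
  pcy <- if (bare) drm else drm$pcy
  imputed <- if (bare) matrix(FALSE, nrow(pcy), ncol(pcy),
                              dimnames = dimnames(pcy)) else drm$imputed
  status <- list()
  for (j in seq_len(ncol(pcy))) {
    y_all <- pcy[, j]
    miss <- is.na(y_all)
    if (!any(miss)) next
    if (is.null(predictors)) {
      x_all <- pcy[, -j, drop = FALSE]
      for (k in seq_len(ncol(x_all))) {
        xk <- x_all[, k]
        xk[is.na(xk)] <- mean(xk, na.rm = TRUE)
        x_all[, k] <- xk
      }
    } else {
      x_all <- predictors[rownames(pcy), , drop = FALSE]
    }
    train <- which(!miss & stats::complete.cases(x_all))
    trt <- colnames(pcy)[j]
    if (length(train) < min_train) {
      status[[trt]] <- "too_few_training_samples"
      next
    }
    fit <- cv_glmnet_scan(x_all[train, , drop = FALSE], y_all[train],
                          alpha = 1, seed = seed)
    pred_train <- as.numeric(stats::predict(fit, x_all[train, , drop = FALSE],
                                            s = "lambda.min"))
    r <- suppressWarnings(stats::cor(pred_train, y_all[train]))
    if (!is.finite(r) || r < train_cor_min) {
      status[[trt]] <- sprintf("filtered_train_cor_%.3f",
                               ifelse(is.finite(r), r, NA))
      next
    }
    target <- which(miss & stats::complete.cases(x_all))
    if (length(target) == 0L) next
    pcy[target, j] <- as.numeric(stats::predict(
      fit, x_all[target, , drop = FALSE], s = "lambda.min"))
    imputed[target, j] <- TRUE
    status[[trt]] <- sprintf("imputed_%d_train_cor_%.3f", length(target), r)
  }
  if (bare) {
    return(structure(list(pcy = pcy, imputed = imputed, models = status),
                     class = "drug_response_matrix"))
  }
  drm$pcy <- pcy
  drm$imputed <- imputed
  attr(drm, "models") <- status
  drm
}

#' Rank protein predictors of a drug response by elastic net
#'
#' Elastic-net regression (`alpha = 0.5`) of a drug-response column on the
#' proteome, with a 100-value lambda scan minimizing the deviance in
#' 10-fold CV; coefficients are reported at the deviance-minimizing lambda,
#' and the top-three positive and negative nonzero coefficients are listed.
#' Constant protein columns are dropped with a warning; missing proteome
#' entries are mean-imputed per protein.
#'
#' @param proteome Matrix proteins x samples (normalized abundances).
#' @param response Named numeric vector of PCY scores per sample.
#' @param alpha Elastic-net mixing (default 0.5).
#' @param treatment Name recorded in the output.
#' @param seed Seed for CV fold assignment.
#' @return List of class `predictor_ranking`: `treatment`, `coefficients`
#'   (named numeric), `top3_positive`, `top3_negative`, `lambda`.
#' @export
elasticnet_predictors <- function(proteome, response, alpha = 0.5,
                                  treatment = "drug", seed = 1L) {
  common <- intersect(colnames(proteome), names(response))
  common <- common[!is.na(response[common])]
  if (length(common) < 15L) stop("need >= 15 complete sample pairs")
  x <- t(proteome[, common, drop = FALSE])
  for (k in seq_len(ncol(x))) {
    xk <- x[, k]
    xk[is.na(xk)] <- mean(xk, na.rm = TRUE)
    x[, k] <- xk
  }
  const <- apply(x, 2, function(v) stats::sd(v) < 1e-12 || !is.finite(stats::sd(v)))
  if (any(const)) {
    warning("dropping ", sum(const), " all-constant protein column(s)")
    x <- x[, !const, drop = FALSE]
  }
  fit <- cv_glmnet_scan(x, response[common], alpha = alpha, seed = seed)
  co <- stats::coef(fit, s = "lambda.min")
  co <- stats::setNames(as.numeric(co)[-1], rownames(co)[-1])
  nz <- co[co != 0]
  top <- function(v) names(v)[order(abs(v), decreasing = TRUE)][seq_len(min(3, length(v)))]
  structure(list(treatment = treatment, coefficients = co,
                 top3_positive = top(nz[nz > 0]),
                 top3_negative = top(nz[nz < 0]),
                 lambda = fit$lambda.min),
            class = "predictor_ranking")
}
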
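test_that("RCF formula arithmetic and control self-normalization", {
  expect_equal(compute_rcf(50 / 500, c(0.2, 0.2)), 0.5)
  expect_equal(compute_rcf(0.10, c(0.18, 0.20, 0.22)), 0.5)
  expect_true(is.na(compute_rcf(0.1, c(0, 0))))

  # mean RCF over matched control wells is exactly 1, for any class
  co <- small_cohort(n_samples = 2, n_cells_per_well = 600, seed = 41)
  for (s in unique(co$layout$sample_id)) {
    lay <- co$layout[co$layout$sample_id == s, ]
    cells <- co$cells[co$cells$sample_id == s, ]
    for (target in c("myeloma", "t_cell", "monocyte", "other")) {
      frac <- well_class_fractions(cells, target)
      ctl <- frac[lay$well_id[lay$control_type == "dmso"]]
      rcf <- vapply(ctl, compute_rcf, numeric(1), control_fractions = ctl)
      expect_equal(mean(rcf), 1, tolerance = 1e-9)
    }
  }
})

test_that("PCY averages replicates and matches the composition oracle", {
  # replicate RCFs {0.5, 0.6, 0.7} -> PCY 0.4 (pure arithmetic)
  expect_equal(1 - mean(c(0.5, 0.6, 0.7)), 0.4)

  # planted kill 50% on myeloma only: the killed cells also shrink the
  # well total, which raises the surviving myeloma fraction, so the
  # analytic PCY falls short of the kill fraction (mode 1: 1 - 0.5/0.8
  # = 0.375); the closed-form composition oracle gives the exact value
  kc <- mmpt:::kill_classes()
  kf <- matrix(0, 1, length(kc), dimnames = list("BOR", kc))
  kf[, "myeloma"] <- 0.5
  cfg <- cohort_config(n_samples = 3, n_cells_per_well = 1300,
                       n_latent_features = 0, n_concentrations = 1,
                       drug_panel = tiny_panel(), kill_fractions = kf,
                       mode_assignment = c(1, 1, 1), n_proteins = 20,
                       n_signature_proteins = 4, seed = 42)
  co <- generate_cohort(cfg)
  drm <- drug_response_matrix(co$cells, co$layout)
  oracle <- expected_pcy_matrix(cfg, co$truth$true_kill_fraction)
  m <- co$config$phenogroup_modes[1, ]
  expect_equal(unname(oracle[1, "BOR"]), 1 - 0.5 / (0.5 * 0.4 + 0.6),
               tolerance = 1e-12)
  expect_lt(oracle[1, "BOR"], 0.5)   # compositional denominator effect
  for (s in rownames(drm$pcy)) {
    expect_lt(abs(drm$pcy[s, "BOR"] - oracle[s, "BOR"]), 0.05)
  }
})

test_that("a no-effect drug scores |PCY| < 0.05 at 3 x 1,300 cells", {
  kc <- mmpt:::kill_classes()
  kf <- matrix(0, 1, length(kc))
  co <- small_cohort(n_samples = 2, n_cells_per_well = 1300, seed = 43,
                     drug_panel = tiny_panel(), kill_fractions = kf,
                     mode_assignment = c(1, 1))
  drm <- drug_response_matrix(co$cells, co$layout)
  expect_true(all(abs(drm$pcy[, "BOR"]) < 0.05))
})

test_that("PCY is invariant to 2x uniform subsampling in expectation", {
  co <- small_cohort(n_samples = 3, n_cells_per_well = 1300, seed = 44,
                     mode_assignment = c(1, 1, 1))
  drm_full <- drug_response_matrix(co$cells, co$layout)
  set.seed(1)
  sub <- co$cells[sample(nrow(co$cells), nrow(co$cells) %/% 2), ]
  drm_sub <- drug_response_matrix(sub, co$layout)
  common <- intersect(rownames(drm_full$pcy), rownames(drm_sub$pcy))
  diffs <- drm_sub$pcy[common, ] - drm_full$pcy[common, ]
  expect_lt(abs(mean(diffs, na.rm = TRUE)), 0.03)
})

test_that("replicate QC flags discordant samples and tracks noise", {
  co <- small_cohort(n_samples = 2, n_cells_per_well = 1300, seed = 45,
                     mode_assignment = c(1, 1))
  qc <- replicate_qc(co$cells, co$layout)
  expect_true(all(qc$concordance > 0.5))

  # noise sweep: concordance monotonically non-increasing (Spearman <= 0)
  conc <- vapply(c(0, 0.5, 1, 2), function(nsd) {
    coh <- small_cohort(n_samples = 1, n_cells_per_well = 800, seed = 46,
                        replicate_noise_sd = nsd, mode_assignment = 1)
    replicate_qc(coh$cells, coh$layout)$concordance
  }, numeric(1))
  expect_lte(cor(seq_along(conc), conc, method = "spearman"), 0)
})

test_that("LASSO imputation recovers linear structure and filters noise", {
  set.seed(51)
  n <- 60; p <- 20
  base <- matrix(rnorm(n * p), n,
                 dimnames = list(sprintf("S%02d", 1:n), sprintf("D%02d", 1:p)))
  # noiseless copy of another drug: near-perfect recovery
  m <- cbind(base, DUP = base[, 1])
  miss <- sample(n, 12)
  truth <- m[miss, "DUP"]
  m[miss, "DUP"] <- NA
  out <- lasso_impute(m, seed = 1)
  expect_true(all(out$imputed[miss, "DUP"]))
  expect_gte(cor(out$pcy[miss, "DUP"], truth), 0.99)

  # independent target: the 0.8 training-correlation filter blocks it
  y <- rnorm(n); y[miss] <- NA
  m2 <- cbind(base, IND = y)
  out2 <- lasso_impute(m2, seed = 2)
  expect_false(any(out2$imputed[, "IND"]))

  # planted linear structure with ~20% masked: imputed vs truth r >= 0.9
  set.seed(52)
  W <- matrix(rnorm(p * 3), p, 3)
  Z <- matrix(rnorm(n * 3), n, 3)
  lin <- Z %*% t(W) + matrix(rnorm(n * p, 0, 0.2), n)
  dimnames(lin) <- dimnames(base)
  mask <- matrix(runif(n * p) < 0.2, n, p)
  masked <- lin; masked[mask] <- NA
  out3 <- lasso_impute(masked, seed = 3)
  got <- out3$pcy[mask & out3$imputed]
  want <- lin[mask & out3$imputed]
  expect_gt(length(got), 50)
  expect_gte(cor(got, want), 0.9)
})

test_that("elastic net ranks planted predictors and survives degeneracies", {
  set.seed(53)
  prot <- matrix(rnorm(300 * 60), 300, 60,
                 dimnames = list(sprintf("P%03d", 1:300),
                                 sprintf("S%02d", 1:60)))
  y <- 2 * prot["P001", ] - 1 * prot["P002", ] + rnorm(60, 0, 0.1)
  names(y) <- colnames(prot)
  pr <- elasticnet_predictors(prot, y, seed = 1)
  expect_true("P001" %in% pr$top3_positive)
  expect_true("P002" %in% pr$top3_negative)

  # duplicated predictor columns: grouping keeps both, nothing crashes
  prot2 <- rbind(prot, P301 = prot["P001", ])
  pr2 <- elasticnet_predictors(prot2, y, seed = 1)
  expect_true(all(c("P001", "P301") %in% names(which(pr2$coefficients != 0))))

  # constant column dropped with warning
  prot3 <- rbind(prot, PCONST = rep(1, 60))
  expect_warning(elasticnet_predictors(prot3, y, seed = 1), "constant")

  # pure-noise response: sparse solution, few proteins selected on average
  nz <- vapply(1:10, function(s) {
    set.seed(60 + s)
    y0 <- rnorm(60); names(y0) <- colnames(prot)
    sum(elasticnet_predictors(prot, y0, seed = s)$coefficients != 0)
  }, numeric(1))
  expect_lte(mean(nz / 300), 0.05)
})

test_that("imputed entries never feed downstream statistics", {
  set.seed(54)
  pcy <- matrix(rnorm(30 * 4), 30, 4,
                dimnames = list(sprintf("S%02d", 1:30), paste0("D", 1:4)))
  imputed <- matrix(FALSE, 30, 4, dimnames = dimnames(pcy))
  imputed[1:10, 1] <- TRUE
  drm <- structure(list(pcy = pcy, imputed = imputed),
                   class = "drug_response_matrix")
  resid <- matrix(rnorm(5 * 30), 5, 30,
                  dimnames = list(paste0("P", 1:5), rownames(pcy)))
  edges <- data.frame(a = "P1", b = "P2")
  net1 <- drug_protein_network(resid, drm, edges)
  # poisoning the imputed entries must not change the result
  drm2 <- drm
  drm2$pcy[imputed] <- 1e6
  net2 <- drug_protein_network(resid, drm2, edges)
  expect_identical(net1$associations, net2$associations)

  # same for the feature-association stage
  clin <- data.frame(sample_id = rownames(pcy),
                     grp = rep(c("a", "b"), 15), active_clonal = TRUE)
  e1 <- feature_drug_associations(drm, clin, "grp", n_cv = 5, seed = 1)
  e2 <- feature_drug_associations(drm2, clin, "grp", n_cv = 5, seed = 1)
  expect_identical(e1, e2)

  # and for iPCY
  panel <- data.frame(treatment = "D1", drug_class = "compound",
                      components = "D1")
  r <- compute_ipcy(drm2$pcy["S01", ], "D1", panel, drm2$imputed["S01", ])
  expect_true(is.na(r$ipcy))
})
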
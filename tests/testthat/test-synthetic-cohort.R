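test_that("generation is fully seed-determined and seeds differ", {
  co1 <- small_cohort(seed = 11)
  co2 <- small_cohort(seed = 11)
  expect_identical(co1, co2)
  co3 <- small_cohort(seed = 12)
  expect_false(identical(co1$cells$x_um, co3$cells$x_um))
})

test_that("configuration invariants are enforced", {
  bad_modes <- default_phenogroup_modes()
  bad_modes[1, 1] <- bad_modes[1, 1] + 0.2
  expect_error(cohort_config(phenogroup_modes = bad_modes), "sum to 1")
  kf <- matrix(1.2, 9, 5)
  expect_error(cohort_config(kill_fractions = kf), "\\[0, 1\\]")
  expect_error(cohort_config(n_proteins = 10, n_signature_proteins = 20),
               "n_signature_proteins")
  expect_error(cohort_config(hazard_model = list(baseline_rate = -1, coef = 0)),
               "baseline")
})

test_that("mode bookkeeping: 60 samples over 3 modes gives 3 x 20 truth", {
  cfg <- cohort_config(n_samples = 60, seed = 1)
  expect_equal(unname(table(cfg$mode_assignment)), rep(20L, 3),
               ignore_attr = TRUE)
})

test_that("zero kill fractions make treated wells look like controls", {
  kc <- mmpt:::kill_classes()
  kf <- matrix(0, 1, length(kc))
  co <- small_cohort(n_samples = 2, n_cells_per_well = 1000, seed = 4,
                     drug_panel = tiny_panel(), kill_fractions = kf,
                     mode_assignment = c(1, 1))
  for (s in c("S01", "S02")) {
    cells <- co$cells[co$cells$sample_id == s, ]
    lay <- co$layout[co$layout$sample_id == s, ]
    frac <- well_class_fractions(cells, "myeloma")
    trt <- frac[lay$well_id[lay$control_type == "none"]]
    ctl <- frac[lay$well_id[lay$control_type == "dmso"]]
    # two-sample t on per-well fractions: no significant difference
    expect_gt(t.test(trt, ctl)$p.value, 0.01)
  }
})

test_that("class abundances match the mode composition within sampling error", {
  co <- small_cohort(n_samples = 3, n_cells_per_well = 1000, seed = 6,
                     drug_panel = tiny_panel())
  cat_ <- subcluster_catalogue()
  for (s in unique(co$cells$sample_id)) {
    mode_vec <- co$config$phenogroup_modes[
      co$truth$true_phenogroup[s], ]
    ctrl_wells <- co$layout$well_id[co$layout$sample_id == s &
                                      co$layout$control_type == "dmso"]
    cells <- co$cells[co$cells$sample_id == s &
                        co$cells$well_id %in% ctrl_wells, ]
    obs <- tabulate(cells$true_subcluster, nbins = nrow(cat_)) / nrow(cells)
    # multinomial sd per component ~ sqrt(p(1-p)/n); allow 4 sd
    tol <- 4 * sqrt(mode_vec * (1 - mode_vec) / nrow(cells))
    expect_true(all(abs(obs - mode_vec) <= tol + 1e-3))
  }
})

test_that("proteome missingness matches the binomial expectation", {
  set.seed(2)
  fb <- rbeta(77, 4, 2); names(fb) <- sprintf("S%02d", 1:77)
  pr <- generate_proteome(fb, n_proteins = 2000, n_signature = 100,
                          missing_rate = 0.1)
  n_missing <- sum(is.na(pr$raw))
  expected <- 0.1 * 2000 * 77
  tol <- 4 * sqrt(2000 * 77 * 0.1 * 0.9)
  expect_lt(abs(n_missing - expected), tol)
})

test_that("noiseless planted proteins correlate perfectly with myeloma fraction", {
  set.seed(3)
  fb <- rbeta(30, 4, 2); names(fb) <- sprintf("S%02d", 1:30)
  pr <- generate_proteome(fb, n_proteins = 100, n_signature = 20,
                          effect = 1, noise_sd = 0, missing_rate = 0)
  for (p in pr$truth$up) {
    expect_equal(abs(cor(log10(pr$raw[p, ]), fb, method = "spearman")), 1)
  }
  for (p in pr$truth$down) {
    expect_equal(cor(log10(pr$raw[p, ]), fb, method = "spearman"), -1)
  }
})

test_that("zero effect size leaves planted and background rho exchangeable", {
  set.seed(4)
  rho_planted <- c(); rho_bg <- c()
  for (r in 1:30) {
    fb <- rbeta(40, 4, 2); names(fb) <- sprintf("S%02d", 1:40)
    pr <- generate_proteome(fb, n_proteins = 60, n_signature = 20,
                            effect = 0, missing_rate = 0, n_drug_assoc = 0)
    rho <- apply(pr$raw, 1, function(x) cor(log10(x), fb, method = "spearman"))
    planted <- c(pr$truth$up, pr$truth$down)
    rho_planted <- c(rho_planted, rho[planted])
    rho_bg <- c(rho_bg, rho[setdiff(rownames(pr$raw), planted)])
  }
  expect_gt(suppressWarnings(  # rank ties make the KS p approximate
    ks.test(rho_planted, rho_bg)$p.value), 0.05)
})

test_that("survival generator honors the censoring and hazard contracts", {
  # censoring rate 0: every patient has an event
  sv <- generate_survival(rnorm(50), censoring_rate = 0, seed = 1)
  expect_true(all(sv$event == 1))
  expect_error(generate_survival(rnorm(5),
                                 list(baseline_rate = -0.1, coef = 0)),
               "baseline")

  # null coefficient: log-rank p uniform over reps
  ps <- vapply(1:100, function(r) {
    ipcy <- rep(c(0, 1), 20)
    sv <- generate_survival(ipcy, list(baseline_rate = 1 / 365, coef = 0),
                            censoring_rate = 0.2, seed = 4000 + r)
    km_logrank(sv$time, sv$event, ipcy > 0.5)$logrank_p
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.05)

  # true HR 4 between strata, n = 200: Cox oracle recovers it
  # (Monte-Carlo oracle band computed before the build: median in [3.4, 4.7])
  hrs <- vapply(1:200, function(r) {
    ipcy <- rep(c(0, 1), 100)
    sv <- generate_survival(ipcy, list(baseline_rate = 1 / 365,
                                       coef = log(4)),
                            censoring_rate = 0.2, seed = 8000 + r)
    fit <- survival::coxph(survival::Surv(sv$time, sv$event) ~ I(ipcy <= 0.5))
    exp(unname(coef(fit)))
  }, numeric(1))
  expect_gte(median(hrs), 3.4)
  expect_lte(median(hrs), 4.7)
})

test_that("scRNA generator emits consistent flags and referenced ids", {
  sc <- generate_scrna(n_patients = 6, cells_per_patient = 80, seed = 2)
  expect_s4_class(sc$counts, "sparseMatrix")
  expect_true(all(sc$counts@x >= 0))
  expect_identical(rownames(sc$counts), sc$genes$gene)
  expect_identical(colnames(sc$counts), sc$cells$cell)
  expect_identical(names(sc$truth$true_big_like), sc$cells$cell)
  expect_true(all(sc$truth$planted_low_umi %in% sc$cells$cell))
})

test_that("cohort files round-trip through the plain-text writers", {
  co <- small_cohort(n_samples = 2, n_cells_per_well = 200, seed = 9,
                     scrna = list(n_patients = 2, cells_per_patient = 40,
                                  seed = 9),
                     cytokines = list(n_samples = 4, n_cytokines = 6,
                                      seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  cells <- read_cells(file.path(dir, "cells.tsv"))
  expect_equal(nrow(cells), nrow(co$cells))
  lay <- read_layout(file.path(dir, "plate_layout.csv"))
  expect_equal(sort(unique(lay$control_type)), c("dmso", "isotype", "none"))
  prot <- read_proteome(file.path(dir, "proteome.tsv"))
  expect_equal(dim(prot), dim(co$proteome))
  expect_equal(unname(prot[5, 2]), unname(co$proteome[5, 2]), tolerance = 1e-6)
  mm <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  expect_equal(dim(mm), dim(co$scrna$counts))
})
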
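test_that("proteome normalization: z-steps, degenerate rows, planted tail", {
  set.seed(71)
  raw <- matrix(10^rnorm(50 * 20, 6, 0.5), 50,
                dimnames = list(sprintf("P%02d", 1:50), sprintf("S%02d", 1:20)))
  norm1 <- normalize_proteome(raw, low_abundance_quantile = 0,
                              steps = "protein_only")
  expect_true(all(abs(rowMeans(norm1, na.rm = TRUE)) < 1e-9))
  expect_true(all(abs(apply(norm1, 1, sd, na.rm = TRUE) - 1) < 1e-9))

  # constant row: warning and all-missing output
  raw2 <- raw; raw2[3, ] <- 100
  expect_warning(n2 <- normalize_proteome(raw2, 0), "constant")
  expect_true(all(is.na(n2[3, ])))

  # non-positive entries rejected
  raw3 <- raw; raw3[1, 1] <- -1
  expect_error(normalize_proteome(raw3), "non-positive")

  # planted low-abundance tail at the 5% quantile is exactly the mask:
  # 2 of 40 entries per protein (the 5% tail) sit far below the body, so
  # the per-protein floor lands between tail and body
  raw4 <- matrix(10^runif(40 * 40, 5, 6), 40,
                 dimnames = list(sprintf("P%02d", 1:40), sprintf("S%02d", 1:40)))
  planted <- do.call(rbind, lapply(seq_len(40), function(i) {
    cbind(i, sample(40, 2))
  }))
  raw4[planted] <- 10^runif(nrow(planted), 1, 2)
  n4 <- normalize_proteome(raw4, 0.05)
  expect_true(all(is.na(n4[planted])))
  expect_equal(sum(is.na(n4)), nrow(planted))
})

test_that("discovery associations: perfect monotone, AUROC on planted truth", {
  set.seed(72)
  fb <- rbeta(77, 4, 2); names(fb) <- sprintf("S%02d", 1:77)
  # protein identical to the fraction: rho 1, positive signed log p
  prot <- rbind(PEXACT = fb,
                matrix(rnorm(20 * 77), 20,
                       dimnames = list(sprintf("P%02d", 1:20), names(fb))))
  disc <- discovery_associations(prot, fb)
  ex <- disc[disc$protein == "PEXACT", ]
  expect_equal(ex$rho, 1)
  expect_gt(ex$signed_logp, 0)

  # planted effect 0.8 at n = 77: |signed log p| separates planted from
  # background with AUROC >= 0.95
  pr <- generate_proteome(fb, n_proteins = 400, n_signature = 40,
                          effect = 0.8, missing_rate = 0.1, n_drug_assoc = 0)
  disc2 <- discovery_associations(normalize_proteome(pr$raw), fb)
  planted <- disc2$protein %in% c(pr$truth$up, pr$truth$down)
  score <- abs(disc2$signed_logp)
  r <- rank(score)
  auroc <- (sum(r[planted]) - sum(planted) * (sum(planted) + 1) / 2) /
    (sum(planted) * sum(!planted))
  expect_gte(auroc, 0.95)

  # proteins with too few pairs are omitted with a reason
  prot3 <- prot
  prot3["P01", 1:70] <- NA
  disc3 <- discovery_associations(prot3, fb)
  expect_false("P01" %in% disc3$protein)
  expect_true("P01" %in% attr(disc3, "skipped"))
})

test_that("validation fold changes match the closed-form paired t", {
  big <- matrix(c(1, 1, 1, 1), 1, dimnames = list("P1", NULL))
  small <- big
  v <- validation_foldchanges(big, small)
  expect_equal(v$log2fc, 0)
  expect_equal(v$p, 1)

  # exact doubling on the linear scale = +1 on log2
  small2 <- matrix(c(10, 11, 12, 13), 1, dimnames = list("P1", NULL))
  big2 <- small2 + 1   # log2 scale
  expect_equal(validation_foldchanges(big2, small2)$log2fc, 1)

  # hand-computed t for differences (0.5, 0.6, 0.4, 0.5)
  d <- c(0.5, 0.6, 0.4, 0.5)
  small3 <- matrix(rnorm(4), 1, dimnames = list("P1", NULL))
  big3 <- small3 + matrix(d, 1)
  v3 <- validation_foldchanges(big3, small3)
  tstat <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(v3$p, 2 * pt(abs(tstat), df = 3, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(v3$log2fc, mean(d), tolerance = 1e-12)

  # < 2 complete pairs: missing
  big4 <- matrix(c(1, NA, NA, NA), 1, dimnames = list("P1", NULL))
  expect_true(is.na(validation_foldchanges(big4, small3)$log2fc))
})

test_that("signature selection: quadrants, strict cutoff, order invariance", {
  disc <- data.frame(protein = sprintf("P%02d", 1:6),
                     rho = c(0.9, 0.8, -0.9, -0.8, 0.9, 0.7),
                     p = c(0.001, 0.01, 0.001, 0.01, 0.04, 0.5))
  val <- data.frame(protein = sprintf("P%02d", 1:6),
                    log2fc = c(1, 0.5, -1, -0.5, 0.29, 1),
                    p = rep(0.01, 6))
  sig <- select_signature(disc, val)
  expect_setequal(sig$up, c("P01", "P02"))
  expect_setequal(sig$down, c("P03", "P04"))
  # P05: log2FC 0.29 fails the strict > 0.3; P06: discovery p 0.5 fails
  expect_false("P05" %in% sig$up)
  expect_false("P06" %in% sig$up)
  # protein order invariance
  perm <- c(4, 1, 6, 2, 5, 3)
  sig2 <- select_signature(disc[perm, ], val[perm, ])
  expect_setequal(sig2$up, sig$up)
  expect_setequal(sig2$down, sig$down)
  expect_equal(sig2$fisher_p, sig$fisher_p)
})

test_that("Fisher concordance equals the hypergeometric enumeration", {
  # [[10, 0], [0, 10]]: two-sided p = 2 / C(20, 10)
  disc <- data.frame(protein = sprintf("P%02d", 1:20),
                     rho = rep(c(1, -1), each = 10), p = 1e-6)
  val <- data.frame(protein = sprintf("P%02d", 1:20),
                    log2fc = rep(c(1, -1), each = 10), p = 1e-6)
  sig <- select_signature(disc, val)
  expect_equal(sig$fisher_p, 2 / choose(20, 10), tolerance = 1e-9)

  # random signs: p approximately uniform over reps
  set.seed(73)
  ps <- vapply(1:200, function(r) {
    rho <- sample(c(-1, 1), 40, replace = TRUE)
    fc <- sample(c(-1, 1), 40, replace = TRUE)
    d <- data.frame(protein = sprintf("P%02d", 1:40), rho = rho, p = 1e-6)
    v <- data.frame(protein = sprintf("P%02d", 1:40), log2fc = fc, p = 1e-6)
    suppressWarnings(select_signature(d, v)$fisher_p)
  }, numeric(1))
  # the Fisher null is discrete and conservative; check stochastic
  # dominance over uniform rather than exact uniformity
  expect_gt(suppressWarnings(  # KS ties from the discrete Fisher null
    ks.test(ps, "punif", alternative = "greater")$p.value), 0.05)

  # degenerate table: warning and p = 1
  d <- data.frame(protein = "P1", rho = 1, p = 1e-6)
  v <- data.frame(protein = "P1", log2fc = 1, p = 1e-6)
  expect_warning(s <- select_signature(d, v), "degenerate")
  expect_equal(s$fisher_p, 1)
})

test_that("hypergeometric enrichment matches closed forms and ranks signal", {
  # universe 10, set 5, signature 5, overlap 5: p = 1 / C(10, 5)
  u <- sprintf("G%02d", 1:10)
  res <- geneset_enrichment(u[1:5], list(hit = u[1:5]), u)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  # zero overlap with a small set: upper tail includes 0, p = 1
  res0 <- geneset_enrichment(u[1:5], list(none = u[6:7]), u)
  expect_equal(res0$p, 1)
  expect_error(geneset_enrichment(u[1:5], list(a = u[1:2]), character(0)),
               "empty universe")

  # planted enriched set ranks first among 100 random sets
  set.seed(74)
  universe <- sprintf("G%04d", 1:1000)
  signature <- sample(universe, 50)
  planted <- c(sample(signature, 8), sample(setdiff(universe, signature), 2))
  sets <- c(list(planted = planted),
            lapply(1:100, function(i) sample(universe, 10)))
  names(sets) <- c("planted", sprintf("rand%03d", 1:100))
  res2 <- geneset_enrichment(signature, sets, universe)
  expect_equal(res2$set[1], "planted")
})

test_that("covariate regression leaves the orthogonal signal intact", {
  set.seed(75)
  cv <- rnorm(40); names(cv) <- sprintf("S%02d", 1:40)
  sig <- unname(resid(lm(rnorm(40) ~ cv)))  # independent of the covariate
  prot <- rbind(LIN = 2 * cv + 1,
                ORTH = sig - mean(sig),
                MIX = cv + sig)
  colnames(prot) <- names(cv)
  res <- regress_out_covariate(prot, cv)
  expect_true(all(abs(res["LIN", ]) < 1e-9))
  # orthogonal-by-construction signal: residual = centered original
  fit <- lm(prot["ORTH", ] ~ cv)
  expect_equal(unname(res["ORTH", ]), unname(resid(fit)), tolerance = 1e-12)
  expect_gte(cor(res["MIX", ], sig), 0.95)
  expect_warning(regress_out_covariate(prot, setNames(rep(1, 40), names(cv))),
                 "constant covariate")
})

test_that("drug-protein network equals its brute-force re-selection", {
  set.seed(76)
  n <- 30
  resid <- matrix(rnorm(20 * n), 20,
                  dimnames = list(sprintf("P%02d", 1:20), sprintf("S%02d", 1:n)))
  pcy <- matrix(rnorm(n * 5), n,
                dimnames = list(colnames(resid), paste0("D", 1:5)))
  # plant two strong associations
  resid["P01", ] <- pcy[, "D1"] + rnorm(n, 0, 0.3)
  resid["P02", ] <- -pcy[, "D2"] + rnorm(n, 0, 0.3)
  edges <- data.frame(a = c("P01", "P02", "P03", "P19"),
                      b = c("P02", "P03", "P04", "P20"))
  net <- drug_protein_network(resid, pcy, edges)

  # brute-force oracle over all (protein, drug) pairs
  sel <- character(0)
  for (d in colnames(pcy)) {
    rho <- apply(resid, 1, function(x) cor(x, pcy[, d], method = "spearman"))
    pv <- vapply(rownames(resid), function(p)
      spearman_test(resid[p, ], pcy[, d])$p, numeric(1))
    sel <- union(sel, names(which(abs(rho) > 0.585 & pv < 0.05)))
    ord <- order(rho)
    sel <- union(sel, names(rho)[c(head(ord, 2), tail(ord, 2))])
  }
  expect_setequal(net$selected, sel)

  # every drug contributes its top-2/bottom-2 even with no threshold passers
  resid0 <- matrix(rnorm(20 * n), 20, dimnames = dimnames(resid))
  net0 <- drug_protein_network(resid0, pcy[, "D1", drop = FALSE], edges)
  expect_equal(length(net0$selected), 4)

  # nodes connected only to dropped nodes are dropped (no isolated nodes)
  expect_true(all(c(net$edges$a, net$edges$b) %in% rownames(net$nodes)))
  expect_warning(drug_protein_network(resid, pcy, edges[0, ]), "empty")
})
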
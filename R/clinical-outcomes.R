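#' One-way ANOVA F statistic and p-value
#'
#' Closed-form between/within mean squares; used for feature-drug
#' association edges and directly testable against hand computation.
#'
#' @param values Numeric response vector.
#' @param groups Factor-like group labels.
#' @return List: `F`, `p`, `df1`, `df2`, `group_means`.
#' @export
oneway_anova <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(factor(groups[ok]))
  k <- nlevels(groups); n <- length(values)
  if (k < 2L || n <= k) {
    return(list(F = NA_real_, p = NA_real_, df1 = NA, df2 = NA,
                group_means = tapply(values, groups, mean)))
  }
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  grand <- mean(values)
  ss_between <- sum(gn * (gm - grand)^2)
  ss_within <- sum((values - gm[groups])^2)
  df1 <- k - 1L; df2 <- n - k
  Fstat <- (ss_between / df1) / (ss_within / df2)
  list(F = Fstat, p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, group_means = gm)
}

# Two-group t-test p for an association edge: for 2-level features the two
# levels, for multi-level features the extreme-mean levels.
edge_ttest <- function(values, groups) {
  gm <- tapply(values, groups, mean)
  lv <- names(gm)[c(which.min(gm), which.max(gm))]
  if (lv[1] == lv[2]) return(list(p = 1, direction = lv[1]))
  a <- values[groups == lv[1]]; b <- values[groups == lv[2]]
  if (length(a) < 2L || length(b) < 2L) return(list(p = NA_real_,
                                                    direction = lv[2]))
  list(p = stats::t.test(a, b)$p.value, direction = lv[2])
}

#' Feature-drug association network with cross-validated stability
#'
#' For every (clinical/morphological feature, drug) pair: one-way ANOVA
#' across feature levels and a two-group t-test (the two levels, or the
#' extreme-mean levels for multi-level features). An edge is retained iff
#' both p-values fall below `p_cut` (default 0.01). Stability
#' (`cv_fraction`) is the share of `n_cv` seeded leave-`holdout_frac`-out
#' resamples in which both tests stay below the cutoff. Only samples
#' flagged as active clonal disease enter; feature levels with fewer than
#' `min_level_n` samples are dropped per comparison.
#'
#' @param drm `drug_response_matrix` (imputed entries excluded) or matrix
#'   samples x treatments.
#' @param clinical data.frame with `sample_id`, optionally
#'   `active_clonal`, and the feature columns.
#' @param features Character vector of feature column names.
#' @param p_cut Significance cutoff for both tests (default 0.01).
#' @param n_cv Number of resamples (default 100).
#' @param holdout_frac Fraction left out per resample (default 0.2).
#' @param min_level_n Minimum samples per feature level (default 3).
#' @param seed Seed for the resampling.
#' @return data.frame of edges: `feature`, `treatment`, `direction`
#'   (level with the higher mean response, i.e. ex vivo better),
#'   `anova_F`, `p_anova`, `p_ttest`, `cv_fraction`, `n`.
#' @export
feature_drug_associations <- function(drm, clinical, features,
                                      p_cut = 0.01, n_cv = 100L,
                                      holdout_frac = 0.2,
                                      min_level_n = 3L, seed = 1L) {
  pcy <- if (inherits(drm, "drug_response_matrix")) {
    m <- drm$pcy; m[drm$imputed] <- NA_real_; m
  } else as.matrix(drm)
  if ("active_clonal" %in% names(clinical)) {
    clinical <- clinical[clinical$active_clonal %in% TRUE, , drop = FALSE]
  }
  clinical <- clinical[clinical$sample_id %in% rownames(pcy), , drop = FALSE]
  edges <- list()
  for (f in features) {
    for (d in colnames(pcy)) {
      y <- pcy[clinical$sample_id, d]
      g <- as.character(clinical[[f]])
      ok <- is.finite(y) & !is.na(g)
      y <- y[ok]; g <- g[ok]
      tab <- table(g)
      keep_lv <- names(tab)[tab >= min_level_n]
      sel <- g %in% keep_lv
      y <- y[sel]; g <- g[sel]
      if (length(unique(g)) < 2L) next
      an <- oneway_anova(y, g)
      tt <- edge_ttest(y, g)
      if (!is.finite(an$p) || !is.finite(tt$p)) next
      if (an$p >= p_cut || tt$p >= p_cut) next
      cv_hits <- with_seed(seed + match(d, colnames(pcy)) * 1000L +
                             match(f, features), {
        vapply(seq_len(n_cv), function(r) {
          idx <- sample(length(y), ceiling((1 - holdout_frac) * length(y)))
          if (length(unique(g[idx])) < 2L) return(FALSE)
          an2 <- oneway_anova(y[idx], g[idx])
          tt2 <- edge_ttest(y[idx], g[idx])
          isTRUE(an2$p < p_cut) && isTRUE(tt2$p < p_cut)
        }, logical(1))
      })
      edges[[length(edges) + 1L]] <- data.frame(
        feature = f, treatment = d, direction = tt$direction,
        anova_F = an$F, p_anova = an$p, p_ttest = tt$p,
        cv_fraction = mean(cv_hits), n = length(y),
        stringsAsFactors = FALSE)
    }
  }
  if (length(edges) == 0L) {
    return(data.frame(feature = character(0), treatment = character(0),
                      direction = character(0), anova_F = numeric(0),
                      p_anova = numeric(0), p_ttest = numeric(0),
                      cv_fraction = numeric(0), n = integer(0)))
  }
  do.call(rbind, edges)
}

# Normalize a treatment/regimen name to comparable component tokens,
# applying the corticosteroid alias table.
normalize_components <- function(x, aliases = steroid_aliases()) {
  parts <- toupper(trimws(unlist(strsplit(x, "[+/,]"))))
  parts <- parts[nzchar(parts)]
  unname(vapply(parts, function(p) {
    if (p %in% names(aliases)) aliases[[p]] else p
  }, character(1)))
}

#' Corticosteroid and common-agent alias table
#'
#' Editable mapping of clinical names/abbreviations onto the tested-panel
#' vocabulary, used during iPCY regimen matching.
#' @return Named character vector alias -> canonical token.
#' @export
steroid_aliases <- function() {
  c(DEXAMETHASONE = "DEX", DEX = "DEX", PREDNISONE = "DEX",
    PREDNISOLONE = "DEX", BORTEZOMIB = "BOR", BOR = "BOR",
    CARFILZOMIB = "CFZ", CFZ = "CFZ", LENALIDOMIDE = "LEN", LEN = "LEN",
    POMALIDOMIDE = "POM", POM = "POM", DARATUMUMAB = "DARA", DARA = "DARA",
    ELOTUZUMAB = "ELO", ELO = "ELO", VENETOCLAX = "VEN", VEN = "VEN")
}

# Treatments (rows of the panel) whose component set is contained in the
# clinical regimen; with mode "exact" only identical component sets match.
match_regimen <- function(panel, regimen, mode = c("subset", "exact"),
                          aliases = steroid_aliases()) {
  mode <- match.arg(mode)
  reg <- normalize_components(paste(regimen, collapse = "+"), aliases)
  hits <- vapply(seq_len(nrow(panel)), function(i) {
    comp <- normalize_components(panel$components[i], aliases)
    if (mode == "subset") all(comp %in% reg)
    else setequal(comp, reg)
  }, logical(1))
  panel$treatment[hits]
}

#' Integrated PCY (iPCY) for a patient's clinical regimen
#'
#' Matches the tested panel against the regimen the patient subsequently
#' received (a tested combination whose component set is a subset of the
#' regimen matches, in addition to its single agents) and sums the matched
#' non-imputed PCY scores.
#'
#' @param pcy_row Named numeric vector treatment -> PCY for the patient's
#'   sample.
#' @param regimen Character vector (or single "+"-separated string) of the
#'   clinical regimen.
#' @param panel Treatment panel data.frame (`treatment`, `components`).
#' @param imputed_row Optional logical vector flagging imputed entries
#'   (excluded from the sum; patients whose every match is imputed get NA).
#' @param mode `"subset"` (default) or `"exact"` matching.
#' @return List: `ipcy` (NA when nothing matches), `matched` (treatments
#'   used).
#' @export
compute_ipcy <- function(pcy_row, regimen, panel, imputed_row = NULL,
                         mode = "subset") {
  matched <- match_regimen(panel, regimen, mode)
  matched <- matched[matched %in% names(pcy_row)]
  if (!is.null(imputed_row)) {
    matched <- matched[!(imputed_row[matched] %in% TRUE)]
  }
  matched <- matched[is.finite(pcy_row[matched])]
  if (length(matched) == 0L) {
    return(list(ipcy = NA_real_, matched = character(0)))
  }
  list(ipcy = sum(pcy_row[matched]), matched = matched)
}

#' Stratify patients by iPCY around the subcohort mean
#'
#' The sensitivity threshold of each subcohort (immunotherapy /
#' non-immunotherapy) is its mean iPCY; a patient is `sensitive` iff its
#' iPCY strictly exceeds the threshold (at full scale the study's
#' thresholds were 0.21 and 0.40).
#'
#' @param outcomes data.frame with `patient_id`, `ipcy`, `subcohort`.
#' @return The data.frame with a `label` column added; attribute
#'   `thresholds` records the per-subcohort means.
#' @export
stratify_by_ipcy <- function(outcomes) {
  outcomes <- outcomes[is.finite(outcomes$ipcy), , drop = FALSE]
  thresholds <- c()
  outcomes$label <- NA_character_
  for (sc in unique(outcomes$subcohort)) {
    sel <- outcomes$subcohort == sc
    if (sum(sel) < 2L) stop("subcohort ", sc, " has fewer than 2 patients")
    thr <- mean(outcomes$ipcy[sel])
    thresholds[sc] <- thr
    outcomes$label[sel] <- ifelse(outcomes$ipcy[sel] > thr,
                                  "sensitive", "resistant")
    if (all(outcomes$label[sel] == "resistant")) {
      warning("all iPCY values equal in subcohort ", sc,
              ": every patient labelled resistant")
    }
  }
  attr(outcomes, "thresholds") <- thresholds
  outcomes
}

#' Kaplan-Meier, log-rank and hazard ratio for two groups
#'
#' Product-limit KM curves per group, the two-group log-rank (Mantel-Cox)
#' chi-square p-value, and the O/E hazard-ratio estimate
#' `HR = (O1/E1)/(O2/E2)` with the log-scale 95% CI
#' `exp(log HR +/- 1.96 sqrt(1/E1 + 1/E2))`. Group 1 is the first factor
#' level (or the first unique label); the HR is group 1 relative to
#' group 2.
#'
#' @param time Times to event/censoring (> 0).
#' @param event Event indicator (1 = event, 0 = censored).
#' @param group Two-level group labels.
#' @return List of class `survival_result`: `groups`, `logrank_p`,
#'   `hazard_ratio`, `hr_ci` (length-2), `observed`, `expected`,
#'   `km` (per-group data.frame time/surv/n.risk), `at_risk`.
#' @export
km_logrank <- function(time, event, group) {
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (sum(event) == 0L) stop("no events observed")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  O <- sd_$obs; E <- sd_$exp
  if (any(E == 0)) {
    warning("a group has zero expected events; HR is a degenerate bound")
  }
  hr <- (O[1] / E[1]) / (O[2] / E[2])
  ci <- exp(log(hr) + c(-1, 1) * 1.96 * sqrt(1 / E[1] + 1 / E[2]))
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  strata <- rep(names(fit$strata), fit$strata)
  km <- data.frame(group = sub("^group=", "", strata), time = fit$time,
                   surv = fit$surv, n_risk = fit$n.risk,
                   n_event = fit$n.event, stringsAsFactors = FALSE)
  ev_times <- sort(unique(time[event == 1]))
  at_risk <- vapply(levels(group), function(g) {
    vapply(ev_times, function(t0) sum(time[group == g] >= t0), numeric(1))
  }, numeric(length(ev_times)))
  structure(list(groups = levels(group), logrank_p = p, hazard_ratio = hr,
                 hr_ci = ci, observed = O, expected = E, km = km,
                 at_risk = cbind(time = ev_times, at_risk)),
            class = "survival_result")
}

#' Outcome split by PhenoGroup
#'
#' Binary regrouping of PhenoGroup labels (one group versus the rest),
#' then [km_logrank()].
#'
#' @param outcomes data.frame with `time_to_next_treatment`, `event` and a
#'   key column matching `names(phenogroups)` (default `sample_id`).
#' @param phenogroups Named character vector sample -> PG label.
#' @param split PG label forming one side (default "PG2").
#' @param key Column of `outcomes` holding the sample ids.
#' @return A `survival_result`.
#' @export
phenogroup_outcome_split <- function(outcomes, phenogroups, split = "PG2",
                                     key = "sample_id") {
  pg <- phenogroups[outcomes[[key]]]
  ok <- !is.na(pg)
  side <- ifelse(pg[ok] == split, split, paste0("not_", split))
  if (length(unique(side)) < 2L) stop("empty side of the PhenoGroup split")
  km_logrank(outcomes$time_to_next_treatment[ok], outcomes$event[ok], side)
}
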
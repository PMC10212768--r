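#' Normalize a raw proteotype matrix
#'
#' Log10-transforms positive raw abundances, masks each protein's
#' low-abundance tail (entries strictly below the per-protein
#' `low_abundance_quantile` quantile become missing, emulating the NaN-ing
#' of low-abundant measurements), then z-scores across proteins (each row
#' mean 0, sd 1 over non-missing values) and subsequently across samples.
#' Constant protein rows cannot be z-scored and are set missing with a
#' warning.
#'
#' @param raw Matrix proteins x samples of positive abundances (NA =
#'   missing).
#' @param low_abundance_quantile Per-protein masking quantile (default
#'   0.05; 0 disables masking).
#' @param steps `"both"` (default) or `"protein_only"` to stop after the
#'   across-protein z-step (each row exactly mean 0, sd 1).
#' @return Matrix of normalized abundances with attribute
#'   `normalization = "log10-z-protein-z-sample"`.
#' @export
normalize_proteome <- function(raw, low_abundance_quantile = 0.05,
                               steps = c("both", "protein_only")) {
  steps <- match.arg(steps)
  raw <- as.matrix(raw)
  bad <- which(!is.na(raw) & raw <= 0)
  if (length(bad) > 0) {
    stop("non-positive abundances at entries: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  m <- log10(raw)
  if (low_abundance_quantile > 0) {
    for (i in seq_len(nrow(m))) {
      v <- m[i, ]
      if (all(is.na(v))) next
      floor_i <- stats::quantile(v, low_abundance_quantile, na.rm = TRUE,
                                 names = FALSE)
      m[i, !is.na(v) & v < floor_i] <- NA_real_
    }
  }
  rs <- apply(m, 1, stats::sd, na.rm = TRUE)
  const <- !is.na(rs) & rs < 1e-12
  if (any(const)) {
    warning(sum(const), " constant protein row(s) set to missing")
    m[const, ] <- NA_real_
  }
  m <- t(scale(t(m)))          # z across proteins
  if (steps == "both") m <- scale(m)  # then z across samples
  m <- m[, , drop = FALSE]
  attr(m, "normalization") <- "log10-z-protein-z-sample"
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  m
}

#' Discovery associations: protein abundance vs myeloma fraction
#'
#' Spearman correlation (with exact permutation p-values for n <= 8, t
#' approximation otherwise) of each protein's abundance with the per-sample
#' fraction of big cells among plasma cells, on pairwise-complete data.
#' Records the signed log10 p and Storey q-values.
#'
#' @param proteome Normalized matrix proteins x samples.
#' @param fraction_big Named numeric vector sample -> fraction.
#' @param min_pairs Minimum complete pairs per protein (default 10; others
#'   are omitted and listed in the `skipped` attribute).
#' @return data.frame: `protein`, `partner`, `rho`, `p`, `signed_logp`,
#'   `q`, `n`.
#' @export
discovery_associations <- function(proteome, fraction_big, min_pairs = 10L) {
  common <- intersect(colnames(proteome), names(fraction_big))
  fb <- fraction_big[common]
  rows <- vector("list", nrow(proteome))
  skipped <- character(0)
  for (i in seq_len(nrow(proteome))) {
    x <- proteome[i, common]
    st <- spearman_test(x, fb)
    if (st$n < min_pairs || is.na(st$rho)) {
      skipped <- c(skipped, rownames(proteome)[i])
      next
    }
    rows[[i]] <- data.frame(protein = rownames(proteome)[i],
                            partner = "myeloma_fraction",
                            rho = st$rho, p = st$p,
                            signed_logp = st$signed_logp, n = st$n,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(protein = character(0), partner = character(0),
                      rho = numeric(0), p = numeric(0),
                      signed_logp = numeric(0), n = integer(0))
  }
  res$q <- storey_qvalue(res$p)
  attr(res, "skipped") <- skipped
  res
}

#' Validation fold changes: FACS-sorted big vs small plasma cells
#'
#' Per protein, the mean over pairs of (big - small) on the log2 scale and
#' a two-sided paired t-test p-value. Proteins with fewer than 2 complete
#' pairs are reported missing; an all-zero difference vector yields an
#' undefined t and is reported as p = 1.
#'
#' @param big,small Matrices proteins x pairs of log2-scale abundances.
#' @return data.frame: `protein`, `log2fc`, `p`, `n_pairs`.
#' @export
validation_foldchanges <- function(big, small) {
  stopifnot(all(dim(big) == dim(small)))
  rows <- lapply(seq_len(nrow(big)), function(i) {
    d <- big[i, ] - small[i, ]
    d <- d[is.finite(d)]
    if (length(d) < 2L) {
      return(data.frame(protein = rownames(big)[i], log2fc = NA_real_,
                        p = NA_real_, n_pairs = length(d),
                        stringsAsFactors = FALSE))
    }
    fc <- mean(d)
    p <- if (stats::sd(d) < 1e-15) {
      if (abs(fc) < 1e-15) 1 else 1e-300  # all identical differences
    } else {
      stats::t.test(d)$p.value
    }
    data.frame(protein = rownames(big)[i], log2fc = fc, p = p,
               n_pairs = length(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select the quadrant signature with Fisher concordance
#'
#' Proteins in the up (myeloma-associated) signature have discovery
#' `p < p_cut` with positive rho and validation `log2FC > fc_cut` (strict);
#' the down (small-cell) signature is the mirrored quadrant. Fisher's exact
#' two-sided test on the 2x2 table of discovery sign x validation sign,
#' among proteins passing both magnitude cutoffs, quantifies concordance
#' between the cohorts.
#'
#' @param discovery [discovery_associations()] output.
#' @param validation [validation_foldchanges()] output.
#' @param p_cut Discovery p cutoff (default 0.05).
#' @param fc_cut Validation |log2FC| cutoff (default 0.3, strict).
#' @return List of class `signature_set`: `up`, `down`, `fisher_p`,
#'   `quadrant_counts` (2x2), `thresholds`.
#' @export
select_signature <- function(discovery, validation, p_cut = 0.05,
                             fc_cut = 0.3) {
  if (nrow(discovery) == 0L || nrow(validation) == 0L) {
    warning("empty discovery or validation table; empty signature")
    return(structure(list(up = character(0), down = character(0),
                          fisher_p = 1,
                          quadrant_counts = matrix(0, 2, 2),
                          thresholds = c(p_cut = p_cut, fc_cut = fc_cut)),
                     class = "signature_set"))
  }
  m <- merge(discovery[, c("protein", "rho", "p")],
             validation[, c("protein", "log2fc", "p")],
             by = "protein", suffixes = c("_disc", "_val"))
  m <- m[stats::complete.cases(m[, c("rho", "p_disc", "log2fc")]), ]
  pass <- m$p_disc < p_cut & abs(m$log2fc) > fc_cut
  up <- m$protein[pass & m$rho > 0 & m$log2fc > fc_cut]
  down <- m$protein[pass & m$rho < 0 & m$log2fc < -fc_cut]
  tab <- table(factor(m$rho[pass] > 0, levels = c(FALSE, TRUE)),
               factor(m$log2fc[pass] > 0, levels = c(FALSE, TRUE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate concordance table; Fisher p set to 1")
    fp <- 1
  } else {
    fp <- stats::fisher.test(tab)$p.value
  }
  structure(list(up = up, down = down, fisher_p = fp,
                 quadrant_counts = tab,
                 thresholds = c(p_cut = p_cut, fc_cut = fc_cut)),
            class = "signature_set")
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric p-value per gene set for overlap with a
#' signature, within a declared universe, with Benjamini-Hochberg FDR.
#'
#' @param signature Character vector of hit genes/proteins.
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector; signature and sets are intersected
#'   with it.
#' @return data.frame: `set`, `overlap`, `set_size`, `signature_size`,
#'   `universe_size`, `p`, `fdr`, ordered by p.
#' @export
geneset_enrichment <- function(signature, gene_sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  signature <- intersect(signature, universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(set, signature))
    p <- stats::phyper(k - 1, length(signature),
                       length(universe) - length(signature),
                       length(set), lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = length(set),
               signature_size = length(signature),
               universe_size = length(universe), p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res[order(res$p), ]
}

#' Regress myeloma content out of a proteome
#'
#' Per protein, ordinary least squares of abundance on the covariate (with
#' intercept) over complete pairs; residuals replace abundances and missing
#' entries stay missing. A constant covariate yields centered abundances
#' with a warning.
#'
#' @param proteome Matrix proteins x samples.
#' @param covariate Named numeric vector sample -> covariate (e.g. myeloma
#'   fraction).
#' @return Residual matrix, same dimensions and dimnames.
#' @export
regress_out_covariate <- function(proteome, covariate) {
  common <- intersect(colnames(proteome), names(covariate))
  if (length(common) < ncol(proteome)) {
    proteome <- proteome[, common, drop = FALSE]
  }
  cv <- covariate[colnames(proteome)]
  out <- proteome
  out[] <- NA_real_
  if (stats::sd(cv, na.rm = TRUE) < 1e-12) {
    warning("constant covariate: residuals are centered abundances")
    for (i in seq_len(nrow(proteome))) {
      x <- proteome[i, ]
      out[i, ] <- x - mean(x, na.rm = TRUE)
    }
    return(out)
  }
  for (i in seq_len(nrow(proteome))) {
    x <- proteome[i, ]
    ok <- is.finite(x) & is.finite(cv)
    if (sum(ok) < 3L) next
    fit <- stats::lm.fit(cbind(1, cv[ok]), x[ok])
    out[i, ok] <- fit$residuals
  }
  out
}

#' Drug-protein association network
#'
#' Spearman associations between residual protein expression and
#' (non-imputed) drug responses. Node proteins are those with
#' `|rho| > rho_cut` and `p < p_cut` for any drug, plus the top-two and
#' bottom-two strongest associations per drug. Edges are restricted to the
#' user-supplied interaction list (e.g. a STRING export) and isolated nodes
#' are dropped.
#'
#' @param residual Matrix proteins x samples of residual expression.
#' @param drm `drug_response_matrix` (imputed entries excluded) or a bare
#'   matrix samples x treatments.
#' @param edges data.frame with two columns of protein ids (may be empty).
#' @param rho_cut,p_cut Selection thresholds (defaults 0.585 / 0.05).
#' @param min_pairs Minimum complete pairs per (protein, drug).
#' @return List of class `drug_protein_network`: `associations` (long
#'   data.frame), `selected` (node proteins before edge filtering), `nodes`
#'   (data.frame protein x per-drug rho, after dropping isolated nodes),
#'   `edges`.
#' @export
drug_protein_network <- function(residual, drm, edges,
                                 rho_cut = 0.585, p_cut = 0.05,
                                 min_pairs = 10L) {
  if (inherits(drm, "drug_response_matrix")) {
    pcy <- drm$pcy
    pcy[drm$imputed] <- NA_real_   # imputed responses never feed statistics
  } else {
    pcy <- as.matrix(drm)
  }
  common <- intersect(colnames(residual), rownames(pcy))
  rows <- list()
  for (d in colnames(pcy)) {
    y <- pcy[common, d]
    for (i in seq_len(nrow(residual))) {
      st <- spearman_test(residual[i, common], y)
      if (st$n < min_pairs || is.na(st$rho)) next
      rows[[length(rows) + 1L]] <- data.frame(
        protein = rownames(residual)[i], drug = d, rho = st$rho, p = st$p,
        n = st$n, stringsAsFactors = FALSE)
    }
  }
  assoc <- do.call(rbind, rows)
  selected <- character(0)
  if (!is.null(assoc)) {
    selected <- unique(assoc$protein[abs(assoc$rho) > rho_cut & assoc$p < p_cut])
    for (d in unique(assoc$drug)) {
      a <- assoc[assoc$drug == d, ]
      a <- a[order(a$rho), ]
      selected <- union(selected,
                        c(utils::head(a$protein, 2), utils::tail(a$protein, 2)))
    }
  }
  if (is.null(edges) || nrow(edges) == 0) {
    warning("empty interaction list: network has no edges")
    keep_edges <- data.frame(a = character(0), b = character(0))
  } else {
    colnames(edges)[1:2] <- c("a", "b")
    keep_edges <- edges[edges$a %in% selected & edges$b %in% selected, 1:2]
  }
  connected <- unique(c(keep_edges$a, keep_edges$b))
  node_rho <- NULL
  if (length(connected) > 0) {
    node_rho <- do.call(rbind, lapply(connected, function(p) {
      r <- stats::setNames(rep(NA_real_, ncol(pcy)), colnames(pcy))
      a <- assoc[assoc$protein == p, ]
      r[a$drug] <- a$rho
      r
    }))
    rownames(node_rho) <- connected
  }
  structure(list(associations = assoc, selected = selected,
                 nodes = node_rho, edges = keep_edges),
            class = "drug_protein_network")
}
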
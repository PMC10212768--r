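#' Quality-filter scRNA-seq cells
#'
#' Keeps cells with (1) at least 300 UMIs not counting immunoglobulin
#' genes (cells with fewer than 300 are removed), (2) mitochondrial
#' content of at most 50% (cells with more are removed), and (3) zero
#' counts on every exclusion-marker gene (any expression of S100A8, CD14,
#' CD3D, CD3E, TRAC, COL1A2 or C1QA removes the cell). Per-rule removal
#' counts are reported.
#'
#' @param counts Genes x cells matrix (sparse or dense), rownames = genes.
#' @param gene_flags data.frame with `gene`, `is_immunoglobulin`,
#'   `is_mitochondrial`, `is_exclusion_marker` (see [generate_scrna()]).
#' @param min_umi Non-Ig UMI threshold (default 300; keep >= 300).
#' @param max_mito Maximum mitochondrial fraction (default 0.5; keep <= 0.5).
#' @return List: `keep` (character vector of surviving cell ids),
#'   `removed` (named counts per rule, overlaps counted in each rule they
#'   violate).
#' @export
scrna_qc_filter <- function(counts, gene_flags, min_umi = 300L,
                            max_mito = 0.5) {
  stopifnot(all(rownames(counts) %in% gene_flags$gene))
  flags <- gene_flags[match(rownames(counts), gene_flags$gene), ]
  total <- Matrix::colSums(counts)
  non_ig <- Matrix::colSums(counts[!flags$is_immunoglobulin, , drop = FALSE])
  low_umi <- non_ig < min_umi
  if (any(flags$is_mitochondrial)) {
    mito_frac <- Matrix::colSums(counts[flags$is_mitochondrial, , drop = FALSE]) /
      pmax(total, 1)
    high_mito <- mito_frac > max_mito
  } else {
    warning("no mitochondrial gene flags: mito rule skipped")
    high_mito <- rep(FALSE, ncol(counts))
  }
  if (any(flags$is_exclusion_marker)) {
    marker_pos <- Matrix::colSums(counts[flags$is_exclusion_marker, ,
                                         drop = FALSE]) > 0
  } else {
    marker_pos <- rep(FALSE, ncol(counts))
  }
  keep <- !(low_umi | high_mito | marker_pos)
  list(keep = colnames(counts)[keep],
       removed = c(low_umi = sum(low_umi), high_mito = sum(high_mito),
                   marker_positive = sum(marker_pos),
                   total_removed = sum(!keep)))
}

#' Score cells by the big-like signature ratio
#'
#' Per-cell score = mean expression of the big-associated (up) genes
#' divided by the mean expression of the small-associated (down) genes,
#' on library-size-normalized expression (counts per 10,000, log1p).
#' Undetected genes and immunoglobulin genes are dropped from both lists.
#' A cell is big-like if its score exceeds the median of all scores
#' (default rule) or a fixed ratio (`rule = "fixed_ratio"`, cutoff 5).
#' A pseudocount of 1e-9 x the global mean expression guards zero
#' denominators.
#'
#' @param counts Genes x cells matrix of the QC-passing cells.
#' @param up,down Character vectors of signature gene names.
#' @param gene_flags Optional flags data.frame (to drop Ig genes).
#' @param rule `"median"` (default) or `"fixed_ratio"`.
#' @param fixed_cutoff Score cutoff used by the fixed-ratio rule.
#' @return data.frame: `cell`, `score`, `big_like`; attribute
#'   `threshold_rule` records the rule and realized threshold.
#' @export
big_like_scores <- function(counts, up, down, gene_flags = NULL,
                            rule = c("median", "fixed_ratio"),
                            fixed_cutoff = 5) {
  rule <- match.arg(rule)
  detected <- rownames(counts)[Matrix::rowSums(counts) > 0]
  if (!is.null(gene_flags)) {
    ig <- gene_flags$gene[gene_flags$is_immunoglobulin]
    detected <- setdiff(detected, ig)
  }
  up <- intersect(up, detected)
  down <- intersect(down, detected)
  if (length(up) == 0L || length(down) == 0L) {
    stop("empty signature gene list after dropping undetected and Ig genes")
  }
  lib <- Matrix::colSums(counts)
  norm <- function(genes) {
    sub <- counts[genes, , drop = FALSE]
    cp10k <- Matrix::t(Matrix::t(sub) / pmax(lib, 1)) * 1e4
    Matrix::colMeans(log1p(cp10k))
  }
  up_mean <- norm(up)
  down_mean <- norm(down)
  pseudo <- 1e-9 * mean(c(up_mean, down_mean))
  score <- up_mean / (down_mean + pseudo)
  threshold <- if (rule == "median") stats::median(score) else fixed_cutoff
  res <- data.frame(cell = colnames(counts), score = score,
                    big_like = score > threshold, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "threshold_rule") <- list(rule = rule, threshold = threshold)
  res
}

#' Per-patient big-like fractions and disease-state test
#'
#' Fraction of big-like cells per patient, compared between two
#' disease-state groups with a Welch two-sided t-test.
#'
#' @param scores [big_like_scores()] output.
#' @param patients Named character vector cell -> patient id (or vector
#'   aligned with `scores$cell`).
#' @param groups Named character vector patient -> group label.
#' @return List: `fractions` (data.frame patient, n_cells, fraction,
#'   group), `test` (htest or NULL), `direction` (group with the higher
#'   mean fraction, or NA).
#' @export
fraction_big_like <- function(scores, patients, groups) {
  pat <- if (!is.null(names(patients))) patients[scores$cell] else patients
  fr <- do.call(rbind, lapply(unique(pat), function(p) {
    sel <- pat == p
    data.frame(patient = p, n_cells = sum(sel),
               fraction = mean(scores$big_like[sel]),
               stringsAsFactors = FALSE)
  }))
  fr$group <- groups[fr$patient]
  lv <- unique(stats::na.omit(fr$group))
  if (length(lv) != 2L || any(table(fr$group) < 2)) {
    warning("need two groups with >= 2 patients each: test skipped")
    return(list(fractions = fr, test = NULL, direction = NA_character_))
  }
  tt <- stats::t.test(fraction ~ group, data = fr)
  means <- tapply(fr$fraction, fr$group, mean)
  list(fractions = fr, test = tt,
       direction = names(means)[which.max(means)])
}

#' Normalize a cytokine panel with detection-limit handling
#'
#' Below-limit-of-detection entries become missing; above-maximum entries
#' are replaced by the maximum observed (in-range) value of that cytokine
#' across the cohort. Concentrations are then log10-transformed, z-scored
#' per cytokine across samples, and finally z-scored per sample across
#' cytokines (missing values ignored in all moments). Cytokines missing in
#' every sample are dropped with a warning.
#'
#' @param concentration Matrix cytokines x samples of concentrations.
#' @param status Character matrix of the same shape: `"ok"`,
#'   `"below_lod"`, `"above_max"`.
#' @param steps `"both"` (default) or `"cytokine_only"` to stop after the
#'   per-cytokine z-step.
#' @return Normalized matrix (NA = below LOD or undefined).
#' @export
normalize_cytokines <- function(concentration, status,
                                steps = c("both", "cytokine_only")) {
  steps <- match.arg(steps)
  stopifnot(all(dim(concentration) == dim(status)))
  x <- as.matrix(concentration)
  x[status == "below_lod"] <- NA_real_
  for (i in seq_len(nrow(x))) {
    am <- status[i, ] == "above_max"
    if (any(am)) {
      mx <- suppressWarnings(max(x[i, status[i, ] == "ok"], na.rm = TRUE))
      x[i, am] <- if (is.finite(mx)) mx else NA_real_
    }
  }
  all_na <- apply(x, 1, function(v) all(is.na(v)))
  if (any(all_na)) {
    warning("dropping ", sum(all_na), " cytokine(s) missing in all samples")
    x <- x[!all_na, , drop = FALSE]
  }
  x <- log10(x)
  x <- t(scale(t(x)))          # z per cytokine across samples
  if (steps == "both") x <- scale(x)  # z per sample across cytokines
  x <- x[, , drop = FALSE]
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  x
}
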
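#' Write a synthetic cohort to plain-text files
#'
#' Emits `cells.tsv`, `plate_layout.csv`, `proteome.tsv`,
#' `validation_big.tsv`/`validation_small.tsv`, `cytokines.csv`,
#' `matrix.mtx` + `genes.tsv` + `scrna_cells.tsv` (when scRNA data are
#' present), `clinical.csv` and `ground_truth.json` under `dir`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(obj, file, fun) {
    p <- file.path(dir, file)
    fun(obj, p)
    paths <<- c(paths, p)
  }
  wt <- function(df, p) utils::write.table(df, p, sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  wm <- function(mat, p) {
    df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  w(cohort$cells, "cells.tsv", wt)
  w(cohort$layout, "plate_layout.csv",
    function(df, p) utils::write.csv(df, p, row.names = FALSE))
  w(cohort$proteome, "proteome.tsv", wm)
  w(cohort$proteome_validation$big, "validation_big.tsv", wm)
  w(cohort$proteome_validation$small, "validation_small.tsv", wm)
  if (!is.null(cohort$cytokines)) {
    w(cohort$cytokines$concentration, "cytokines.csv", function(mat, p) {
      long <- data.frame(cytokine = rownames(mat)[row(mat)],
                         sample_id = colnames(mat)[col(mat)],
                         concentration = as.vector(mat),
                         status = as.vector(cohort$cytokines$status))
      utils::write.csv(long, p, row.names = FALSE)
    })
  }
  if (!is.null(cohort$scrna)) {
    p <- file.path(dir, "matrix.mtx")
    Matrix::writeMM(cohort$scrna$counts, p)
    paths <- c(paths, p)
    w(cohort$scrna$genes, "genes.tsv", wt)
    w(cohort$scrna$cells, "scrna_cells.tsv", wt)
  }
  w(cohort$clinical, "clinical.csv",
    function(df, p) utils::write.csv(df, p, row.names = FALSE))
  w(cohort$truth, "ground_truth.json", function(obj, p) {
    obj$subcluster_catalogue <- NULL
    obj$true_kill_fraction <- as.vector(obj$true_kill_fraction)
    jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  })
  invisible(paths)
}

#' Read a single-cell feature table
#' @param path Path to a cells.tsv written by [write_cohort()] or with the
#'   same columns.
#' @return data.frame.
#' @export
read_cells <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a plate layout CSV
#' @param path Path to plate_layout.csv.
#' @return data.frame.
#' @export
read_layout <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a proteome TSV (first column = protein id)
#' @param path Path to proteome.tsv.
#' @return Numeric matrix proteins x samples.
#' @export
read_proteome <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a drug-response matrix and its imputation mask
#' @param drm A `drug_response_matrix`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_drug_response <- function(drm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "drug_response.tsv")
  p2 <- file.path(dir, "drug_response_mask.tsv")
  df <- data.frame(sample_id = rownames(drm$pcy), drm$pcy, check.names = FALSE)
  utils::write.table(df, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  dfm <- data.frame(sample_id = rownames(drm$imputed), drm$imputed,
                    check.names = FALSE)
  utils::write.table(dfm, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}
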
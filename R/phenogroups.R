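#' Select latent features by PC1/PC2 contribution
#'
#' PCA of the standardized latent features; the contribution of feature j
#' is the variance-weighted absolute loading
#' `lambda1 * |l1j| + lambda2 * |l2j|` (lambda = explained variance of the
#' component). The indices of the top `n_keep` features, sorted by
#' descending contribution, are returned (all features when F <= n_keep).
#'
#' @param X Numeric matrix cells x features.
#' @param n_keep Number of features to keep (default 100).
#' @return Integer vector of selected column indices; attribute
#'   `variance_explained` records the PC1+PC2 share.
#' @export
select_latent_features <- function(X, n_keep = 100L) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("need at least 2 features")
  sds <- apply(X, 2, stats::sd)
  if (all(sds < 1e-12)) stop("zero-variance feature matrix")
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  lam <- pc$sdev^2
  contrib <- lam[1] * abs(pc$rotation[, 1]) + lam[2] * abs(pc$rotation[, 2])
  idx <- order(contrib, decreasing = TRUE)[seq_len(min(n_keep, ncol(X)))]
  attr(idx, "variance_explained") <- sum(lam[1:2]) / sum(lam)
  idx
}

#' Balanced training subsample for subcluster fitting
#'
#' Draws up to `per_sample` cells from each sample's control (DMSO) wells,
#' as equally balanced among the four cell classes as availability permits
#' (at full scale the study used ~1,200 cells per sample).
#'
#' @param cells Quality-filtered cells.
#' @param layout Plate layout (to identify DMSO wells).
#' @param per_sample Target cells per sample.
#' @param seed Seed for the subsample draw.
#' @return Integer row indices into `cells`.
#' @export
balanced_training_sample <- function(cells, layout, per_sample = 1200L,
                                     seed = 1L) {
  dmso_wells <- layout$well_id[layout$control_type == "dmso"]
  ctrl <- which(cells$well_id %in% dmso_wells)
  with_seed(seed, {
    idx <- integer(0)
    for (s in unique(cells$sample_id)) {
      rows <- ctrl[cells$sample_id[ctrl] == s]
      classes <- unique(cells$cell_class[rows])
      per_class <- ceiling(per_sample / length(classes))
      take <- unlist(lapply(classes, function(cl) {
        r <- rows[cells$cell_class[rows] == cl]
        if (length(r) > per_class) sample(r, per_class) else r
      }))
      if (length(take) > per_sample) take <- sample(take, per_sample)
      idx <- c(idx, take)
    }
    sort(idx)
  })
}

# Blockwise k-nearest-neighbor indices of `query` among `ref` (Euclidean);
# returns an n_query x k matrix of row indices into `ref`.
knn_indices <- function(ref, query, k, block = 2000L) {
  ref2 <- rowSums(ref^2)
  out <- matrix(0L, nrow(query), k)
  for (start in seq(1L, nrow(query), by = block)) {
    end <- min(start + block - 1L, nrow(query))
    q <- query[start:end, , drop = FALSE]
    d2 <- outer(rowSums(q^2), ref2, "+") - 2 * q %*% t(ref)
    for (i in seq_len(nrow(q))) {
      out[start + i - 1L, ] <- order(d2[i, ])[seq_len(k)]
    }
  }
  out
}

#' Fit phenotypic subclusters by spectral clustering
#'
#' Standardizes the selected features on the training cells, builds a
#' symmetrized k-nearest-neighbor graph (15 neighbors), embeds it with the
#' normalized-Laplacian (`D^{-1/2} A D^{-1/2}`) spectral embedding and
#' partitions the embedding into `k` clusters with seeded k-means. The
#' scaler, training features and labels are retained so held-out cells can
#' be k-NN-propagated into the same clusters.
#'
#' @param X Training-cell feature matrix (cells x features, already
#'   restricted to the selected features).
#' @param k Number of subclusters (default 15).
#' @param graph_neighbors Neighbors in the affinity graph (default 15).
#' @param knn_k Neighbors used later for label propagation (default 15).
#' @param seed Seed for embedding/k-means.
#' @param meta Optional data.frame of per-training-cell annotations (e.g.
#'   `cell_class`), carried along for composition labelling.
#' @return List of class `subcluster_model`: `center`, `scale`, `train`
#'   (standardized features), `labels`, `k`, `knn_k`, `meta`.
#' @export
fit_subclusters <- function(X, k = 15L, graph_neighbors = 15L, knn_k = 15L,
                            seed = 1L, meta = NULL) {
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k exceeds the number of training cells")
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scl, "/")
  nb <- knn_indices(Z, Z, graph_neighbors + 1L)[, -1, drop = FALSE]
  n <- nrow(Z)
  adj <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = ncol(nb)),
    j = as.vector(t(nb)), x = 1, dims = c(n, n)
  )
  adj <- (adj + Matrix::t(adj)) > 0  # symmetrize (union)
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected",
                                           weighted = NULL)
  labels <- with_seed(seed, {
    emb <- igraph::embed_laplacian_matrix(g, no = k, which = "lm",
                                          type = "DAD")
    km <- stats::kmeans(emb$X, centers = k, nstart = 10, iter.max = 100)
    km$cluster
  })
  structure(list(center = center, scale = scl, train = Z,
                 labels = labels, k = as.integer(k),
                 knn_k = as.integer(knn_k), meta = meta),
            class = "subcluster_model")
}

#' Propagate subcluster labels to held-out cells by k-NN
#'
#' Cells are standardized with the training scaler and assigned the
#' majority label among their `knn_k` nearest training cells (Euclidean in
#' the standardized space); ties are broken by the nearest neighbor's label.
#'
#' @param model A [fit_subclusters()] model.
#' @param X Feature matrix of the cells to classify (same columns as the
#'   training features).
#' @return Integer vector of subcluster labels 1..k.
#' @export
assign_subclusters <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$center)) {
    stop("feature mismatch: expected ", length(model$center),
         " features, got ", ncol(X))
  }
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  nb <- knn_indices(model$train, Z, model$knn_k)
  apply(nb, 1, function(idx) {
    votes <- table(model$labels[idx])
    winners <- as.integer(names(votes)[votes == max(votes)])
    if (length(winners) == 1L) return(winners)
    # tie: the nearest neighbor (first index) decides
    nearest <- model$labels[idx]
    nearest[nearest %in% winners][1]
  })
}

#' Sample composition over subclusters from control-well cells
#'
#' Per-sample fractions of DMSO-control cells in each subcluster; rows sum
#' to 1. Samples with fewer than `min_cells` control cells are dropped with
#' a message.
#'
#' @param cells Cells with `sample_id` and `well_id`.
#' @param labels Integer subcluster labels aligned with `cells` rows.
#' @param layout Plate layout (identifies DMSO wells).
#' @param k Number of subclusters.
#' @param min_cells Minimum control cells per sample (default 50).
#' @return Matrix samples x k of fractions.
#' @export
sample_composition <- function(cells, labels, layout, k,
                               min_cells = 50L) {
  dmso_wells <- layout$well_id[layout$control_type == "dmso"]
  sel <- cells$well_id %in% dmso_wells
  if (!any(sel)) stop("no control-well cells found")
  sid <- cells$sample_id[sel]
  lab <- labels[sel]
  samples <- unique(sid)
  comp <- matrix(NA_real_, length(samples), k,
                 dimnames = list(samples, paste0("SC", seq_len(k))))
  drop <- character(0)
  for (s in samples) {
    l <- lab[sid == s]
    if (length(l) < min_cells) {
      drop <- c(drop, s)
      next
    }
    comp[s, ] <- tabulate(l, nbins = k) / length(l)
  }
  if (length(drop) > 0) {
    message("dropping ", length(drop), " sample(s) with < ", min_cells,
            " control cells")
    comp <- comp[setdiff(samples, drop), , drop = FALSE]
  }
  comp
}

#' Derive PhenoGroups from sample compositions
#'
#' Sample-to-sample similarity is the pairwise correlation of composition
#' rows (Pearson by default); hierarchical clustering (average linkage) on
#' the `1 - similarity` distance is cut into exactly `n_groups` groups.
#' Groups are labelled PG1..PGn by descending mean abundance of the
#' myeloma-dominated subclusters, so PG1 is the most myeloma-rich mode.
#'
#' @param composition Matrix samples x subclusters ([sample_composition()]).
#' @param n_groups Number of PhenoGroups (default 3).
#' @param plasma_weight Numeric vector over subclusters weighting the
#'   myeloma content used for label ordering (e.g. the per-subcluster
#'   myeloma fraction of the training cells); default: first subcluster.
#' @param cor_method `"pearson"` (default) or `"spearman"`.
#' @return List of class `phenogroup_assignment`: `groups` (named character
#'   vector sample -> "PG1".."PGn"), `similarity`, `hclust`.
#' @export
derive_phenogroups <- function(composition, n_groups = 3L,
                               plasma_weight = NULL,
                               cor_method = c("pearson", "spearman")) {
  cor_method <- match.arg(cor_method)
  if (nrow(composition) < n_groups) stop("fewer samples than groups")
  const <- apply(composition, 1, function(r) stats::sd(r) < 1e-15)
  sim <- suppressWarnings(stats::cor(t(composition), method = cor_method))
  if (any(const)) {
    warning("constant composition row(s); undefined correlations set to 0")
    sim[is.na(sim)] <- 0
  }
  diag(sim) <- 1
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  raw <- stats::cutree(hc, k = n_groups)
  if (is.null(plasma_weight)) {
    plasma_weight <- c(1, rep(0, ncol(composition) - 1))
  }
  myeloma_load <- as.numeric(composition %*% plasma_weight)
  grp_load <- tapply(myeloma_load, raw, mean)
  ord <- order(grp_load, decreasing = TRUE)
  relabel <- stats::setNames(paste0("PG", seq_len(n_groups)), names(grp_load)[ord])
  groups <- stats::setNames(relabel[as.character(raw)], rownames(composition))
  structure(list(groups = groups, similarity = sim, hclust = hc),
            class = "phenogroup_assignment")
}

#' End-to-end PhenoGroup derivation from cells
#'
#' Feature selection, balanced training subsample, spectral subcluster
#' fitting, k-NN propagation to all control cells, composition and
#' dendrogram cut, in one call.
#'
#' @param cells Quality-filtered cells carrying `latent_*` columns.
#' @param layout Plate layout.
#' @param k Number of spectral subclusters (default 15).
#' @param n_groups Number of PhenoGroups (default 3).
#' @param n_features Latent features kept (default 100).
#' @param per_sample Training cells per sample (default 1200; scale down
#'   for desk-size runs).
#' @param min_confidence Confidence filter (default 0.6).
#' @param seed Seed controlling subsample, embedding and k-means.
#' @return List: `assignment` ([derive_phenogroups()] result),
#'   `composition`, `model`, `selected_features`, `subcluster_labels`
#'   (aligned with `cell_ids`), `cell_ids` (ids of the scored control
#'   cells).
#' @export
phenogroup_pipeline <- function(cells, layout, k = 15L, n_groups = 3L,
                                n_features = 100L, per_sample = 1200L,
                                min_confidence = 0.6, seed = 1L) {
  cells <- filter_cells(cells, min_confidence)
  feat_cols <- grep("^latent_", names(cells), value = TRUE)
  if (length(feat_cols) < 2L) stop("cells carry no latent feature columns")
  train_idx <- balanced_training_sample(cells, layout, per_sample, seed)
  Xtrain_full <- as.matrix(cells[train_idx, feat_cols, drop = FALSE])
  sel <- select_latent_features(Xtrain_full, n_features)
  model <- fit_subclusters(Xtrain_full[, sel, drop = FALSE], k = k,
                           seed = seed,
                           meta = cells[train_idx,
                                        intersect(c("cell_class", "plasma_subtype"),
                                                  names(cells)),
                                        drop = FALSE])
  dmso_wells <- layout$well_id[layout$control_type == "dmso"]
  ctrl <- which(cells$well_id %in% dmso_wells)
  Xall <- as.matrix(cells[ctrl, feat_cols, drop = FALSE])[, sel, drop = FALSE]
  labels <- assign_subclusters(model, Xall)
  comp <- sample_composition(cells[ctrl, , drop = FALSE], labels, layout, k)
  pw <- if (!is.null(model$meta) && "plasma_subtype" %in% names(model$meta)) {
    vapply(seq_len(k), function(j) {
      mean(model$meta$plasma_subtype[model$labels == j] == "myeloma")
    }, numeric(1))
  } else NULL
  assignment <- derive_phenogroups(comp, n_groups, plasma_weight = pw)
  list(assignment = assignment, composition = comp, model = model,
       selected_features = sel, subcluster_labels = labels,
       cell_ids = if ("cell_id" %in% names(cells)) cells$cell_id[ctrl] else ctrl)
}
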
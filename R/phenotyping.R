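#' Default marker gating thresholds
#'
#' Positivity cutoffs per channel (linear intensity), the big/small plasma
#' diameter cutoff and the minimum classification confidence. The channel
#' cutoffs sit midway (log scale) between the background and positive
#' intensity modes of the synthetic generator; on real feature tables they
#' should be set per staining batch. The diameter cutoff of 11 um separates
#' the big (myeloma, ~14 um) and small (~8.5 um) plasma morphologies.
#'
#' @param channel_cutoff Named numeric vector of per-channel cutoffs.
#' @param big_small_diameter_cutoff Diameter cutoff in um.
#' @param min_confidence Minimum class confidence (strictly exceeded).
#' @return A `gating_thresholds` list.
#' @export
gating_thresholds <- function(channel_cutoff = c(CD138 = 10^0.75,
                                                 CD319 = 10^0.75,
                                                 CD3 = 10^0.75,
                                                 CD14 = 10^0.75),
                              big_small_diameter_cutoff = 11,
                              min_confidence = 0.6) {
  stopifnot(all(is.finite(channel_cutoff)), all(channel_cutoff > 0),
            is.finite(big_small_diameter_cutoff),
            big_small_diameter_cutoff > 0)
  structure(list(channel_cutoff = channel_cutoff,
                 big_small_diameter_cutoff = big_small_diameter_cutoff,
                 min_confidence = min_confidence),
            class = "gating_thresholds")
}

#' Filter cells by classification confidence
#'
#' Keeps cells with `class_confidence` strictly greater than the cutoff
#' (cells at exactly the cutoff are discarded). Order is preserved.
#'
#' @param cells data.frame with a `class_confidence` column.
#' @param min_confidence Confidence cutoff (default 0.6).
#' @return The filtered data.frame.
#' @export
filter_cells <- function(cells, min_confidence = 0.6) {
  stopifnot("class_confidence" %in% names(cells))
  cells[cells$class_confidence > min_confidence, , drop = FALSE]
}

#' Assign exclusive cell classes by marker gating
#'
#' Stand-in for the CNN classifier when only marker intensities are
#' available: a cell is `plasma` if CD138 or CD319 exceeds its cutoff
#' (single- or double-positive), else `t_cell` if CD3 is positive, else
#' `monocyte` if CD14 is positive, else `other`. Precedence
#' plasma > T > monocyte enforces exclusive classes.
#'
#' @param cells data.frame with intensity columns for all gated channels.
#' @param thresholds A [gating_thresholds()].
#' @return Character vector of classes, one per row of `cells`.
#' @export
gate_cell_class <- function(cells, thresholds = gating_thresholds()) {
  cut <- thresholds$channel_cutoff
  need <- c("CD138", "CD319", "CD3", "CD14")
  missing_ch <- setdiff(need, names(cells))
  if (length(missing_ch) > 0) {
    stop("missing marker channel(s): ", paste(missing_ch, collapse = ", "))
  }
  cls <- rep("other", nrow(cells))
  cls[cells$CD14 > cut[["CD14"]]] <- "monocyte"
  cls[cells$CD3 > cut[["CD3"]]] <- "t_cell"
  cls[cells$CD138 > cut[["CD138"]] | cells$CD319 > cut[["CD319"]]] <- "plasma"
  cls
}

#' Split plasma cells into big (myeloma) and small morphologies by diameter
#'
#' A plasma cell is labelled `myeloma` (big) iff its diameter is greater
#' than or equal to the cutoff, else `small`. Non-plasma cells get `none`.
#'
#' @param cells data.frame with `cell_class` and `diameter_um`.
#' @param diameter_cutoff Cutoff in um (default 11).
#' @return Character vector of plasma subtypes per row.
#' @export
split_plasma_by_size <- function(cells, diameter_cutoff = 11) {
  stopifnot(all(c("cell_class", "diameter_um") %in% names(cells)))
  out <- rep("none", nrow(cells))
  pl <- cells$cell_class == "plasma"
  out[pl] <- ifelse(cells$diameter_um[pl] >= diameter_cutoff,
                    "myeloma", "small")
  out
}

#' Per-sample fraction of big cells among plasma cells
#'
#' @param cells data.frame with `sample_id` and a `plasma_subtype` column
#'   (values `myeloma`/`small`/`none`).
#' @return data.frame `sample_id`, `n_big`, `n_small`, `fraction_big`
#'   (NA when the sample has no plasma cells).
#' @export
fraction_big <- function(cells) {
  samples <- unique(cells$sample_id)
  res <- lapply(samples, function(s) {
    sub <- cells[cells$sample_id == s, ]
    nb <- sum(sub$plasma_subtype == "myeloma")
    nsm <- sum(sub$plasma_subtype == "small")
    data.frame(sample_id = s, n_big = nb, n_small = nsm,
               fraction_big = if (nb + nsm == 0) NA_real_ else nb / (nb + nsm),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Marker-positivity threshold and fraction from a density histogram
#'
#' Reproduces the density-histogram thresholding used for time-course
#' positivity readouts (e.g. gamma-H2AX in myeloma cells): a kernel density
#' estimate of log10 intensity is computed; if it is bimodal the threshold
#' is placed at the density minimum between the two main modes, otherwise
#' the fall-back `mean + 2 sd` (log scale) is used and flagged. The
#' positive fraction is the share of cells above the threshold.
#'
#' @param intensities Positive intensities of the scored cells (at least 50
#'   finite values expected for a stable KDE).
#' @return List: `threshold` (linear scale), `fraction`, `fallback`
#'   (TRUE if the unimodal fall-back was used), `n`.
#' @export
marker_positive_fraction <- function(intensities) {
  x <- intensities[is.finite(intensities) & intensities > 0]
  n <- length(x)
  if (n == 0L) return(list(threshold = NA_real_, fraction = NA_real_,
                           fallback = TRUE, n = 0L))
  lx <- log10(x)
  if (stats::sd(lx) < 1e-12) {
    # degenerate: all intensities equal; nothing exceeds mean + 2 sd
    thr <- mean(lx) + 2 * stats::sd(lx)
    return(list(threshold = 10^thr, fraction = mean(lx > thr),
                fallback = TRUE, n = n))
  }
  d <- stats::density(lx, n = 512)
  peaks <- which(diff(sign(diff(d$y))) == -2) + 1L
  fallback <- TRUE
  thr <- mean(lx) + 2 * stats::sd(lx)
  if (length(peaks) >= 2L) {
    main <- peaks[order(d$y[peaks], decreasing = TRUE)][1:2]
    main <- sort(main)
    between <- seq(main[1], main[2])
    valley <- between[which.min(d$y[between])]
    # require a genuine dip between the modes
    if (d$y[valley] < 0.8 * min(d$y[main])) {
      thr <- d$x[valley]
      fallback <- FALSE
    }
  }
  list(threshold = 10^thr, fraction = mean(lx > thr), fallback = fallback,
       n = n)
}

#' Drug-induced cell-cell interaction score
#'
#' The raw contact fraction is the fraction of myeloma cells in a well that
#' have at least one effector cell (activated T cell or monocyte) within
#' `contact_radius_um` of their center (Euclidean center-to-center
#' distance). The normalized score divides the treatment-well fraction by
#' the mean fraction over matched control wells.
#'
#' @param cells Cells of one well, with `x_um`, `y_um`, `plasma_subtype`,
#'   `t_subtype`, `cell_class` columns.
#' @param effector `"activated_t"` or `"monocyte"`.
#' @param contact_radius_um Contact radius (default 15 um, about the sum of
#'   two typical cell radii).
#' @param method `"grid"` (bucketed spatial index) or `"brute"` (all-pairs);
#'   both give identical results.
#' @return Raw contact fraction in `[0, 1]`, or NA when the well has no
#'   myeloma cells.
#' @export
contact_fraction <- function(cells, effector = c("activated_t", "monocyte"),
                             contact_radius_um = 15,
                             method = c("grid", "brute")) {
  effector <- match.arg(effector)
  method <- match.arg(method)
  tum <- cells[cells$plasma_subtype == "myeloma", c("x_um", "y_um")]
  eff <- if (effector == "activated_t") {
    cells[cells$t_subtype == "activated", c("x_um", "y_um")]
  } else {
    cells[cells$cell_class == "monocyte", c("x_um", "y_um")]
  }
  if (nrow(tum) == 0L) return(NA_real_)
  if (nrow(eff) == 0L) return(0)
  r <- contact_radius_um
  if (method == "brute") {
    hit <- vapply(seq_len(nrow(tum)), function(i) {
      any((eff$x_um - tum$x_um[i])^2 + (eff$y_um - tum$y_um[i])^2 <= r^2)
    }, logical(1))
    return(mean(hit))
  }
  # grid method: bucket effectors into r-sized cells, check 3x3 neighborhood
  bx <- floor(eff$x_um / r); by <- floor(eff$y_um / r)
  key <- paste(bx, by)
  buckets <- split(seq_len(nrow(eff)), key)
  hit <- logical(nrow(tum))
  tbx <- floor(tum$x_um / r); tby <- floor(tum$y_um / r)
  for (i in seq_len(nrow(tum))) {
    for (dx in -1:1) {
      for (dy in -1:1) {
        idx <- buckets[[paste(tbx[i] + dx, tby[i] + dy)]]
        if (is.null(idx)) next
        if (any((eff$x_um[idx] - tum$x_um[i])^2 +
                (eff$y_um[idx] - tum$y_um[i])^2 <= r^2)) {
          hit[i] <- TRUE
          break
        }
      }
      if (hit[i]) break
    }
  }
  mean(hit)
}

#' Interaction scores per treatment, normalized to matched controls
#'
#' Computes the per-well contact fraction for every well of a sample and
#' normalizes treatment wells to the mean fraction over their matched
#' control wells (isotype for antibodies, DMSO otherwise).
#'
#' @param cells All cells of one sample.
#' @param layout Plate layout rows for that sample (see
#'   [build_plate_layout()] columns).
#' @param effector `"activated_t"` or `"monocyte"`.
#' @param contact_radius_um Contact radius in um.
#' @return data.frame: `sample_id`, `treatment`, `effector_class`,
#'   `raw_contact_fraction` (mean over wells), `normalized_score`.
#' @export
interaction_score <- function(cells, layout,
                              effector = c("activated_t", "monocyte"),
                              contact_radius_um = 15) {
  effector <- match.arg(effector)
  per_well <- vapply(layout$well_id, function(w) {
    contact_fraction(cells[cells$well_id == w, , drop = FALSE],
                     effector, contact_radius_um)
  }, numeric(1))
  ctrl_mean <- function(type) {
    v <- per_well[layout$control_type == type]
    mean(v, na.rm = TRUE)
  }
  dmso_mean <- ctrl_mean("dmso")
  iso_mean <- ctrl_mean("isotype")
  trts <- unique(layout$treatment[layout$control_type == "none"])
  res <- lapply(trts, function(trt) {
    sel <- layout$treatment == trt
    raw <- mean(per_well[sel], na.rm = TRUE)
    ctrl <- if (unique(layout$drug_class[sel])[1] == "antibody") iso_mean
            else dmso_mean
    data.frame(sample_id = cells$sample_id[1], treatment = trt,
               effector_class = effector,
               raw_contact_fraction = raw,
               normalized_score = if (is.finite(ctrl) && ctrl > 0) raw / ctrl
                                  else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
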
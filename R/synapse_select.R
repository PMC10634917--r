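# Synapse selection: scaffold cluster detection, rejection of nonspecific
# clusters by frame statistics, alpha-shape boundaries, en-face criteria,
# and restriction of analysis targets to the active-zone boundary.

#' Detect candidate synaptic clusters of a scaffold target
#'
#' DBSCAN on the scaffold localizations (48-nm radius, 10 minimum points by
#' default); clusters with fewer than `min_cluster_size` localizations are
#' relabeled as noise. Cluster labels are renumbered consecutively.
#'
#' @param table a [loc_table()].
#' @param eps_nm DBSCAN radius (nm).
#' @param min_points DBSCAN minimum neighborhood size.
#' @param min_cluster_size minimum localizations per surviving cluster.
#' @return integer label vector (0 = noise).
#' @export
detect_synaptic_clusters <- function(table, eps_nm = 48, min_points = 10,
                                     min_cluster_size = 75) {
  if (nrow(table) == 0) stopf("empty localization table")
  labels <- dbscan_labels(table$x_nm, table$y_nm, eps_nm, min_points)
  sizes <- tabulate(labels)
  small <- which(sizes < min_cluster_size)
  labels[labels %in% small] <- 0L
  relabel_consecutive(labels)
}

relabel_consecutive <- function(labels) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(labels)
  match(labels, ids, nomatch = 0L)
}

#' Reject nonspecific scaffold clusters by frame statistics
#'
#' Nonspecific imager binding produces clusters localized over a short time
#' window, so their mean frame deviates from mid-acquisition and their frame
#' standard deviation is small. A cluster is removed when its mean frame
#' falls outside mu +/- 2 sd of a Gaussian fit over all clusters' mean
#' frames, or when its frame standard deviation is below/above the stated
#' bounds (defaults assume a 30,000-frame acquisition; a uniformly visible
#' cluster has frame SD ~ n_frames/sqrt(12) ~ 8,660).
#'
#' @param table the scaffold [loc_table()].
#' @param labels cluster labels from [detect_synaptic_clusters()].
#' @param frame_sd_bounds keep clusters with frame SD inside these bounds.
#' @param mean_k_sd the +/- multiplier of the Gaussian-fit criterion.
#' @return list with `labels` (survivors, renumbered), `stats` (per input
#'   cluster: mean frame, frame SD, removal verdict and reason).
#' @export
remove_nonspecific_clusters <- function(table, labels,
                                        frame_sd_bounds = c(2500, 11000),
                                        mean_k_sd = 2) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids))
    return(list(labels = labels, stats = data.frame()))
  mean_f <- vapply(ids, function(i) mean(table$frame[labels == i]), numeric(1))
  sd_f <- vapply(ids, function(i) sd(table$frame[labels == i]), numeric(1))
  sd_f[is.na(sd_f)] <- 0
  bad_sd <- sd_f < frame_sd_bounds[1] | sd_f > frame_sd_bounds[2]
  bad_mean <- rep(FALSE, length(ids))
  if (length(ids) >= 3) {
    fit <- fit_gaussian_1d(mean_f)
    bad_mean <- abs(mean_f - fit$mu) > mean_k_sd * fit$sd
  } else {
    warnf("fewer than 3 clusters: mean-frame criterion skipped")
  }
  removed <- bad_sd | bad_mean
  out <- labels
  out[labels %in% ids[removed]] <- 0L
  stats <- data.frame(cluster = ids, mean_frame = mean_f, frame_sd = sd_f,
                      removed = removed,
                      reason = ifelse(bad_sd, "frame_sd",
                                      ifelse(bad_mean, "mean_frame", "")))
  list(labels = relabel_consecutive(out), stats = stats)
}

#' Pair scaffold clusters and apply the en-face selection criteria
#'
#' Builds alpha-shape boundaries for a presynaptic-mask (Bassoon-role)
#' cluster and its postsynaptic (PSD-95-role) partner, smooths the mask
#' boundary with a 3-vertex moving average, and accepts the synapse as
#' en-face when the smoothed boundary's roundness (major/minor axis ratio of
#' its second-moment ellipse) is at most `shape_max` and the area overlap of
#' the two shapes is at least `overlap_min`. The overlap denominator is the
#' smaller of the two shape areas by default (`"bassoon"` uses the mask
#' shape's area instead).
#'
#' @param bassoon_points,psd_points Nx2 matrices (nm) of the two scaffold
#'   clusters' localizations.
#' @param alpha_radius_nm alpha radius for the synapse-scale shapes.
#' @param overlap_min minimum area-overlap fraction.
#' @param shape_max maximum roundness metric.
#' @param overlap_denominator `"smaller"` or `"bassoon"`.
#' @param raster_cell_nm grid cell for the overlap-area rasterization.
#' @return a `synapse_roi`: list with `bassoon_shape`, `psd_shape`,
#'   `smoothed_ring`, `shape_metric`, `overlap_fraction`, `accepted`,
#'   `reason`.
#' @export
select_enface <- function(bassoon_points, psd_points, alpha_radius_nm = 150,
                          overlap_min = 0.70, shape_max = 2,
                          overlap_denominator = c("smaller", "bassoon"),
                          raster_cell_nm = 2) {
  overlap_denominator <- match.arg(overlap_denominator)
  roi <- structure(list(bassoon_shape = NULL, psd_shape = NULL,
                        smoothed_ring = NULL, shape_metric = NA_real_,
                        overlap_fraction = NA_real_, accepted = FALSE,
                        reason = ""), class = "synapse_roi")
  shapes <- tryCatch(list(b = alpha_shape(bassoon_points, alpha_radius_nm),
                          p = alpha_shape(psd_points, alpha_radius_nm)),
                     error = function(e) e)
  if (inherits(shapes, "error")) {
    roi$reason <- paste("degenerate polygon:", conditionMessage(shapes))
    return(roi)
  }
  roi$bassoon_shape <- shapes$b
  roi$psd_shape <- shapes$p
  roi$smoothed_ring <- smooth_ring(shapes$b$rings[[shapes$b$main]], 3)
  roi$shape_metric <- polygon_axis_ratio(roi$smoothed_ring)
  roi$overlap_fraction <- shape_overlap(shapes$b, shapes$p, raster_cell_nm,
                                        overlap_denominator)
  if (!is.finite(roi$shape_metric) || roi$shape_metric > shape_max) {
    roi$reason <- sprintf("shape metric %.2f > %g", roi$shape_metric,
                          shape_max)
  } else if (!is.finite(roi$overlap_fraction) ||
             roi$overlap_fraction < overlap_min) {
    roi$reason <- sprintf("overlap %.2f < %g", roi$overlap_fraction,
                          overlap_min)
  } else {
    roi$accepted <- TRUE
  }
  roi
}

# Area overlap of two shapes on a common raster grid.
shape_overlap <- function(shape_a, shape_b, cell_nm = 2,
                          denominator = "smaller") {
  va <- do.call(rbind, as_rings(shape_a))
  vb <- do.call(rbind, as_rings(shape_b))
  allv <- rbind(va, vb)
  ox <- floor(min(allv[, 1]) / cell_nm) * cell_nm - cell_nm
  oy <- floor(min(allv[, 2]) / cell_nm) * cell_nm - cell_nm
  nx <- ceiling((max(allv[, 1]) - ox) / cell_nm) + 1
  ny <- ceiling((max(allv[, 2]) - oy) / cell_nm) + 1
  cxs <- ox + (seq_len(nx) - 0.5) * cell_nm
  cys <- oy + (seq_len(ny) - 0.5) * cell_nm
  g <- expand.grid(x = cxs, y = cys)
  in_a <- point_in_shape(g$x, g$y, shape_a)
  in_b <- point_in_shape(g$x, g$y, shape_b)
  inter <- sum(in_a & in_b)
  den <- switch(denominator,
                smaller = min(sum(in_a), sum(in_b)),
                bassoon = sum(in_a))
  if (den == 0) return(NA_real_)
  inter / den
}

#' Restrict analysis targets to the active-zone boundary
#'
#' Point-in-polygon restriction (boundary-inclusive) of each analysis
#' target's localizations to the presynaptic-mask alpha shape. The synapse
#' is rejected when any required target retains fewer than `min_locs`
#' localizations inside the boundary.
#'
#' @param roi an accepted `synapse_roi` from [select_enface()].
#' @param analysis_tables named list of [loc_table()] objects to restrict
#'   (typically the two analysis targets and the postsynaptic target).
#' @param min_locs minimum in-boundary localizations per required target.
#' @return the `synapse_roi` with `restricted` (named list of restricted
#'   tables), `counts`, and updated `accepted`/`reason`.
#' @export
restrict_to_active_zone <- function(roi, analysis_tables, min_locs = 25) {
  stopifnot(inherits(roi, "synapse_roi"))
  if (!roi$accepted) return(roi)
  shape <- roi$bassoon_shape
  roi$restricted <- lapply(analysis_tables, function(tab) {
    keep <- point_in_shape(tab$x_nm, tab$y_nm, shape)
    reloc(tab[keep, , drop = FALSE], tab)
  })
  roi$counts <- vapply(roi$restricted, nrow, integer(1))
  if (any(roi$counts < min_locs)) {
    roi$accepted <- FALSE
    low <- names(roi$counts)[roi$counts < min_locs][1]
    roi$reason <- sprintf("target %s has %d < %d localizations in the boundary",
                          low, roi$counts[[low]], min_locs)
  }
  roi
}
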
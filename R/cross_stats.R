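# Randomization engine, randomization-normalized cross-enrichment with
# per-bin outlier smoothing, enrichment classification, and the nanocluster
# separation index.

#' Uniform random point sets inside a polygonal ROI
#'
#' Rejection sampling from the ROI's bounding box; each set holds exactly
#' `n_points` independent uniform points inside the ROI. Deterministic for a
#' given seed.
#'
#' @param n_points points per set.
#' @param roi an `alpha_shape`, ring matrix, or list of rings.
#' @param n_rand number of sets.
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @return list of `n_rand` Nx2 matrices.
#' @export
randomize_in_roi <- function(n_points, roi, n_rand = 100, seed = NULL) {
  if (n_points < 1) stopf("n_points must be >= 1")
  rings <- as_rings(roi)
  allv <- do.call(rbind, rings)
  xr <- range(allv[, 1]); yr <- range(allv[, 2])
  if (diff(xr) <= 0 || diff(yr) <= 0) stopf("degenerate ROI polygon")
  draw_set <- function() {
    got <- matrix(numeric(0), 0, 2)
    guard <- 0
    while (nrow(got) < n_points) {
      m <- max(2 * (n_points - nrow(got)), 64)
      cand <- cbind(runif(m, xr[1], xr[2]), runif(m, yr[1], yr[2]))
      ok <- point_in_shape(cand[, 1], cand[, 2], rings)
      got <- rbind(got, cand[ok, , drop = FALSE])
      guard <- guard + 1
      if (guard > 1000) stopf("ROI rejection sampling failed to converge")
    }
    got[seq_len(n_points), , drop = FALSE]
  }
  with_seed(seed, replicate(n_rand, draw_set(), simplify = FALSE))
}

# Per-bin density (count / in-ROI annulus area) of `points` around
# `centers`, averaged over centers. Bins whose in-ROI annulus area is
# (near) zero for a center are treated as missing for that center.
radial_density <- function(centers, points, areas, bin_edges_nm) {
  counts <- pair_hist_cross(centers[, 1], centers[, 2],
                            points[, 1], points[, 2], bin_edges_nm)
  dens <- counts / areas
  dens[!is.finite(dens)] <- NA_real_
  colMeans(dens, na.rm = TRUE)
}

#' Randomization-normalized cross-enrichment profile
#'
#' Density of protein B per radial bin around reference points of protein A
#' (nanocluster centers), each bin's annulus clipped to the ROI, averaged
#' over the reference points, and divided by the same quantity averaged
#' over randomized placements of B inside the ROI. An enrichment of 1 means
#' B is distributed as under spatial randomness; the randomized-placement
#' normalization removes B's overall intensity.
#'
#' @param centers_a Nx2 matrix of reference points (nm).
#' @param points_b Mx2 matrix of the opposite protein's localizations.
#' @param roi the active-zone shape (`alpha_shape`, ring, or list of rings).
#' @param bin_edges_nm radial bin edges.
#' @param rand_norm list of randomized B point sets used for normalization
#'   (typically 100 from [randomize_in_roi()]).
#' @param rand_class optional second ensemble (typically 50 independent
#'   sets); their enrichment curves, normalized by the same denominator,
#'   are stored for [classify_enrichment()].
#' @param raster_cell_nm grid cell for annulus-area clipping.
#' @param area_cache optional precomputed ROI raster (from a prior profile
#'   with the same ROI).
#' @return an `enrichment_profile`: list with `bin_edges_nm`, `r_mid_nm`,
#'   `enrichment`, `rand_curves` (one row per classification set),
#'   `n_centers`, `n_points_b`, `n_randomizations`, `area_cache`.
#' @export
cross_enrichment <- function(centers_a, points_b, roi, bin_edges_nm = seq(0, 200, 10),
                             rand_norm, rand_class = NULL,
                             raster_cell_nm = 2, area_cache = NULL) {
  centers_a <- matrix(as.numeric(centers_a), ncol = 2)
  points_b <- as.matrix(points_b)
  if (nrow(centers_a) < 1) stopf("need at least one reference center")
  if (nrow(points_b) < 1) stopf("need at least one point of the opposite protein")
  if (is.null(area_cache)) area_cache <- rasterize_shape(roi, raster_cell_nm)
  areas <- annulus_area_impl(area_cache$mask, area_cache$cell_nm,
                             area_cache$origin_nm[1], area_cache$origin_nm[2],
                             centers_a[, 1], centers_a[, 2], bin_edges_nm)
  min_area <- area_cache$cell_nm^2
  areas[areas < min_area] <- NA_real_
  d_obs <- radial_density(centers_a, points_b, areas, bin_edges_nm)
  d_rand <- vapply(rand_norm, function(ps)
    radial_density(centers_a, ps, areas, bin_edges_nm),
    numeric(length(bin_edges_nm) - 1))
  d_norm <- rowMeans(d_rand, na.rm = TRUE)
  enr <- ifelse(d_norm > 0, d_obs / d_norm, NA_real_)
  rand_curves <- NULL
  if (!is.null(rand_class)) {
    d_cls <- vapply(rand_class, function(ps)
      radial_density(centers_a, ps, areas, bin_edges_nm),
      numeric(length(bin_edges_nm) - 1))
    d_cls <- matrix(d_cls, nrow = length(bin_edges_nm) - 1) / d_norm
    d_cls[!is.finite(d_cls)] <- NA_real_
    rand_curves <- t(d_cls)
  }
  structure(list(bin_edges_nm = bin_edges_nm,
                 r_mid_nm = (head(bin_edges_nm, -1) + tail(bin_edges_nm, -1)) / 2,
                 enrichment = enr, rand_curves = rand_curves,
                 n_centers = nrow(centers_a), n_points_b = nrow(points_b),
                 n_randomizations = length(rand_norm),
                 area_cache = area_cache),
            class = "enrichment_profile")
}

#' Classify a nanocluster's cross-enrichment against its randomizations
#'
#' The statistic is the unweighted mean enrichment over bins whose outer
#' edge lies within `r_max_nm` of the reference center. The same statistic
#' is computed for each randomized placement of the opposite protein
#' (`rand_curves` of the profile); the nanocluster is `enriched` when the
#' real statistic exceeds the randomized mean plus `k_sd` standard
#' deviations, `de_enriched` below the mean minus `k_sd` SD, and
#' `indistinguishable` otherwise (strict inequalities).
#'
#' @param profile an `enrichment_profile` with `rand_curves`.
#' @param r_max_nm outer distance of the classification window.
#' @param k_sd the SD multiplier (1.96 for two-sided 5 percent).
#' @return list with `class` (`enriched`, `indistinguishable`,
#'   `de_enriched`, or `unclassifiable`), `statistic`, `rand_mean`,
#'   `rand_sd`, `n_rand`.
#' @export
classify_enrichment <- function(profile, r_max_nm = 60, k_sd = 1.96) {
  stopifnot(inherits(profile, "enrichment_profile"))
  sel <- which(tail(profile$bin_edges_nm, -1) <= r_max_nm)
  sel <- sel[is.finite(profile$enrichment[sel])]
  if (!length(sel) || is.null(profile$rand_curves))
    return(list(class = "unclassifiable", statistic = NA_real_,
                rand_mean = NA_real_, rand_sd = NA_real_, n_rand = 0L))
  statistic <- mean(profile$enrichment[sel])
  rand_stats <- rowMeans(profile$rand_curves[, sel, drop = FALSE], na.rm = TRUE)
  rand_stats <- rand_stats[is.finite(rand_stats)]
  if (length(rand_stats) < 2)
    return(list(class = "unclassifiable", statistic = statistic,
                rand_mean = NA_real_, rand_sd = NA_real_, n_rand = 0L))
  mu <- mean(rand_stats)
  s <- sd(rand_stats)
  cls <- if (statistic > mu + k_sd * s) "enriched"
         else if (statistic < mu - k_sd * s) "de_enriched"
         else "indistinguishable"
  list(class = cls, statistic = statistic, rand_mean = mu, rand_sd = s,
       n_rand = length(rand_stats))
}

#' Smooth enrichment curves across a population by per-bin outlier capping
#'
#' At each distance bin, high outliers across the population of curves
#' (ROUT, high side, Q = 0.1 percent by default) are replaced by the highest
#' non-outlier value in that bin.
#'
#' @param curves matrix, one row per synapse/nanocluster, one column per bin.
#' @param Q ROUT false-discovery rate.
#' @return the smoothed matrix.
#' @export
smooth_enrichment_population <- function(curves, Q = 0.001) {
  for (j in seq_len(ncol(curves))) {
    v <- curves[, j]
    ok <- is.finite(v)
    if (sum(ok) < 3) next
    res <- rout_outliers(v[ok], Q = Q, side = "high")
    if (any(res$mask)) {
      cap <- max(v[ok][!res$mask])
      vv <- v[ok]
      vv[res$mask] <- cap
      curves[ok, j] <- vv
    }
  }
  curves
}

#' Separation index between a nanocluster and the nearest opposite one
#'
#' `SI = d / (r1 + r2)`: `d` is the Euclidean distance between the source
#' nanocluster's centroid and the centroid of the nearest nanocluster of
#' the other protein; `r1` and `r2` are the distances from each centroid to
#' its own alpha-shape border along the line connecting the centroids.
#' `SI < 1` means the borders overlap along that line; `SI > 1` means the
#' nanoclusters are separated.
#'
#' @param source a `nanocluster`.
#' @param opposite non-empty list of `nanocluster` objects of the other
#'   protein.
#' @return a `separation_result`: list with `opposite_index`, `d_nm`,
#'   `r1_nm`, `r2_nm`, `si`, `overlap`, `degenerate`.
#' @export
separation_index <- function(source, opposite) {
  if (!length(opposite)) stopf("no opposite nanoclusters")
  cc <- source$centroid_nm
  dists <- vapply(opposite, function(nc)
    sqrt(sum((nc$centroid_nm - cc)^2)), numeric(1))
  j <- which(dists == min(dists))[1]   # tie -> lower index
  other <- opposite[[j]]
  d <- dists[j]
  if (d == 0) {
    return(structure(list(opposite_index = j, d_nm = 0,
                          r1_nm = source$effective_radius_nm,
                          r2_nm = other$effective_radius_nm,
                          si = 0, overlap = TRUE, degenerate = TRUE),
                     class = "separation_result"))
  }
  u <- (other$centroid_nm - cc) / d
  r1 <- ray_boundary_distance(source$shape, cc, u)
  r2 <- ray_boundary_distance(other$shape, other$centroid_nm, -u)
  si <- d / (r1 + r2)
  structure(list(opposite_index = j, d_nm = d, r1_nm = r1, r2_nm = r2,
                 si = si, overlap = si < 1, degenerate = FALSE),
            class = "separation_result")
}
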
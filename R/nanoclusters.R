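# Nanocluster detection, geometry and filtering inside the active zone, and
# the within-synapse pair autocorrelation of a single target.

#' Detect nanoclusters of one target inside the active zone
#'
#' DBSCAN on the restricted localizations. The radius and minimum-point
#' parameters are mandatory (they are recorded with every result set;
#' defaults of 25 nm / 5 points are consistent with the 5-localization
#' nanocluster size filter).
#'
#' @param points Nx2 matrix (nm).
#' @param eps_nm DBSCAN radius.
#' @param min_points DBSCAN minimum neighborhood size.
#' @param alpha_radius_nm alpha radius for nanocluster geometry.
#' @return list of `nanocluster` objects (pre-filter); clusters with
#'   degenerate geometry are dropped with a message.
#' @export
detect_nanoclusters <- function(points, eps_nm = 25, min_points = 5,
                                alpha_radius_nm = 150) {
  points <- as.matrix(points)
  if (nrow(points) < min_points) return(list())
  labels <- dbscan_labels(points[, 1], points[, 2], eps_nm, min_points)
  ids <- sort(unique(labels[labels > 0]))
  out <- list()
  for (i in ids) {
    idx <- which(labels == i)
    nc <- nanocluster_geometry(points[idx, , drop = FALSE], alpha_radius_nm,
                               indices = idx)
    if (!is.null(nc)) out[[length(out) + 1]] <- nc
  }
  out
}

#' Geometry of one nanocluster
#'
#' Centroid (unweighted mean of member positions), alpha-shape boundary and
#' area, and the effective radius `sqrt(area / pi)`.
#'
#' @param points member localizations, Nx2 (nm), at least 3 non-collinear.
#' @param alpha_radius_nm alpha radius (150 nm corresponds to 0.9375 camera
#'   pixels at a 160-nm pixel).
#' @param indices optional member indices carried through for bookkeeping.
#' @return a `nanocluster`: list with `indices`, `points`, `n_locs`,
#'   `centroid_nm`, `shape`, `area_nm2`, `effective_radius_nm`; or `NULL`
#'   with a message when the geometry is degenerate.
#' @export
nanocluster_geometry <- function(points, alpha_radius_nm = 150,
                                 indices = NULL) {
  points <- as.matrix(points)
  shape <- tryCatch(alpha_shape(points, alpha_radius_nm),
                    error = function(e) e)
  if (inherits(shape, "error")) {
    message("nanocluster dropped: ", conditionMessage(shape))
    return(NULL)
  }
  structure(list(indices = indices, points = points, n_locs = nrow(points),
                 centroid_nm = colMeans(points), shape = shape,
                 area_nm2 = shape$area_nm2,
                 effective_radius_nm = sqrt(shape$area_nm2 / pi)),
            class = "nanocluster")
}

#' Filter nanoclusters by size and by robust area outliers
#'
#' Removes nanoclusters with fewer than `min_locs` localizations, and those
#' whose area exceeds the largest area not flagged as a high outlier by the
#' univariate ROUT procedure (Q = 0.1 percent by default) applied to the area
#' distribution across the supplied set (typically the whole dataset).
#'
#' @param clusters list of `nanocluster` objects.
#' @param min_locs minimum member count.
#' @param Q ROUT false-discovery rate.
#' @return the surviving list.
#' @export
filter_nanoclusters <- function(clusters, min_locs = 5, Q = 0.001) {
  keep <- vapply(clusters, function(nc) nc$n_locs >= min_locs, logical(1))
  clusters <- clusters[keep]
  if (length(clusters) < 3) {
    if (length(clusters)) warnf("fewer than 3 nanoclusters: area outlier filter skipped")
    return(clusters)
  }
  areas <- vapply(clusters, function(nc) nc$area_nm2, numeric(1))
  res <- rout_outliers(areas, Q = Q, side = "high")
  if (any(res$mask)) {
    max_ok <- max(areas[!res$mask])
    clusters <- clusters[areas <= max_ok]
  }
  clusters
}

# Isotropized set covariance of a rasterized ROI, integrated over radial
# annuli: returns per-bin integral of the set covariance (units nm^4),
# computed by FFT autocorrelation of the binary mask on its grid.
set_covariance_annuli <- function(raster, bin_edges_nm) {
  m <- raster$mask
  cell <- raster$cell_nm
  nx <- nrow(m); ny <- ncol(m)
  px <- 2 * nx; py <- 2 * ny
  P <- matrix(0, px, py)
  P[1:nx, 1:ny] <- as.numeric(m)
  F <- fft(P)
  C <- Re(fft(F * Conj(F), inverse = TRUE)) / (px * py)  # overlap cell counts
  # shift (dx, dy) lives at wrapped index; enumerate dx in -(nx-1)..(nx-1)
  dxs <- c(0:(nx - 1), -(nx - 1):-1)
  dys <- c(0:(ny - 1), -(ny - 1):-1)
  ix <- c(1:nx, (px - nx + 2):px)
  iy <- c(1:ny, (py - ny + 2):py)
  sub <- C[ix, iy]
  dmat <- sqrt(outer((dxs * cell)^2, (dys * cell)^2, "+"))
  nb <- length(bin_edges_nm) - 1
  out <- numeric(nb)
  bin_idx <- findInterval(dmat, bin_edges_nm, rightmost.closed = FALSE)
  valid <- bin_idx >= 1 & bin_idx <= nb & dmat >= bin_edges_nm[1] &
    dmat < bin_edges_nm[nb + 1]
  sums <- tapply(sub[valid], bin_idx[valid], sum)
  counts <- tapply(rep(1, sum(valid)), bin_idx[valid], sum)
  # mean covariance over the lattice samples in the annulus, times the exact
  # annulus area: avoids the lattice-measure bias that is worst in the
  # smallest annuli (where the (0,0) sample dominates)
  idx <- as.integer(names(sums))
  annulus_area <- pi * diff(bin_edges_nm^2)
  out[idx] <- (sums / counts) * annulus_area[idx]
  out * cell^2   # covariance cell counts -> nm^2
}

#' Pair autocorrelation of a 2D point pattern inside a polygonal ROI
#'
#' Edge-corrected pair-correlation function g(r): observed pair counts per
#' radial annulus divided by their expectation under a spatially homogeneous
#' (binomial) pattern of the same intensity inside the ROI. The expectation
#' uses the ROI's isotropized set covariance estimated on a raster grid, so
#' the CSR calibration g = 1 holds for irregular boundaries. g = 1 means
#' spatial homogeneity; values above 1 at short distances indicate
#' clustering.
#'
#' @param points Nx2 matrix (nm); only points inside the ROI are used, and
#'   at least `min_points` are required.
#' @param roi an `alpha_shape`, ring matrix, or list of rings.
#' @param bin_edges_nm radial bin edges (default 0-200 nm in 10-nm steps).
#' @param raster_cell_nm grid cell for the set-covariance estimate.
#' @param min_points minimum in-ROI points.
#' @param cov_cache optional precomputed list from a previous call with the
#'   same ROI and bins (fields `raster`, `annuli`), to avoid recomputation.
#' @return an `autocorrelation_curve`: list with `bin_edges_nm`, `r_mid_nm`,
#'   `g`, `n_points`, and the reusable `cov_cache`.
#' @export
autocorrelation <- function(points, roi, bin_edges_nm = seq(0, 200, 10),
                            raster_cell_nm = 2, min_points = 25,
                            cov_cache = NULL) {
  points <- as.matrix(points)
  inside <- point_in_shape(points[, 1], points[, 2], roi)
  pts <- points[inside, , drop = FALSE]
  n <- nrow(pts)
  if (n < min_points)
    stopf("insufficient data: %d points inside the ROI (need >= %d)", n,
          min_points)
  if (is.null(cov_cache)) {
    raster <- rasterize_shape(roi, raster_cell_nm)
    annuli <- set_covariance_annuli(raster, bin_edges_nm)
    cov_cache <- list(raster = raster, annuli = annuli)
  }
  area <- sum(cov_cache$raster$mask) * cov_cache$raster$cell_nm^2
  obs <- pair_hist_auto(pts[, 1], pts[, 2], bin_edges_nm)
  expected <- n * (n - 1) / 2 * cov_cache$annuli / area^2
  g <- ifelse(expected > 0, obs / expected, NA_real_)
  structure(list(bin_edges_nm = bin_edges_nm,
                 r_mid_nm = (head(bin_edges_nm, -1) + tail(bin_edges_nm, -1)) / 2,
                 g = g, n_points = n, cov_cache = cov_cache),
            class = "autocorrelation_curve")
}
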
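# STED side-view quantification: perpendicular line profiles across the
# postsynaptic marker, rolling average, peak alignment/averaging, and
# per-culture peak normalization.

# Bilinear interpolation of image[ix, iy] at continuous nm coordinates;
# pixel (i, j) covers [ (i-1)*px, i*px ) x [ (j-1)*px, j*px ) with its
# sample value at the pixel center.
bilinear_sample <- function(image, x_nm, y_nm, pixel_nm) {
  gx <- x_nm / pixel_nm - 0.5
  gy <- y_nm / pixel_nm - 0.5
  nx <- nrow(image); ny <- ncol(image)
  x0 <- floor(gx); y0 <- floor(gy)
  fx <- gx - x0; fy <- gy - y0
  cl <- function(i, n) pmin(pmax(i, 0), n - 1) + 1
  v00 <- image[cbind(cl(x0, nx), cl(y0, ny))]
  v10 <- image[cbind(cl(x0 + 1, nx), cl(y0, ny))]
  v01 <- image[cbind(cl(x0, nx), cl(y0 + 1, ny))]
  v11 <- image[cbind(cl(x0 + 1, nx), cl(y0 + 1, ny))]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

#' Extract a multi-channel side-view line profile from 2D images
#'
#' A `length_nm`-long, `width_nm`-wide profile window centered on `center_nm`
#' and oriented along `direction` (the axis perpendicular to the
#' postsynaptic marker bar). At each along-axis sample the intensity is the
#' mean over across-axis samples spanning the width, with bilinear
#' interpolation; sampling step equals the image pixel size.
#'
#' @param channels named list of image matrices (`image[ix, iy]`, common
#'   geometry).
#' @param center_nm length-2 center of the profile (nm).
#' @param direction length-2 direction vector of the profile axis
#'   (normalized internally).
#' @param length_nm profile length (750 nm default).
#' @param width_nm integration width (250 nm default).
#' @param pixel_nm image pixel size (22.7 nm default).
#' @return a `side_view_profile`: list with `positions_nm` (along-axis
#'   offsets, centered), `intensity` (samples x channels matrix),
#'   `pixel_nm`, `alignment_offset_nm` (0 until aligned).
#' @export
extract_profile <- function(channels, center_nm, direction,
                            length_nm = 750, width_nm = 250,
                            pixel_nm = 22.7) {
  stopifnot(is.list(channels), length(channels) >= 1)
  u <- direction / sqrt(sum(direction^2))
  v <- c(-u[2], u[1])
  n_along <- floor(length_nm / pixel_nm)
  n_across <- max(1, floor(width_nm / pixel_nm))
  s_along <- (seq_len(n_along) - (n_along + 1) / 2) * pixel_nm
  s_across <- (seq_len(n_across) - (n_across + 1) / 2) * pixel_nm
  img <- channels[[1]]
  ext <- c(nrow(img), ncol(img)) * pixel_nm
  corners_along <- range(s_along)
  corners_across <- range(s_across)
  for (sa in corners_along) for (sc in corners_across) {
    p <- center_nm + sa * u + sc * v
    if (p[1] < 0 || p[2] < 0 || p[1] > ext[1] || p[2] > ext[2])
      stopf("profile window exits the image bounds")
  }
  intensity <- sapply(channels, function(im) {
    vapply(s_along, function(sa) {
      px <- center_nm[1] + sa * u[1] + s_across * v[1]
      py <- center_nm[2] + sa * u[2] + s_across * v[2]
      mean(bilinear_sample(im, px, py, pixel_nm))
    }, numeric(1))
  })
  intensity <- matrix(intensity, nrow = n_along,
                      dimnames = list(NULL, names(channels)))
  structure(list(positions_nm = s_along, intensity = intensity,
                 pixel_nm = pixel_nm, alignment_offset_nm = 0),
            class = "side_view_profile")
}

#' Rolling average of a line profile
#'
#' Centered moving average over `window_px` samples per channel; windows
#' shrink at the profile edges.
#'
#' @param profile a `side_view_profile`.
#' @param window_px window size in samples (5 by default).
#' @return the smoothed profile.
#' @export
smooth_profile <- function(profile, window_px = 5) {
  n <- nrow(profile$intensity)
  if (n < window_px) stopf("profile shorter than the smoothing window")
  half <- (window_px - 1) %/% 2
  sm <- apply(profile$intensity, 2, function(v) {
    vapply(seq_len(n), function(i) {
      mean(v[max(1, i - half):min(n, i + half)])
    }, numeric(1))
  })
  profile$intensity <- matrix(sm, nrow = n,
                              dimnames = dimnames(profile$intensity))
  profile
}

#' Align profiles to the postsynaptic-marker peak and average
#'
#' Each profile is shifted so the maximum of its reference channel sits at
#' offset 0 (a non-unique maximum is broken toward the profile center);
#' channel-wise mean and SEM are computed across profiles on the common
#' offset grid (positions covered by every profile).
#'
#' @param profiles list of `side_view_profile` objects with identical
#'   sampling.
#' @param reference_channel name of the postsynaptic marker channel.
#' @return list with `positions_nm`, `mean` (matrix), `sem` (matrix), `n`.
#' @export
align_and_average <- function(profiles, reference_channel) {
  stopifnot(length(profiles) >= 1)
  step <- profiles[[1]]$pixel_nm
  n <- nrow(profiles[[1]]$intensity)
  shifts <- vapply(profiles, function(p) {
    ref <- p$intensity[, reference_channel]
    peaks <- which(ref == max(ref))
    mid <- (n + 1) / 2
    peaks[which.min(abs(peaks - mid))]
  }, numeric(1))
  # common grid: indices offset so each profile's peak is at 0
  rel_lo <- max(1 - shifts)
  rel_hi <- min(n - shifts)
  rel <- seq(rel_lo, rel_hi)
  acc <- lapply(colnames(profiles[[1]]$intensity), function(ch) {
    vapply(seq_along(profiles), function(k)
      profiles[[k]]$intensity[rel + shifts[k], ch], numeric(length(rel)))
  })
  names(acc) <- colnames(profiles[[1]]$intensity)
  mean_mat <- vapply(acc, function(m) rowMeans(matrix(m, length(rel))),
                     numeric(length(rel)))
  sem_mat <- vapply(acc, function(m) {
    m <- matrix(m, length(rel))
    if (ncol(m) < 2) rep(NA_real_, nrow(m))
    else apply(m, 1, sd) / sqrt(ncol(m))
  }, numeric(length(rel)))
  list(positions_nm = rel * step, mean = mean_mat, sem = sem_mat,
       n = length(profiles))
}

#' Peak intensities with per-culture normalization to the control condition
#'
#' The peak of each (smoothed) profile is the maximum of its channel of
#' interest. Within each culture, peaks are divided by the mean peak of the
#' control condition in that culture and expressed in percent, so the
#' control group's mean is 100 percent by construction.
#'
#' @param profiles list of `side_view_profile` objects (smooth first).
#' @param channel channel of interest.
#' @param culture factor/vector: culture of each profile.
#' @param is_control logical vector: control-condition membership.
#' @return data.frame with `culture`, `is_control`, `peak`,
#'   `normalized_pct`.
#' @export
peak_and_normalize <- function(profiles, channel, culture, is_control) {
  stopifnot(length(profiles) == length(culture),
            length(profiles) == length(is_control))
  peak <- vapply(profiles, function(p) max(p$intensity[, channel]),
                 numeric(1))
  out <- data.frame(culture = culture, is_control = is_control, peak = peak,
                    normalized_pct = NA_real_)
  for (cu in unique(culture)) {
    sel <- culture == cu
    ctrl <- sel & is_control
    if (!any(ctrl)) stopf("culture %s has no control profiles", cu)
    ref <- mean(peak[ctrl])
    if (ref == 0) stopf("zero control mean peak in culture %s", cu)
    out$normalized_pct[sel] <- 100 * peak[sel] / ref
  }
  out
}
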
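# Preprocessing: localization quality filters, temporal linking of blinking
# events, redundant cross-correlation drift correction, polynomial chromatic
# registration and residual inter-target offset correction.

#' Quality-filter a localization table
#'
#' Removes localizations with a PSF-fit standard deviation below/above the
#' stated bounds (strict inequalities), a localization error above
#' `precision_max_nm`, or a photon count above the upper edge of the modal
#' bin of the photon histogram (fixed-width bins starting at zero; ties go
#' to the lower bin). Rows with `NA` in a quality column are not removed by
#' that criterion. Surviving rows are unchanged.
#'
#' @param table a [loc_table()].
#' @param sigma_bounds_px keep `sigma_px` within these bounds (inclusive).
#' @param precision_max_nm keep `precision_nm <= this`.
#' @param photon_bin_width histogram bin width for the photon-mode rule.
#' @param photon_mode_edge which edge of the modal bin is the threshold:
#'   `"upper"` (default), `"center"`, or `"lower"`.
#' @return list with `table` (filtered) and `report` (a QC report:
#'   `rows_in`, per-cause removal counts with precedence sigma -> precision
#'   -> photons, `rows_out`, thresholds used).
#' @export
filter_quality <- function(table, sigma_bounds_px = c(0.3, 1.6),
                           precision_max_nm = 20, photon_bin_width = 50,
                           photon_mode_edge = c("upper", "center", "lower")) {
  photon_mode_edge <- match.arg(photon_mode_edge)
  n <- nrow(table)
  bad_sigma <- !is.na(table$sigma_px) &
    (table$sigma_px < sigma_bounds_px[1] | table$sigma_px > sigma_bounds_px[2])
  bad_prec <- !is.na(table$precision_nm) & table$precision_nm > precision_max_nm
  ph <- table$photons
  photon_threshold <- Inf
  if (any(!is.na(ph))) {
    bin <- floor(ph[!is.na(ph)] / photon_bin_width)
    tab <- table(bin)
    modal <- as.numeric(names(tab)[which.max(tab)])  # ties -> lower bin
    photon_threshold <- switch(photon_mode_edge,
      upper = (modal + 1) * photon_bin_width,
      center = (modal + 0.5) * photon_bin_width,
      lower = modal * photon_bin_width)
  }
  bad_photons <- !is.na(ph) & ph > photon_threshold
  removed_sigma <- sum(bad_sigma)
  removed_prec <- sum(bad_prec & !bad_sigma)
  removed_photons <- sum(bad_photons & !bad_sigma & !bad_prec)
  keep <- !(bad_sigma | bad_prec | bad_photons)
  out <- reloc(table[keep, , drop = FALSE], table)
  if (nrow(out) == 0) warnf("quality filter removed every localization")
  report <- list(rows_in = n,
                 rows_removed_sigma = removed_sigma,
                 rows_removed_precision = removed_prec,
                 rows_removed_photons = removed_photons,
                 rows_out = nrow(out),
                 thresholds = list(sigma_bounds_px = sigma_bounds_px,
                                   precision_max_nm = precision_max_nm,
                                   photon_threshold = photon_threshold,
                                   photon_bin_width = photon_bin_width))
  list(table = out, report = report)
}

#' Temporally link localizations of persistent binding events
#'
#' Localizations of one target that reappear within `radius_px` (converted
#' to nm with the table's pixel size) across consecutive frames, allowing up
#' to `max_dark_frames` dark frames between appearances, merge into one
#' event. Greedy in frame order with nearest-candidate matching inside the
#' radius; ties broken by lower event index. The merged event has the
#' photon-weighted mean position, summed photons, photon-weighted mean
#' sigma, the minimum member precision (conservative), and the first frame.
#'
#' @param table a [loc_table()].
#' @param radius_px linking radius in camera pixels.
#' @param max_dark_frames maximum dark frames allowed inside one event.
#' @return a linked [loc_table()] (never more rows than the input; total
#'   photons conserved).
#' @export
link_localizations <- function(table, radius_px = 0.3, max_dark_frames = 5) {
  n <- nrow(table)
  if (n == 0) return(table)
  radius_nm <- radius_px * attr(table, "pixel_size_nm")
  ord <- order(table$frame, seq_len(n))
  x <- table$x_nm[ord]; y <- table$y_nm[ord]
  fr <- table$frame[ord]
  ph <- table$photons[ord]
  w <- if (any(is.na(ph))) rep(1, n) else ph   # weights need complete photons
  sg <- table$sigma_px[ord]; pr <- table$precision_nm[ord]

  # event accumulators
  ex <- ey <- ew <- eph <- esg <- epr <- efirst <- elast <- numeric(0)
  active <- integer(0)   # indices into the accumulators
  n_ev <- 0L
  for (i in seq_len(n)) {
    f <- fr[i]
    if (length(active)) {
      alive <- f - elast[active] <= max_dark_frames + 1
      active <- active[alive]
    }
    j <- 0L
    if (length(active)) {
      cand <- active[elast[active] < f]   # not already matched this frame
      if (length(cand)) {
        d2 <- (ex[cand] / ew[cand] - x[i])^2 + (ey[cand] / ew[cand] - y[i])^2
        k <- which(d2 <= radius_nm^2)
        if (length(k)) {
          k <- k[order(d2[k], cand[k])][1]
          j <- cand[k]
        }
      }
    }
    if (j > 0L) {
      ex[j] <- ex[j] + w[i] * x[i]
      ey[j] <- ey[j] + w[i] * y[i]
      ew[j] <- ew[j] + w[i]
      eph[j] <- eph[j] + ph[i]
      esg[j] <- esg[j] + w[i] * sg[i]
      epr[j] <- if (all(is.na(c(epr[j], pr[i])))) NA_real_ else
        min(epr[j], pr[i], na.rm = TRUE)
      elast[j] <- f
    } else {
      n_ev <- n_ev + 1L
      ex[n_ev] <- w[i] * x[i]; ey[n_ev] <- w[i] * y[i]; ew[n_ev] <- w[i]
      eph[n_ev] <- ph[i]; esg[n_ev] <- w[i] * sg[i]; epr[n_ev] <- pr[i]
      efirst[n_ev] <- f; elast[n_ev] <- f
      active <- c(active, n_ev)
    }
  }
  loc_table(ex / ew, ey / ew, efirst, eph, esg / ew, epr,
            pixel_size_nm = attr(table, "pixel_size_nm"),
            n_frames = attr(table, "n_frames"),
            target_id = attr(table, "target_id"))
}

# 2D count histogram of positions on a fixed grid
hist2d <- function(x, y, origin, pixel, nx, ny) {
  ix <- floor((x - origin[1]) / pixel) + 1
  iy <- floor((y - origin[2]) / pixel) + 1
  ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
  m <- matrix(0, nx, ny)
  if (any(ok)) {
    idx <- (iy[ok] - 1) * nx + ix[ok]
    cnt <- tabulate(idx, nbins = nx * ny)
    m[] <- cnt
  }
  m
}

# Translation (dx, dy) in pixels such that shifting image B by it best
# aligns B with A; sub-pixel by 3-point parabola. Images are zero-padded to
# twice their size to avoid circular wrap.
xcorr_offset <- function(A, B, max_shift_px = Inf) {
  nx <- nrow(A); ny <- ncol(A)
  px <- 2 * nx; py <- 2 * ny
  PA <- matrix(0, px, py); PA[1:nx, 1:ny] <- A - mean(A)
  PB <- matrix(0, px, py); PB[1:nx, 1:ny] <- B - mean(B)
  C <- Re(fft(fft(PA) * Conj(fft(PB)), inverse = TRUE))
  if (is.finite(max_shift_px)) {
    sx <- ifelse(0:(px - 1) > px / 2, 0:(px - 1) - px, 0:(px - 1))
    sy <- ifelse(0:(py - 1) > py / 2, 0:(py - 1) - py, 0:(py - 1))
    allowed <- outer(abs(sx) <= max_shift_px, abs(sy) <= max_shift_px, "&")
    Cmask <- C
    Cmask[!allowed] <- -Inf
    peak <- which.max(Cmask)
  } else {
    peak <- which.max(C)
  }
  pi_ <- (peak - 1) %% px
  pj_ <- (peak - 1) %/% px
  sub <- function(c_m, c_l, c_r) {
    den <- c_l - 2 * c_m + c_r
    if (den == 0) 0 else max(-0.5, min(0.5, 0.5 * (c_l - c_r) / den))
  }
  wrap <- function(i, nmax) ((i %% nmax) + nmax) %% nmax
  cm <- C[peak]
  cl <- C[wrap(pi_ - 1, px) + 1, pj_ + 1]
  cr <- C[wrap(pi_ + 1, px) + 1, pj_ + 1]
  cu <- C[pi_ + 1, wrap(pj_ - 1, py) + 1]
  cd <- C[pi_ + 1, wrap(pj_ + 1, py) + 1]
  ix_peak <- if (pi_ > px / 2) pi_ - px else pi_
  iy_peak <- if (pj_ > py / 2) pj_ - py else pj_
  dx <- ix_peak + sub(cm, cl, cr)
  dy <- iy_peak + sub(cm, cu, cd)
  prominence <- (cm - mean(C)) / max(sd(C), .Machine$double.eps)
  # plateau width: a reliable peak is spatially compact; count cells whose
  # correlation comes within 10% (above the mean) of the peak value
  near <- C - mean(C) >= 0.9 * (cm - mean(C))
  # a peak on the search-window boundary means the true optimum may lie
  # outside the window -- untrustworthy for a residual (small) offset
  at_edge <- is.finite(max_shift_px) &&
    max(abs(c(ix_peak, iy_peak))) >= floor(max_shift_px)
  list(offset_px = c(dx, dy), prominence = prominence,
       plateau_cells = sum(near), at_edge = at_edge)
}

#' Redundant cross-correlation drift correction
#'
#' The acquisition is cut into temporal segments of `segment_frames` frames;
#' every pair of segment density images is cross-correlated, and the
#' per-segment offsets are solved from all pairwise measurements by least
#' squares (redundant cross-correlation). The per-frame drift is linearly
#' interpolated between segment midpoints (with linear extrapolation at the
#' ends), normalized to mean zero -- drift is only defined up to a global
#' translation -- and subtracted.
#'
#' @param table a [loc_table()] (for a multi-target acquisition, combine the
#'   targets before estimation; the estimate applies to all of them).
#' @param segment_frames frames per segment.
#' @param render_pixel_nm rendering pixel for the correlation images.
#' @return list with `table` (corrected) and `drift_nm` (`n_frames` x 2
#'   estimated trajectory, mean zero).
#' @export
drift_correct_rcc <- function(table, segment_frames = 1000,
                              render_pixel_nm = 30) {
  nf <- attr(table, "n_frames")
  if (nf < 2 * segment_frames)
    stopf("need n_frames >= 2 * segment_frames (%d < %d)", nf,
          2 * segment_frames)
  S <- floor(nf / segment_frames)
  seg <- pmin(table$frame %/% segment_frames, S - 1)
  origin <- c(min(table$x_nm), min(table$y_nm))
  nx <- floor((max(table$x_nm) - origin[1]) / render_pixel_nm) + 1
  ny <- floor((max(table$y_nm) - origin[2]) / render_pixel_nm) + 1
  imgs <- lapply(0:(S - 1), function(s) {
    sel <- seg == s
    hist2d(table$x_nm[sel], table$y_nm[sel], origin, render_pixel_nm, nx, ny)
  })
  # pairwise offsets: o_j - o_i for all i < j
  rows <- list(); dvals <- list()
  for (i in 1:(S - 1)) {
    for (j in (i + 1):S) {
      m <- xcorr_offset(imgs[[j]], imgs[[i]])   # shift of segment j vs i
      r <- numeric(S); r[i] <- -1; r[j] <- 1
      rows[[length(rows) + 1]] <- r
      dvals[[length(dvals) + 1]] <- m$offset_px * render_pixel_nm
    }
  }
  Amat <- do.call(rbind, rows)[, -1, drop = FALSE]  # o_1 = 0 reference
  D <- do.call(rbind, dvals)
  sol <- qr.solve(Amat, D)
  o <- rbind(c(0, 0), sol)                      # per-segment offsets (nm)
  mid <- (0:(S - 1) + 0.5) * segment_frames
  mid[S] <- (mid[S] + (nf - 1)) / 2             # last segment absorbs remainder
  frames <- 0:(nf - 1)
  interp_extrap <- function(v) {
    out <- approx(mid, v, xout = frames, rule = 2)$y
    # linear extrapolation beyond the first/last midpoints
    lo <- frames < mid[1]
    hi <- frames > mid[S]
    out[lo] <- v[1] + (v[2] - v[1]) / (mid[2] - mid[1]) * (frames[lo] - mid[1])
    out[hi] <- v[S] + (v[S] - v[S - 1]) / (mid[S] - mid[S - 1]) *
      (frames[hi] - mid[S])
    out
  }
  drift <- cbind(interp_extrap(o[, 1]), interp_extrap(o[, 2]))
  drift <- sweep(drift, 2, colMeans(drift))
  out <- table
  out$x_nm <- out$x_nm - drift[out$frame + 1, 1]
  out$y_nm <- out$y_nm - drift[out$frame + 1, 2]
  list(table = reloc(out, table), drift_nm = drift)
}

#' Fit a degree-2 polynomial chromatic transform from bead pairs
#'
#' Least-squares polynomial registration between two channels from fiducial
#' control points. The forward model regresses the moving-channel positions
#' on the fixed-channel positions (recovering planted warp coefficients
#' exactly on noise-free pairs); the correction applied to localization
#' tables is the least-squares inverse fit (moving -> fixed).
#'
#' @param fixed_points,moving_points Nx2 matrices of paired positions (nm),
#'   at least 6 pairs (a degree-2 polynomial in 2D has 6 coefficients per
#'   axis).
#' @return a `chromatic_transform`: list with `degree`, `coef_fwd` (6x2,
#'   fixed -> moving), `coef_inv` (6x2, moving -> fixed), `fit_rmse_nm`
#'   (residual of the inverse fit at the control points).
#' @export
fit_chromatic_transform <- function(fixed_points, moving_points) {
  fixed_points <- as.matrix(fixed_points)
  moving_points <- as.matrix(moving_points)
  if (nrow(fixed_points) < 6)
    stopf("underdetermined: degree-2 polynomial needs >= 6 point pairs")
  if (nrow(fixed_points) != nrow(moving_points))
    stopf("fixed and moving point counts differ")
  Bf <- poly2_basis(fixed_points[, 1], fixed_points[, 2])
  Bm <- poly2_basis(moving_points[, 1], moving_points[, 2])
  if (qr(Bf)$rank < 6 || qr(Bm)$rank < 6)
    warnf("degenerate control-point configuration: polynomial fit is ill-conditioned")
  coef_fwd <- qr.solve(qr(Bf, LAPACK = TRUE), moving_points)
  coef_inv <- qr.solve(qr(Bm, LAPACK = TRUE), fixed_points)
  resid <- Bm %*% coef_inv - fixed_points
  structure(list(degree = 2, coef_fwd = coef_fwd, coef_inv = coef_inv,
                 fit_rmse_nm = sqrt(mean(rowSums(resid^2)))),
            class = "chromatic_transform")
}

#' Apply a chromatic transform to a localization table
#'
#' Maps the table's positions from the moving channel into the fixed
#' channel's coordinate frame using the fitted inverse polynomial.
#'
#' @param model a `chromatic_transform` from [fit_chromatic_transform()].
#' @param table a [loc_table()].
#' @return the corrected [loc_table()].
#' @export
apply_transform <- function(model, table) {
  w <- apply_warp(cbind(table$x_nm, table$y_nm), model$coef_inv)
  out <- table
  out$x_nm <- w[, 1]
  out$y_nm <- w[, 2]
  reloc(out, table)
}

#' Correct the residual translational offset between two targets
#'
#' Renders both tables on a common grid, cross-correlates the density
#' images, and translates `other_table` by the sub-pixel correlation peak so
#' it aligns with `reference_table`. The measurement is flagged
#' low-confidence -- and no shift is applied -- when the correlation peak is
#' weak (low prominence, as on unrelated point patterns) or not spatially
#' compact (a plateau, as when one pattern sits entirely inside the other so
#' many shifts correlate equally well).
#'
#' @param reference_table,other_table [loc_table()] objects with overlapping
#'   bounding boxes.
#' @param render_pixel_nm rendering pixel for the correlation images.
#' @param min_prominence prominence (peak z-score) below which the shift is
#'   flagged low-confidence.
#' @param max_shift_nm search window half-width for the correlation peak;
#'   residual offsets are small by construction, so the default restricts
#'   the search to +/- 100 nm.
#' @param max_plateau_cells maximum number of near-peak cells for the peak
#'   to count as compact.
#' @return list with `table` (shifted `other_table` when confident,
#'   unshifted otherwise), `offset_nm` (the measured shift), `prominence`,
#'   `low_confidence`.
#' @export
correct_residual_offset <- function(reference_table, other_table,
                                    render_pixel_nm = 20,
                                    min_prominence = 20,
                                    max_shift_nm = 100,
                                    max_plateau_cells = 8) {
  bbox_overlap <-
    min(max(reference_table$x_nm), max(other_table$x_nm)) >
      max(min(reference_table$x_nm), min(other_table$x_nm)) &&
    min(max(reference_table$y_nm), max(other_table$y_nm)) >
      max(min(reference_table$y_nm), min(other_table$y_nm))
  if (!bbox_overlap) stopf("bounding boxes of the two targets do not overlap")
  origin <- c(min(reference_table$x_nm, other_table$x_nm),
              min(reference_table$y_nm, other_table$y_nm))
  nx <- floor((max(reference_table$x_nm, other_table$x_nm) - origin[1]) /
                render_pixel_nm) + 1
  ny <- floor((max(reference_table$y_nm, other_table$y_nm) - origin[2]) /
                render_pixel_nm) + 1
  A <- hist2d(reference_table$x_nm, reference_table$y_nm, origin,
              render_pixel_nm, nx, ny)
  B <- hist2d(other_table$x_nm, other_table$y_nm, origin,
              render_pixel_nm, nx, ny)
  m <- xcorr_offset(A, B, max_shift_nm / render_pixel_nm)
  offset_nm <- m$offset_px * render_pixel_nm
  low_confidence <- m$prominence < min_prominence ||
    m$plateau_cells > max_plateau_cells || m$at_edge
  out <- other_table
  if (!low_confidence) {
    out$x_nm <- out$x_nm + offset_nm[1]
    out$y_nm <- out$y_nm + offset_nm[2]
  }
  list(table = reloc(out, other_table), offset_nm = offset_nm,
       prominence = m$prominence, low_confidence = low_confidence)
}
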
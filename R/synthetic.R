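# Synthetic four-target synaptic fields with planted ground truth.
#
# The generator emulates the acquisition geometry the pipeline is built for:
# two scaffold targets delimiting the synapse (a presynaptic mask target and
# a postsynaptic target), two analysis targets with planted Gaussian
# nanoclusters plus uniform background, DNA-PAINT-style blinking (binding
# events expanded into runs of per-frame localizations with short dark gaps),
# short-lived nonspecific binders, and optional drift / chromatic warp
# corruption. A ground-truth sidecar records everything planted so every
# downstream stage is verifiable.

#' Default parameters of the synthetic field generator
#'
#' Values reflect the study conditions of the imaging protocol the pipeline
#' models: 30,000 acquisition frames, 160-nm camera pixels, an en-face
#' synapse of ~200 nm active-zone radius, nanoclusters of ~15-20 nm Gaussian
#' spread producing detected radii in the 20-30 nm range, ~60 binding events
#' per nanocluster, 10% nonspecific background, events lasting a mean of 3
#' frames, and ~8 nm localization precision.
#'
#' @param architecture `"co_organized"`, `"segregated"` or `"independent"`
#'   relative placement of the two analysis targets' nanoclusters.
#' @param ... overrides of any default listed below.
#' @return a named list of generator parameters.
#' @export
field_params <- function(architecture = c("co_organized", "segregated",
                                          "independent"), ...) {
  architecture <- match.arg(architecture)
  p <- list(
    architecture = architecture,
    n_frames = 30000L,
    pixel_size_nm = 160,
    field_size_nm = 2000,
    synapse_radius_nm = 200,
    en_face = TRUE,
    aspect = 3,              # axis ratio of side-view-like scaffolds
    psd_scale = 1,
    psd_offset_nm = c(0, 0),
    scaffold_events = 600,
    k_a = 3L, k_b = 3L,      # planted nanocluster counts
    events_per_cluster = 60L,
    nc_sd_a_nm = 15, nc_sd_b_nm = 20,
    background_fraction = 0.1,
    nc_min_sep_nm = 100,     # min distance between planted centers (distinct,
                             # resolvable objects at the ~25-30 nm radius scale)
    nc_place_frac = 0.7,     # centers within this fraction of the radius
    co_offset_nm = 0,        # displacement of B centers when co-organized
    seg_min_dist_nm = 100,   # min A-B center distance when segregated
    mean_on_frames = 3,
    dark_gap_prob = 0.2,
    max_dark_gap = 3,
    precision_meanlog = log(8), precision_sdlog = 0.25,
    photons_meanlog = log(800), photons_sdlog = 0.3,
    sigma_mean_px = 1.0, sigma_sd_px = 0.15,
    qc_bad_fraction = 0.02,
    n_nonspecific = 2L,
    nonspecific_events = 500L,
    nonspecific_sd_nm = 60,
    nonspecific_frame_sd_frac = 0.05,
    targets = c(mask = "Bassoon", post = "PSD95", a = "Munc13", b = "CaV21"))
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown))
    stopf("unknown generator parameter(s): %s", paste(unknown, collapse = ", "))
  p[names(over)] <- over
  if (p$n_frames < 1 || p$scaffold_events < 1 || p$events_per_cluster < 1 ||
      p$synapse_radius_nm <= 0 || p$nc_sd_a_nm <= 0 || p$nc_sd_b_nm <= 0)
    stopf("generator parameters must be positive")
  if (p$background_fraction < 0 || p$background_fraction >= 1)
    stopf("background_fraction must lie in [0, 1)")
  p
}

# uniform points in the (possibly elliptical) scaffold footprint
runif_disc <- function(n, center, radius, aspect = 1) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  sa <- sqrt(aspect)
  cbind(center[1] + r * cos(th) * sa, center[2] + r * sin(th) / sa)
}

# rejection-sample n points in the disc with pairwise min separation and
# optional min distance to an `avoid` set
sample_centers <- function(n, center, radius, min_sep, avoid = NULL,
                           avoid_dist = 0, aspect = 1, max_tries = 20000) {
  out <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(out) < n) {
    cand <- runif_disc(1, center, radius, aspect)
    ok <- TRUE
    if (nrow(out) &&
        min(sqrt((out[, 1] - cand[1])^2 + (out[, 2] - cand[2])^2)) < min_sep)
      ok <- FALSE
    if (ok && !is.null(avoid) && nrow(avoid) &&
        min(sqrt((avoid[, 1] - cand[1])^2 + (avoid[, 2] - cand[2])^2)) <
          avoid_dist)
      ok <- FALSE
    if (ok) out <- rbind(out, cand)
    tries <- tries + 1
    if (tries > max_tries)
      stopf("could not place %d cluster centers with the given separations", n)
  }
  out
}

# Expand binding events (one row per event: x, y) into per-frame
# localizations with geometric run lengths, allowed dark gaps, localization
# precision jitter and per-localization quality covariates.
expand_blinking <- function(events, p) {
  n <- nrow(events)
  if (n == 0)
    return(data.frame(x = numeric(0), y = numeric(0), frame = integer(0),
                      event = integer(0)))
  start <- sample.int(p$n_frames, n, replace = TRUE) - 1L
  len <- 1L + rgeom(n, 1 / p$mean_on_frames)
  has_gap <- len >= 2 & runif(n) < p$dark_gap_prob
  gap <- ifelse(has_gap, sample.int(p$max_dark_gap, n, replace = TRUE), 0L)
  cut <- ifelse(len >= 2, 1L + floor(runif(n) * (len - 1L)), 1L)
  ev <- rep.int(seq_len(n), len)
  pos <- sequence(len)
  fr <- start[ev] + pos - 1L + gap[ev] * (pos > cut[ev])
  keep <- fr < p$n_frames
  data.frame(x = events[ev[keep], 1], y = events[ev[keep], 2],
             frame = as.integer(fr[keep]), event = ev[keep])
}

finish_table <- function(locs, p, target_id) {
  n <- nrow(locs)
  precision <- rlnorm(n, p$precision_meanlog, p$precision_sdlog)
  x <- locs$x + rnorm(n, 0, precision)
  y <- locs$y + rnorm(n, 0, precision)
  photons <- rlnorm(n, p$photons_meanlog, p$photons_sdlog)
  sigma <- pmax(0.05, rnorm(n, p$sigma_mean_px, p$sigma_sd_px))
  sigma <- pmin(pmax(sigma, 0.35), 1.55)   # baseline rows pass the QC bounds
  # plant quality violations so the filters have work to do
  if (p$qc_bad_fraction > 0 && n > 0) {
    bad_s <- runif(n) < p$qc_bad_fraction
    sigma[bad_s] <- ifelse(runif(sum(bad_s)) < 0.5, 0.2, 1.8)
    bad_p <- runif(n) < p$qc_bad_fraction
    precision[bad_p] <- runif(sum(bad_p), 21, 35)
    bad_ph <- runif(n) < p$qc_bad_fraction
    photons[bad_ph] <- photons[bad_ph] * 10
  }
  tab <- loc_table(x, y, locs$frame, photons, sigma, precision,
                   pixel_size_nm = p$pixel_size_nm, n_frames = p$n_frames,
                   target_id = target_id)
  tab
}

#' Simulate a four-target synaptic field with planted ground truth
#'
#' Scaffold target 1 (synapse mask role) fills the synapse footprint,
#' scaffold target 2 (postsynaptic role) fills a concentric footprint scaled
#' by `psd_scale` and shifted by `psd_offset_nm`; analysis targets A and B
#' draw binding events from planted Gaussian nanoclusters plus uniform
#' in-synapse background. Every binding event is expanded into a run of
#' per-frame localizations (geometric run length, short dark gaps) jittered
#' by the localization precision. Nonspecific binders are planted as tight
#' spatial clusters whose frames are drawn from a narrow window so the
#' frame-statistics filter can identify them.
#'
#' @param params a [field_params()] list.
#' @param seed integer RNG seed; identical seed and parameters reproduce
#'   identical tables.
#' @return list with `tables` (named list of [loc_table()]: `mask`, `post`,
#'   `a`, `b`) and `truth` (ground-truth list: planted geometry, cluster
#'   centers/spreads/occupancies, nonspecific labels, drift, warp, seed).
#' @export
simulate_field <- function(params = field_params(), seed = 1) {
  p <- params
  with_seed(seed, {
    ctr <- c(p$field_size_nm / 2, p$field_size_nm / 2)
    aspect <- if (p$en_face) 1 else p$aspect
    place_r <- p$nc_place_frac * p$synapse_radius_nm
    # planted nanocluster centers; for the segregated architecture A and B
    # are drawn jointly so the cross-separation constraint stays satisfiable
    if (p$architecture == "segregated") {
      got <- NULL
      for (attempt in 1:50) {
        got <- tryCatch({
          ca_try <- sample_centers(p$k_a, ctr, place_r, p$nc_min_sep_nm,
                                   aspect = aspect, max_tries = 2000)
          cb_try <- sample_centers(p$k_b, ctr, place_r, p$nc_min_sep_nm,
                                   avoid = ca_try,
                                   avoid_dist = p$seg_min_dist_nm,
                                   aspect = aspect, max_tries = 2000)
          list(ca = ca_try, cb = cb_try)
        }, error = function(e) NULL)
        if (!is.null(got)) break
      }
      if (is.null(got))
        stopf("could not place segregated cluster centers; relax k or distances")
      ca <- got$ca
      cb <- got$cb
    } else {
      ca <- sample_centers(p$k_a, ctr, place_r, p$nc_min_sep_nm,
                           aspect = aspect)
      cb <- switch(p$architecture,
        co_organized = {
          base <- ca[rep_len(seq_len(p$k_a), p$k_b), , drop = FALSE]
          if (p$co_offset_nm != 0) {
            th <- runif(p$k_b, 0, 2 * pi)
            base + p$co_offset_nm * cbind(cos(th), sin(th))
          } else base
        },
        independent = sample_centers(p$k_b, ctr, place_r, p$nc_min_sep_nm,
                                     aspect = aspect))
    }
    # binding events per target
    ev_mask <- runif_disc(p$scaffold_events, ctr, p$synapse_radius_nm, aspect)
    ev_post <- runif_disc(p$scaffold_events, ctr + p$psd_offset_nm,
                          p$psd_scale * p$synapse_radius_nm, aspect)
    cluster_events <- function(centers, sd_nm, k) {
      n_sig <- k * p$events_per_cluster
      sig <- centers[rep(seq_len(k), each = p$events_per_cluster), ,
                     drop = FALSE] + matrix(rnorm(2 * n_sig, 0, sd_nm),
                                            ncol = 2)
      n_bg <- round(n_sig * p$background_fraction / (1 - p$background_fraction))
      rbind(sig, runif_disc(n_bg, ctr, p$synapse_radius_nm, aspect))
    }
    ev_a <- cluster_events(ca, p$nc_sd_a_nm, p$k_a)
    ev_b <- cluster_events(cb, p$nc_sd_b_nm, p$k_b)
    # nonspecific binders on the mask target, away from the synapse
    ns_centers <- matrix(numeric(0), 0, 2)
    ns_events <- matrix(numeric(0), 0, 2)
    ns_frames <- integer(0)
    if (p$n_nonspecific > 0) {
      for (i in seq_len(p$n_nonspecific)) {
        repeat {
          cc <- runif(2, 0.1 * p$field_size_nm, 0.9 * p$field_size_nm)
          far_syn <- sqrt(sum((cc - ctr)^2)) > 2.5 * p$synapse_radius_nm
          far_ns <- !nrow(ns_centers) ||
            min(sqrt((ns_centers[, 1] - cc[1])^2 +
                     (ns_centers[, 2] - cc[2])^2)) >
              6 * p$nonspecific_sd_nm
          if (far_syn && far_ns) break
        }
        ns_centers <- rbind(ns_centers, matrix(cc, 1))
        pts <- cbind(rnorm(p$nonspecific_events, cc[1], p$nonspecific_sd_nm),
                     rnorm(p$nonspecific_events, cc[2], p$nonspecific_sd_nm))
        fmid <- runif(1, 0.15, 0.85) * p$n_frames
        fr <- round(rnorm(p$nonspecific_events, fmid,
                          p$nonspecific_frame_sd_frac * p$n_frames))
        fr <- pmin(pmax(fr, 0), p$n_frames - 1L)
        ns_events <- rbind(ns_events, pts)
        ns_frames <- c(ns_frames, as.integer(fr))
      }
    }
    # blinking expansion
    locs_mask <- expand_blinking(ev_mask, p)
    locs_post <- expand_blinking(ev_post, p)
    locs_a <- expand_blinking(ev_a, p)
    locs_b <- expand_blinking(ev_b, p)
    ns_rows <- nrow(ns_events)
    if (ns_rows) {
      # nonspecific binders are short-lived: one frame each
      locs_ns <- data.frame(x = ns_events[, 1], y = ns_events[, 2],
                            frame = ns_frames,
                            event = max(locs_mask$event, 0) +
                              seq_len(ns_rows))
      nonspecific_mask <- c(rep(FALSE, nrow(locs_mask)),
                            rep(TRUE, ns_rows))
      locs_mask <- rbind(locs_mask, locs_ns)
    } else {
      nonspecific_mask <- rep(FALSE, nrow(locs_mask))
    }
    tables <- list(
      mask = finish_table(locs_mask, p, p$targets[["mask"]]),
      post = finish_table(locs_post, p, p$targets[["post"]]),
      a = finish_table(locs_a, p, p$targets[["a"]]),
      b = finish_table(locs_b, p, p$targets[["b"]]))
    truth <- structure(list(
      synapse_center_nm = ctr,
      synapse_radius_nm = p$synapse_radius_nm,
      en_face = p$en_face,
      architecture = p$architecture,
      centers_a = ca, centers_b = cb,
      nc_sd_a_nm = p$nc_sd_a_nm, nc_sd_b_nm = p$nc_sd_b_nm,
      events_per_cluster = p$events_per_cluster,
      background_fraction = p$background_fraction,
      n_events = c(mask = nrow(ev_mask) + ns_rows, post = nrow(ev_post),
                   a = nrow(ev_a), b = nrow(ev_b)),
      nonspecific_centers = ns_centers,
      nonspecific_rows_mask = nonspecific_mask,
      drift_trajectory = matrix(0, p$n_frames, 2),
      warp_coefficients = NULL,
      params = p, seed = seed), class = "ground_truth")
    list(tables = tables, truth = truth)
  })
}

#' Degree-2 polynomial warp coefficients
#'
#' Builds a 6x2 coefficient matrix over the monomial basis
#' `(1, x, y, x^2, xy, y^2)` mapping true to observed coordinates.
#' `make_warp()` with no arguments is the identity.
#'
#' @param translation_nm length-2 offset.
#' @param linear 2x2 matrix (defaults to identity).
#' @param quad 3x2 matrix of the `x^2, xy, y^2` terms for x' and y'.
#' @return 6x2 coefficient matrix.
#' @export
make_warp <- function(translation_nm = c(0, 0), linear = diag(2),
                      quad = matrix(0, 3, 2)) {
  rbind(matrix(translation_nm, 1), t(linear)[1:2, ], quad)
}

poly2_basis <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)

#' Apply a degree-2 polynomial warp to coordinates
#' @param points Nx2 matrix.
#' @param coef 6x2 coefficient matrix from [make_warp()] or a fitted model.
#' @return warped Nx2 matrix.
#' @export
apply_warp <- function(points, coef) {
  poly2_basis(points[, 1], points[, 2]) %*% coef
}

#' Corrupt a simulated field with drift and chromatic warp
#'
#' Positions are displaced by the drift trajectory evaluated at each
#' localization's frame, and the listed targets are additionally warped by a
#' degree-2 polynomial (emulating inter-channel chromatic aberration). The
#' ground truth is updated with what was applied.
#'
#' @param field result of [simulate_field()].
#' @param drift `n_frames` x 2 matrix of per-frame offsets (nm), or `NULL`.
#' @param warp 6x2 coefficient matrix from [make_warp()], or `NULL`.
#' @param warp_targets names of the tables to warp (default the second
#'   spectral channel: `post` and `b`).
#' @return the corrupted field (same structure).
#' @export
corrupt_field <- function(field, drift = NULL, warp = NULL,
                          warp_targets = c("post", "b")) {
  truth <- field$truth
  nf <- attr(field$tables[[1]], "n_frames")
  if (!is.null(drift)) {
    drift <- as.matrix(drift)
    if (nrow(drift) != nf)
      stopf("drift trajectory has %d rows but the acquisition has %d frames",
            nrow(drift), nf)
    field$tables <- lapply(field$tables, function(tab) {
      tab$x_nm <- tab$x_nm + drift[tab$frame + 1L, 1]
      tab$y_nm <- tab$y_nm + drift[tab$frame + 1L, 2]
      tab
    })
    truth$drift_trajectory <- truth$drift_trajectory + drift
  }
  if (!is.null(warp)) {
    for (nm in warp_targets) {
      tab <- field$tables[[nm]]
      w <- apply_warp(cbind(tab$x_nm, tab$y_nm), warp)
      tab$x_nm <- w[, 1]
      tab$y_nm <- w[, 2]
      field$tables[[nm]] <- tab
    }
    truth$warp_coefficients <- warp
    truth$warp_targets <- warp_targets
  }
  field$truth <- truth
  field
}

#' Simulated fiducial bead control-point pairs for a chromatic warp
#'
#' A regular grid of "bead" positions across the field, paired with their
#' warped positions, as produced by imaging multi-color beads.
#'
#' @param warp 6x2 warp coefficients (true -> observed).
#' @param field_size_nm field extent.
#' @param n_side beads per side of the grid.
#' @return list with `fixed` and `moving` Nx2 matrices.
#' @export
simulate_bead_pairs <- function(warp, field_size_nm = 2000, n_side = 6) {
  g <- seq(0.05, 0.95, length.out = n_side) * field_size_nm
  fixed <- as.matrix(expand.grid(x = g, y = g))
  colnames(fixed) <- NULL
  list(fixed = fixed, moving = apply_warp(fixed, warp))
}

#' Write a ground-truth sidecar as YAML
#' @param truth a `ground_truth` list.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  g <- truth
  g$params$targets <- as.list(g$params$targets)
  g$centers_a <- apply(g$centers_a, 1, as.numeric, simplify = FALSE)
  g$centers_b <- apply(g$centers_b, 1, as.numeric, simplify = FALSE)
  g$nonspecific_centers <- apply(g$nonspecific_centers, 1, as.numeric,
                                 simplify = FALSE)
  g$nonspecific_rows_mask <- which(g$nonspecific_rows_mask)
  g$drift_trajectory <- NULL  # bulky; kept in the in-memory object only
  g$n_events <- as.list(g$n_events)
  class(g) <- NULL
  yaml::write_yaml(g, path)
  invisible(path)
}
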
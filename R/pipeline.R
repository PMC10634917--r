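# Pipeline orchestration: configuration, the per-field analysis chain, and
# file-level execution with a run manifest.

#' Pipeline configuration with every stage parameter
#'
#' Defaults follow the analysis conventions of the imaging protocol the
#' pipeline models: 160-nm camera pixels, PSF-sigma bounds 0.3-1.6 px,
#' 20-nm precision ceiling, photon-mode rule, 0.3-px linking radius with 5
#' dark frames, 1000-frame drift segments, 48-nm/10-point synaptic DBSCAN
#' with the 75-localization minimum, frame-SD bounds 2500-11000 (stated for
#' a 30,000-frame acquisition -- rescale for shorter ones), 70% scaffold
#' overlap, roundness limit 2, 25-localization active-zone minimum, 25-nm/
#' 5-point nanocluster DBSCAN with the 5-localization minimum and ROUT
#' Q = 0.1% area filter, 150-nm alpha radius (0.9375 px), 100 normalization
#' and 50 classification randomizations, a 60-nm / 1.96-SD enrichment
#' classification rule, and 0-200 nm radial bins in 10-nm steps.
#'
#' @param seed master seed; all per-synapse randomization seeds derive from
#'   it by a stable hash.
#' @param ... overrides of any default (nested lists are replaced whole).
#' @return a nested named list of parameters.
#' @export
az_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    pixel_size_nm = 160,
    reference_target = "a",       # residual-offset reference role
    qc = list(sigma_bounds_px = c(0.3, 1.6), precision_max_nm = 20,
              photon_bin_width = 50, photon_mode_edge = "upper"),
    link = list(radius_px = 0.3, max_dark_frames = 5),
    drift = list(enabled = TRUE, segment_frames = 1000, render_pixel_nm = 30),
    chromatic = list(targets = c("post", "b")),
    offset = list(enabled = TRUE, render_pixel_nm = 20, min_prominence = 20,
                  max_shift_nm = 100),
    synapse = list(eps_nm = 48, min_points = 10, min_cluster_size = 75,
                   frame_sd_bounds = c(2500, 11000), mean_k_sd = 2,
                   alpha_radius_nm = 150, overlap_min = 0.70, shape_max = 2,
                   overlap_denominator = "smaller", min_locs = 25,
                   pair_max_nm = 500, raster_cell_nm = 2),
    nanocluster = list(eps_nm = 25, min_points = 5, alpha_radius_nm = 150,
                       min_locs = 5, rout_q = 0.001),
    autocorr = list(bin_edges_nm = seq(0, 200, 10), min_points = 25),
    enrichment = list(bin_edges_nm = seq(0, 200, 10), n_rand_norm = 100,
                      n_rand_class = 50, r_max_nm = 60, k_sd = 1.96,
                      raster_cell_nm = 2, smooth_q = 0.001))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stopf("unknown config entry: %s", nm)
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      sub <- over[[nm]]
      bad <- setdiff(names(sub), names(cfg[[nm]]))
      if (length(bad)) stopf("unknown config entry: %s$%s", nm, bad[1])
      cfg[[nm]][names(sub)] <- sub
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg
}

#' Run the full analysis chain on one field of view
#'
#' Stage order: quality filtering, drift correction (redundant
#' cross-correlation on the combined targets), chromatic correction from
#' bead pairs (when given), residual offset correction of each target to
#' the reference target, temporal linking, scaffold cluster detection with
#' nonspecific-cluster rejection, en-face synapse selection, active-zone
#' restriction, per-synapse autocorrelation and nanocluster detection,
#' dataset-level nanocluster filtering, randomization-normalized
#' cross-enrichment with per-nanocluster classification, and separation
#' indices. Randomization seeds derive from the config's master seed per
#' (synapse, protein, purpose), so results are reproducible end to end.
#'
#' @param tables named list of [loc_table()]: `mask` (presynaptic scaffold,
#'   Bassoon role), `post` (postsynaptic, PSD-95 role), `a` and `b` (the two
#'   analysis targets).
#' @param config an [az_config()].
#' @param beads optional list with `fixed`/`moving` control points for the
#'   chromatic transform, applied to `config$chromatic$targets`.
#' @return an `az_result`: list with the processed `tables`, `qc`,
#'   `drift_nm`, `synapses` (per-synapse records), `nanoclusters` (data
#'   frame), `classification` (data frame), `separation` (data frame),
#'   `summary`, `manifest`.
#' @export
analyze_field <- function(tables, config = az_config(), beads = NULL) {
  stopifnot(all(c("mask", "post", "a", "b") %in% names(tables)))
  manifest <- list(config = config, counts = list())
  # --- quality filtering ---------------------------------------------------
  qc <- lapply(tables, filter_quality,
               sigma_bounds_px = config$qc$sigma_bounds_px,
               precision_max_nm = config$qc$precision_max_nm,
               photon_bin_width = config$qc$photon_bin_width,
               photon_mode_edge = config$qc$photon_mode_edge)
  tables <- lapply(qc, `[[`, "table")
  manifest$counts$qc <- lapply(qc, function(q) q$report[
    c("rows_in", "rows_removed_sigma", "rows_removed_precision",
      "rows_removed_photons", "rows_out")])
  # --- drift correction ----------------------------------------------------
  drift <- NULL
  if (isTRUE(config$drift$enabled)) {
    comb <- do.call(rbind, lapply(tables, function(t)
      data.frame(x_nm = t$x_nm, y_nm = t$y_nm, frame = t$frame)))
    comb_tab <- loc_table(comb$x_nm, comb$y_nm, comb$frame,
                          pixel_size_nm = attr(tables[[1]], "pixel_size_nm"),
                          n_frames = attr(tables[[1]], "n_frames"),
                          target_id = "combined")
    est <- drift_correct_rcc(comb_tab, config$drift$segment_frames,
                             config$drift$render_pixel_nm)
    drift <- est$drift_nm
    tables <- lapply(tables, function(t) {
      t$x_nm <- t$x_nm - drift[t$frame + 1, 1]
      t$y_nm <- t$y_nm - drift[t$frame + 1, 2]
      reloc(t, t)
    })
  }
  # --- chromatic correction ------------------------------------------------
  if (!is.null(beads)) {
    model <- fit_chromatic_transform(beads$fixed, beads$moving)
    for (nm in intersect(config$chromatic$targets, names(tables)))
      tables[[nm]] <- apply_transform(model, tables[[nm]])
    manifest$counts$chromatic_rmse_nm <- model$fit_rmse_nm
  }
  # --- residual offset -----------------------------------------------------
  if (isTRUE(config$offset$enabled)) {
    ref <- config$reference_target
    offsets <- list()
    for (nm in setdiff(names(tables), ref)) {
      res <- correct_residual_offset(tables[[ref]], tables[[nm]],
                                     config$offset$render_pixel_nm,
                                     config$offset$min_prominence,
                                     config$offset$max_shift_nm)
      tables[[nm]] <- res$table
      offsets[[nm]] <- c(res$offset_nm, low_confidence = res$low_confidence)
    }
    manifest$counts$residual_offsets <- offsets
  }
  # --- temporal linking ----------------------------------------------------
  tables <- lapply(tables, link_localizations,
                   radius_px = config$link$radius_px,
                   max_dark_frames = config$link$max_dark_frames)
  manifest$counts$linked_rows <- vapply(tables, nrow, integer(1))
  # --- scaffold clusters ---------------------------------------------------
  sc <- config$synapse
  lab_mask <- detect_synaptic_clusters(tables$mask, sc$eps_nm, sc$min_points,
                                       sc$min_cluster_size)
  lab_post <- detect_synaptic_clusters(tables$post, sc$eps_nm, sc$min_points,
                                       sc$min_cluster_size)
  manifest$counts$scaffold_clusters <- c(mask = max(lab_mask, 0L),
                                         post = max(lab_post, 0L))
  ns_mask <- suppressWarnings(
    remove_nonspecific_clusters(tables$mask, lab_mask, sc$frame_sd_bounds,
                                sc$mean_k_sd))
  ns_post <- suppressWarnings(
    remove_nonspecific_clusters(tables$post, lab_post, sc$frame_sd_bounds,
                                sc$mean_k_sd))
  lab_mask <- ns_mask$labels
  lab_post <- ns_post$labels
  manifest$counts$specific_clusters <- c(mask = max(lab_mask, 0L),
                                         post = max(lab_post, 0L))
  # --- pair scaffolds and select synapses ----------------------------------
  centroid_of <- function(tab, labels, i)
    c(mean(tab$x_nm[labels == i]), mean(tab$y_nm[labels == i]))
  n_mask <- max(lab_mask, 0L)
  synapses <- list()
  for (i in seq_len(n_mask)) {
    cm <- centroid_of(tables$mask, lab_mask, i)
    n_post <- max(lab_post, 0L)
    if (n_post == 0) next
    dp <- vapply(seq_len(n_post), function(j)
      sqrt(sum((centroid_of(tables$post, lab_post, j) - cm)^2)), numeric(1))
    j <- which.min(dp)
    if (dp[j] > sc$pair_max_nm) next
    bp <- cbind(tables$mask$x_nm, tables$mask$y_nm)[lab_mask == i, ,
                                                    drop = FALSE]
    pp <- cbind(tables$post$x_nm, tables$post$y_nm)[lab_post == j, ,
                                                    drop = FALSE]
    roi <- select_enface(bp, pp, sc$alpha_radius_nm, sc$overlap_min,
                         sc$shape_max, sc$overlap_denominator,
                         sc$raster_cell_nm)
    if (roi$accepted)
      roi <- restrict_to_active_zone(
        roi, list(a = tables$a, b = tables$b, post = tables$post),
        sc$min_locs)
    roi$mask_cluster <- i
    roi$post_cluster <- j
    synapses[[length(synapses) + 1]] <- roi
  }
  manifest$counts$candidate_synapses <- length(synapses)
  accepted <- Filter(function(r) r$accepted, synapses)
  manifest$counts$accepted_synapses <- length(accepted)
  # --- per-synapse nanoclusters and autocorrelation ------------------------
  nc_cfg <- config$nanocluster
  per_syn <- list()
  for (k in seq_along(accepted)) {
    roi <- accepted[[k]]
    entry <- list(roi = roi, autocorr = list(), nanoclusters = list())
    cov_cache <- NULL
    for (tg in c("a", "b")) {
      pts <- cbind(roi$restricted[[tg]]$x_nm, roi$restricted[[tg]]$y_nm)
      ac <- tryCatch(
        autocorrelation(pts, roi$bassoon_shape, config$autocorr$bin_edges_nm,
                        config$enrichment$raster_cell_nm,
                        config$autocorr$min_points, cov_cache),
        error = function(e) NULL)
      if (!is.null(ac)) cov_cache <- ac$cov_cache
      entry$autocorr[[tg]] <- ac
      entry$nanoclusters[[tg]] <-
        detect_nanoclusters(pts, nc_cfg$eps_nm, nc_cfg$min_points,
                            nc_cfg$alpha_radius_nm)
    }
    per_syn[[k]] <- entry
  }
  # --- dataset-level nanocluster filter ------------------------------------
  for (tg in c("a", "b")) {
    all_nc <- unlist(lapply(per_syn, function(e) e$nanoclusters[[tg]]),
                     recursive = FALSE)
    filtered <- suppressWarnings(
      filter_nanoclusters(all_nc, nc_cfg$min_locs, nc_cfg$rout_q))
    kept_areas <- vapply(filtered, function(nc) nc$area_nm2, numeric(1))
    for (k in seq_along(per_syn)) {
      ncs <- per_syn[[k]]$nanoclusters[[tg]]
      ok <- vapply(ncs, function(nc)
        nc$n_locs >= nc_cfg$min_locs &&
          (length(kept_areas) == 0 || nc$area_nm2 <= max(kept_areas, 0)),
        logical(1))
      per_syn[[k]]$nanoclusters[[tg]] <- ncs[ok]
    }
  }
  manifest$counts$nanoclusters <- c(
    a = sum(vapply(per_syn, function(e) length(e$nanoclusters$a), integer(1))),
    b = sum(vapply(per_syn, function(e) length(e$nanoclusters$b), integer(1))))
  # --- cross-enrichment, classification, separation ------------------------
  en_cfg <- config$enrichment
  cls_rows <- list(); si_rows <- list(); nc_rows <- list()
  curve_rows <- list()
  for (k in seq_along(per_syn)) {
    entry <- per_syn[[k]]
    roi <- entry$roi
    shape <- roi$bassoon_shape
    area_cache <- rasterize_shape(shape, en_cfg$raster_cell_nm)
    rand_sets <- list()
    pts <- list(a = cbind(roi$restricted$a$x_nm, roi$restricted$a$y_nm),
                b = cbind(roi$restricted$b$x_nm, roi$restricted$b$y_nm))
    for (tg in c("a", "b")) {
      rand_sets[[tg]] <- list(
        norm = randomize_in_roi(nrow(pts[[tg]]), shape, en_cfg$n_rand_norm,
                                derive_seed(config$seed, k, tg, "norm")),
        cls = randomize_in_roi(nrow(pts[[tg]]), shape, en_cfg$n_rand_class,
                               derive_seed(config$seed, k, tg, "class")))
    }
    for (tg in c("a", "b")) {
      other <- if (tg == "a") "b" else "a"
      ncs <- entry$nanoclusters[[tg]]
      opp <- entry$nanoclusters[[other]]
      for (m in seq_along(ncs)) {
        nc <- ncs[[m]]
        nc_rows[[length(nc_rows) + 1]] <- data.frame(
          synapse = k, target = tg, nc = m, n_locs = nc$n_locs,
          x_nm = nc$centroid_nm[1], y_nm = nc$centroid_nm[2],
          area_nm2 = nc$area_nm2,
          effective_radius_nm = nc$effective_radius_nm)
        prof <- tryCatch(
          cross_enrichment(matrix(nc$centroid_nm, 1), pts[[other]], shape,
                           en_cfg$bin_edges_nm,
                           rand_norm = rand_sets[[other]]$norm,
                           rand_class = rand_sets[[other]]$cls,
                           raster_cell_nm = en_cfg$raster_cell_nm,
                           area_cache = area_cache),
          error = function(e) NULL)
        if (!is.null(prof)) {
          cl <- classify_enrichment(prof, en_cfg$r_max_nm, en_cfg$k_sd)
          cls_rows[[length(cls_rows) + 1]] <- data.frame(
            synapse = k, target = tg, nc = m, statistic = cl$statistic,
            rand_mean = cl$rand_mean, rand_sd = cl$rand_sd,
            class = cl$class)
          curve_rows[[length(curve_rows) + 1]] <-
            list(target = tg, curve = prof$enrichment)
        }
        if (length(opp)) {
          si <- separation_index(nc, opp)
          si_rows[[length(si_rows) + 1]] <- data.frame(
            synapse = k, target = tg, nc = m, d_nm = si$d_nm,
            r1_nm = si$r1_nm, r2_nm = si$r2_nm, si = si$si,
            overlap = si$overlap, degenerate = si$degenerate)
        }
      }
    }
  }
  classification <- if (length(cls_rows)) do.call(rbind, cls_rows)
                    else data.frame()
  separation <- if (length(si_rows)) do.call(rbind, si_rows)
                else data.frame()
  nanoclusters <- if (length(nc_rows)) do.call(rbind, nc_rows)
                  else data.frame()
  # --- population summaries ------------------------------------------------
  summary <- list()
  for (tg in c("a", "b")) {
    cls <- classification[classification$target == tg, , drop = FALSE]
    sep <- separation[separation$target == tg, , drop = FALSE]
    ncd <- nanoclusters[nanoclusters$target == tg, , drop = FALSE]
    smoothed_mean_curve <- NULL
    if (length(curve_rows)) {
      cm <- do.call(rbind, lapply(curve_rows, function(r) r$curve))
      sel <- vapply(curve_rows, function(r) r$target == tg, logical(1))
      if (any(sel)) {
        sm <- smooth_enrichment_population(cm[sel, , drop = FALSE],
                                           en_cfg$smooth_q)
        smoothed_mean_curve <- colMeans(sm, na.rm = TRUE)
      }
    }
    summary[[tg]] <- list(
      n_nanoclusters = nrow(ncd),
      median_effective_radius_nm =
        if (nrow(ncd)) median(ncd$effective_radius_nm) else NA_real_,
      enriched_fraction =
        if (nrow(cls)) mean(cls$class == "enriched") else NA_real_,
      de_enriched_fraction =
        if (nrow(cls)) mean(cls$class == "de_enriched") else NA_real_,
      indistinguishable_fraction =
        if (nrow(cls)) mean(cls$class == "indistinguishable") else NA_real_,
      non_overlap_fraction =
        if (nrow(sep)) mean(!sep$overlap) else NA_real_,
      median_si = if (nrow(sep)) median(sep$si) else NA_real_,
      mean_enrichment_curve = smoothed_mean_curve)
  }
  summary$n_candidate_synapses <- length(synapses)
  summary$n_accepted_synapses <- length(accepted)
  structure(list(tables = tables, qc = manifest$counts$qc, drift_nm = drift,
                 synapses = per_syn, candidates = synapses,
                 nanoclusters = nanoclusters, classification = classification,
                 separation = separation, summary = summary,
                 manifest = manifest),
            class = "az_result")
}

#' Run the pipeline from files and write result tables and a manifest
#'
#' Thin file-level wrapper around [analyze_field()]: reads the four
#' localization tables, runs the chain, and writes per-nanocluster CSVs,
#' a population summary JSON and the run manifest JSON into `out_dir`.
#'
#' @param paths named character vector/list with entries `mask`, `post`,
#'   `a`, `b` (CSV dialect paths).
#' @param out_dir output directory (created if missing).
#' @param config an [az_config()].
#' @param dialect input dialect passed to [read_localizations()].
#' @return the `az_result`, invisibly.
#' @export
run_pipeline <- function(paths, out_dir, config = az_config(),
                         dialect = "csv") {
  tables <- lapply(paths[c("mask", "post", "a", "b")], read_localizations,
                   dialect = dialect)
  res <- analyze_field(tables, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(res$nanoclusters))
    write.csv(res$nanoclusters, file.path(out_dir, "nanoclusters.csv"),
              row.names = FALSE)
  if (nrow(res$classification))
    write.csv(res$classification, file.path(out_dir, "classification.csv"),
              row.names = FALSE)
  if (nrow(res$separation))
    write.csv(res$separation, file.path(out_dir, "separation.csv"),
              row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(res)
}
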
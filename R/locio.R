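# Localization table input/output and rendering.
#
# The package's universal currency is the localization table: one row per
# localization with spatial (nm), temporal (frame) and quality columns, plus
# table-level acquisition metadata. Positions are always stored in nm
# internally; camera-pixel quantities (the PSF-fit sigma, the linking radius)
# are converted at their use sites through `pixel_size_nm`.

#' Construct a localization table
#'
#' @param x_nm,y_nm numeric positions in nm.
#' @param frame integer acquisition frame index, 0-based.
#' @param photons photon counts (>= 0); `NA` if absent.
#' @param sigma_px PSF-fit standard deviation in camera pixels; `NA` if absent.
#' @param precision_nm localization error in nm; `NA` if absent.
#' @param pixel_size_nm camera pixel pitch in nm (table-level metadata).
#' @param n_frames total frames in the acquisition.
#' @param target_id label of the imaged protein.
#' @return a `data.frame` of class `loc_table` with attributes
#'   `pixel_size_nm`, `n_frames` and `target_id`.
#' @export
loc_table <- function(x_nm, y_nm, frame, photons = NA_real_,
                      sigma_px = NA_real_, precision_nm = NA_real_,
                      pixel_size_nm, n_frames, target_id = "target") {
  df <- data.frame(x_nm = as.numeric(x_nm), y_nm = as.numeric(y_nm),
                   frame = as.integer(frame),
                   photons = as.numeric(photons),
                   sigma_px = as.numeric(sigma_px),
                   precision_nm = as.numeric(precision_nm))
  attr(df, "pixel_size_nm") <- as.numeric(pixel_size_nm)
  attr(df, "n_frames") <- as.integer(n_frames)
  attr(df, "target_id") <- as.character(target_id)
  class(df) <- c("loc_table", "data.frame")
  validate_loc_table(df)
  df
}

#' Validate the invariants of a localization table
#'
#' Checks finite positions, frame range, non-negative photons/precision/sigma
#' and positive pixel size. Invisibly returns the table; stops on violation.
#'
#' @param table a `loc_table`.
#' @export
validate_loc_table <- function(table) {
  req <- c("x_nm", "y_nm", "frame", "photons", "sigma_px", "precision_nm")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stopf("localization table lacks column(s): %s", paste(miss, collapse = ", "))
  if (!all(is.finite(table$x_nm)) || !all(is.finite(table$y_nm)))
    stopf("non-finite positions in localization table")
  ps <- attr(table, "pixel_size_nm")
  nf <- attr(table, "n_frames")
  if (is.null(ps) || !is.finite(ps) || ps <= 0)
    stopf("pixel_size_nm must be a positive number")
  if (is.null(nf) || nf < 1) stopf("n_frames must be >= 1")
  if (nrow(table) && (min(table$frame) < 0 || max(table$frame) >= nf))
    stopf("frame indices must lie in [0, n_frames)")
  for (col in c("photons", "sigma_px", "precision_nm")) {
    v <- table[[col]]
    if (any(!is.na(v) & v < 0)) stopf("negative values in %s", col)
  }
  invisible(table)
}

loc_meta <- function(table) {
  list(pixel_size_nm = attr(table, "pixel_size_nm"),
       n_frames = attr(table, "n_frames"),
       target_id = attr(table, "target_id"))
}

# Rebuild a loc_table from a plain data.frame plus metadata of a template.
reloc <- function(df, template) {
  loc_table(df$x_nm, df$y_nm, df$frame, df$photons, df$sigma_px,
            df$precision_nm,
            pixel_size_nm = attr(template, "pixel_size_nm"),
            n_frames = attr(template, "n_frames"),
            target_id = attr(template, "target_id"))
}

on_disk_cols <- c(x = "x_nm", y = "y_nm", frame = "frame",
                  photons = "photons", sigma = "sigma_px",
                  precision = "precision_nm")

#' Read a localization table from disk
#'
#' Two dialects are supported. `csv`: a header row with columns
#' `x, y, frame, photons, sigma, precision` plus a YAML sidecar
#' (`<path>.yaml`) declaring position units (`nm` or `px`), `pixel_size_nm`,
#' `n_frames` and `target_id`. `hdf5`: one group per target with one dataset
#' per column and the metadata as group attributes (read through the
#' system Python's h5py). Positions are converted to nm on read: on-disk
#' pixel units are multiplied by `pixel_size_nm`.
#'
#' Required columns are `x`, `y`, `frame`; missing optional columns
#' (`photons`, `sigma`, `precision`) are filled as absent (`NA`), never zero.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"hdf5"`.
#' @param pixel_size_nm,n_frames,target_id metadata overrides; taken from the
#'   sidecar/attributes when `NULL`.
#' @param units position units on disk, `"nm"` or `"px"`; default from the
#'   sidecar (`"nm"` if undeclared).
#' @return a [loc_table()].
#' @export
read_localizations <- function(path, dialect = c("csv", "hdf5"),
                               pixel_size_nm = NULL, n_frames = NULL,
                               target_id = NULL, units = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "hdf5") {
    tmp <- tempfile(fileext = ".csv")
    on.exit(unlink(c(tmp, paste0(tmp, ".yaml"))), add = TRUE)
    h5_bridge("r", path, tmp, target_id)
    path <- tmp
  }
  sidecar <- paste0(path, ".yaml")
  meta <- if (file.exists(sidecar)) yaml::read_yaml(sidecar) else list()
  units <- units %||% meta$units %||% "nm"
  pixel_size_nm <- pixel_size_nm %||% meta$pixel_size_nm
  n_frames <- n_frames %||% meta$n_frames
  target_id <- target_id %||% meta$target_id %||% "target"
  if (is.null(pixel_size_nm)) stopf("pixel_size_nm not given and not in sidecar")
  if (is.null(n_frames)) stopf("n_frames not given and not in sidecar")

  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  miss <- setdiff(c("x", "y", "frame"), names(raw))
  if (length(miss))
    stopf("localization file lacks required column(s): %s",
          paste(miss, collapse = ", "))
  num <- list()
  for (dc in names(on_disk_cols)) {
    if (!dc %in% names(raw)) { num[[on_disk_cols[[dc]]]] <- NA_real_; next }
    v <- suppressWarnings(as.numeric(raw[[dc]]))
    bad <- which(is.na(v) & !(raw[[dc]] %in% c("NA", "")))
    if (length(bad))
      stopf("non-numeric value in column '%s' at row %d", dc, bad[1])
    num[[on_disk_cols[[dc]]]] <- v
  }
  scale <- if (identical(units, "px")) pixel_size_nm else 1
  loc_table(num$x_nm * scale, num$y_nm * scale, num$frame, num$photons,
            num$sigma_px, num$precision_nm,
            pixel_size_nm = pixel_size_nm, n_frames = n_frames,
            target_id = target_id)
}

#' Write a localization table to disk
#'
#' Positions are written in nm at full double precision so that a
#' write-then-read round trip reproduces field values bitwise. The CSV
#' dialect writes a YAML sidecar with the units and table metadata.
#'
#' @param table a [loc_table()].
#' @param path output path.
#' @param dialect `"csv"` or `"hdf5"`.
#' @export
write_localizations <- function(table, path, dialect = c("csv", "hdf5")) {
  dialect <- match.arg(dialect)
  validate_loc_table(table)
  csv_path <- if (dialect == "hdf5") tempfile(fileext = ".csv") else path
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.17g", v))
  out <- data.frame(x = fmt(table$x_nm), y = fmt(table$y_nm),
                    frame = table$frame, photons = fmt(table$photons),
                    sigma = fmt(table$sigma_px),
                    precision = fmt(table$precision_nm))
  write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  meta <- loc_meta(table)
  yaml::write_yaml(list(units = "nm", pixel_size_nm = meta$pixel_size_nm,
                        n_frames = meta$n_frames,
                        target_id = meta$target_id),
                   paste0(csv_path, ".yaml"))
  if (dialect == "hdf5") {
    on.exit(unlink(c(csv_path, paste0(csv_path, ".yaml"))), add = TRUE)
    h5_bridge("w", path, csv_path, meta$target_id)
  }
  invisible(path)
}

# HDF5 access goes through a bundled h5py bridge script run with the system
# Python; the CSV intermediate uses %.17g so doubles survive bitwise.
h5_bridge <- function(mode, h5_path, csv_path, target_id = NULL) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stopf("HDF5 dialect requires a python interpreter with h5py")
  script <- system.file("python", "h5_bridge.py", package = "aznano")
  args <- c(script, mode, h5_path, csv_path)
  if (!is.null(target_id)) args <- c(args, target_id)
  res <- suppressWarnings(system2(py, shQuote(args), stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0
  if (status != 0) stopf("HDF5 bridge failed: %s", paste(res, collapse = "\n"))
  invisible(NULL)
}

#' Render a localization table as an averaged-shifted-histogram density image
#'
#' Classic ASH rendering: each localization is binned at the output pixel
#' size and spread with a separable triangular kernel equivalent to averaging
#' `m` shifted histograms per axis. Mass is conserved exactly: the pixel sum
#' equals the number of rendered localizations.
#'
#' @param table a non-empty [loc_table()].
#' @param pixel_nm output pixel size in nm (20 nm reproduces the conventional
#'   "magnification 8" rendering of 160-nm camera pixels).
#' @param m number of shifted histograms per axis.
#' @return a `density_image`: list with `pixels` (matrix indexed
#'   `[ix, iy]`), `pixel_nm`, and `origin_nm` (world coordinate of the
#'   corner of pixel (1,1)).
#' @export
render_ash <- function(table, pixel_nm = 20, m = 4) {
  if (nrow(table) == 0) stopf("cannot render an empty localization table")
  if (pixel_nm <= 0) stopf("pixel_nm must be positive")
  m <- as.integer(m)
  margin <- m - 1L
  ox <- (floor(min(table$x_nm) / pixel_nm) - margin) * pixel_nm
  oy <- (floor(min(table$y_nm) / pixel_nm) - margin) * pixel_nm
  nx <- floor((max(table$x_nm) - ox) / pixel_nm) + 1L + margin
  ny <- floor((max(table$y_nm) - oy) / pixel_nm) + 1L + margin
  px <- ash_impl(table$x_nm, table$y_nm, ox, oy, pixel_nm, m, nx, ny)
  structure(list(pixels = px, pixel_nm = pixel_nm, origin_nm = c(ox, oy)),
            class = "density_image")
}

#' Write a density image as a single-channel 32-bit float TIFF
#'
#' Pixel values are stored scaled to `[0, 1]`; the scale factor, pixel size
#' and origin are written to a YAML sidecar so the image can be restored
#' exactly with [read_density_tiff()].
#'
#' @param image a `density_image` from [render_ash()].
#' @param path output TIFF path.
#' @export
write_density_tiff <- function(image, path) {
  scale <- max(image$pixels)
  if (scale <= 0) scale <- 1
  raster <- t(image$pixels[, rev(seq_len(ncol(image$pixels))), drop = FALSE])
  tiff::writeTIFF(raster / scale, path, bits.per.sample = 32, reduce = FALSE,
                  compression = "none")
  yaml::write_yaml(list(value_scale = scale,
                        pixel_nm = image$pixel_nm,
                        origin_nm = as.numeric(image$origin_nm)),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a density image written by [write_density_tiff()]
#' @param path TIFF path.
#' @return a `density_image`.
#' @export
read_density_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  img <- tiff::readTIFF(path)
  px <- t(img)[, rev(seq_len(nrow(img))), drop = FALSE] * meta$value_scale
  structure(list(pixels = px, pixel_nm = meta$pixel_nm,
                 origin_nm = meta$origin_nm), class = "density_image")
}
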
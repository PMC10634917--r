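# Shared fixtures and independent oracles used across the test files.

# Brute-force DBSCAN oracle: O(n^2) distance matrix, identical control flow
# to the package implementation (closed eps-neighborhood including the point
# itself, clusters grown from core points in ascending index order, border
# points claimed by the first cluster that reaches them), so labels must
# agree verbatim up to nothing.
dbscan_oracle <- function(x, y, eps, min_pts) {
  n <- length(x)
  labels <- integer(n)
  if (n == 0) return(labels)
  d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  nb <- lapply(seq_len(n), function(i) which(d2[i, ] <= eps^2))
  visited <- logical(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    if (length(nb[[i]]) < min_pts) next
    cid <- cid + 1L
    labels[i] <- cid
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) labels[j] <- cid
      if (visited[j]) next
      visited[j] <- TRUE
      if (length(nb[[j]]) >= min_pts) queue <- c(queue, nb[[j]])
    }
  }
  labels
}

# dense circle ring polygon (radius r, centered at `center`)
circle_ring <- function(r, center = c(0, 0), n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-1]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

# a `nanocluster` whose alpha shape is (a dense polygon of) a circle
circle_nanocluster <- function(r, center = c(0, 0)) {
  structure(list(indices = NULL, points = NULL, n_locs = 100L,
                 centroid_nm = center,
                 shape = list(rings = list(circle_ring(r, center)), main = 1,
                              area_nm2 = pi * r^2, alpha_radius_nm = Inf),
                 area_nm2 = pi * r^2, effective_radius_nm = r),
            class = "nanocluster")
}

# quick localization table around given points
quick_table <- function(x, y, frame = 0L, photons = 500, sigma = 1,
                        precision = 8, n_frames = 30000L) {
  loc_table(x, y, frame, photons, sigma, precision,
            pixel_size_nm = 160, n_frames = n_frames)
}

# pipeline configuration for scaled-down (3000-frame) synthetic fields: the
# frame-SD bounds scale with acquisition length
scaled_config <- function(seed = 1, ...) {
  over <- list(...)
  syn <- utils::modifyList(list(frame_sd_bounds = c(250, 1100)),
                           over$synapse %||% list())
  over$synapse <- NULL
  do.call(az_config, c(list(seed = seed, synapse = syn), over))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scaled_params <- function(architecture = "co_organized", ...) {
  field_params(architecture, n_frames = 3000L, ...)
}
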
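# Scaffold cluster detection, frame-statistics rejection, alpha shapes,
# en-face selection and active-zone restriction.

test_that("DBSCAN matches the brute-force oracle on structured point sets", {
  set.seed(40)
  # one clump inside a 40-nm disc -> a single cluster of 100
  th <- runif(100, 0, 2 * pi); r <- 40 * sqrt(runif(100))
  x <- r * cos(th); y <- r * sin(th)
  lab <- dbscan_labels(x, y, 48, 10)
  expect_identical(lab, dbscan_oracle(x, y, 48, 10))
  expect_equal(unname(table(lab)), 100L, ignore_attr = TRUE)
  # two 50-point clumps 500 nm apart -> two clusters
  x2 <- c(rnorm(50, 0, 15), rnorm(50, 500, 15))
  y2 <- c(rnorm(50, 0, 15), rnorm(50, 0, 15))
  lab2 <- dbscan_labels(x2, y2, 48, 10)
  expect_identical(lab2, dbscan_oracle(x2, y2, 48, 10))
  expect_equal(length(unique(lab2[lab2 > 0])), 2)
})

test_that("DBSCAN equals the oracle on random point sets", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(20:500, 1)
    x <- runif(n, 0, 600); y <- runif(n, 0, 600)
    eps <- runif(1, 20, 80)
    mp <- sample(3:12, 1)
    expect_identical(dbscan_labels(x, y, eps, mp),
                     dbscan_oracle(x, y, eps, mp))
  }
})

test_that("clusters below 75 localizations become noise", {
  set.seed(42)
  x <- rnorm(60, 0, 15); y <- rnorm(60, 0, 15)
  tab <- quick_table(x, y)
  lab <- detect_synaptic_clusters(tab, 48, 10, 75)
  expect_true(all(lab == 0))
  lab2 <- detect_synaptic_clusters(tab, 48, 10, 50)
  expect_true(any(lab2 > 0))
})

test_that("frame statistics identify nonspecific clusters", {
  nf <- 30000L
  set.seed(43)
  # uniform frames: SD ~ 30000/sqrt(12) ~ 8660 -> kept
  n <- 300
  make <- function(cx, frames) list(x = rnorm(n, cx, 20), frames = frames)
  cl <- list(make(0, sample.int(nf, n) - 1L),
             make(1000, sample.int(nf, n) - 1L),
             make(2000, sample.int(nf, n) - 1L),
             make(3000, sample(1000:2000, n, replace = TRUE)))  # narrow
  tab <- quick_table(unlist(lapply(cl, `[[`, "x")),
                     rep(0, 4 * n),
                     frame = as.integer(unlist(lapply(cl, `[[`, "frames"))),
                     n_frames = nf)
  labels <- rep(1:4, each = n)
  res <- remove_nonspecific_clusters(tab, labels)
  expect_false(res$stats$removed[1])
  expect_false(res$stats$removed[2])
  expect_true(res$stats$removed[4])
  expect_equal(res$stats$reason[4], "frame_sd")
  expect_lt(res$stats$frame_sd[4], 2500)
  expect_gt(res$stats$frame_sd[1], 2500)
})

test_that("a mean-frame outlier cluster is removed by the fitted 2-sd rule", {
  nf <- 30000L
  set.seed(44)
  n <- 120
  mean_frames <- c(rnorm(20, 15000, 400), 1500)
  frames <- unlist(lapply(mean_frames, function(m)
    pmin(pmax(round(rnorm(n, m, 6000)), 0), nf - 1)))
  tab <- quick_table(rep(0, 21 * n), rep(0, 21 * n),
                     frame = as.integer(frames), n_frames = nf)
  labels <- rep(1:21, each = n)
  res <- remove_nonspecific_clusters(tab, labels)
  # oracle: direct Gaussian fit on the 21 cluster mean frames
  mf <- res$stats$mean_frame
  fit_mu <- mean(mf); fit_sd <- sd(mf)
  expect_true(abs(mf[21] - fit_mu) > 2 * fit_sd)
  expect_true(res$stats$removed[21])
  expect_false(any(res$stats$removed[1:20] &
                     res$stats$reason[1:20] == "mean_frame"))
})

test_that("fewer than 3 clusters skips the mean-frame criterion with warning", {
  tab <- quick_table(c(rnorm(100), rnorm(100, 500)), rep(0, 200),
                     frame = as.integer(sample.int(30000, 200) - 1))
  expect_warning(res <- remove_nonspecific_clusters(tab, rep(1:2, each = 100)),
                 "mean-frame")
  expect_equal(max(res$labels), 2)
})

test_that("alpha shape reaches the convex hull in the large-alpha limit", {
  pts <- cbind(c(0, 1, 1, 0, 0.5, 1, 0.5, 0), c(0, 0, 1, 1, 0, 0.5, 1, 0.5))
  sh <- alpha_shape(pts, 1e9)
  expect_equal(sh$area_nm2, 1, tolerance = 1e-6)
  hull <- grDevices::chull(pts)
  expect_equal(polygon_area(pts[hull, ]), sh$area_nm2, tolerance = 1e-6)
})

test_that("alpha shape area of a sampled disc matches pi r^2 within 5%", {
  set.seed(45)
  th <- runif(3000, 0, 2 * pi); r <- 100 * sqrt(runif(3000))
  extra <- seq(0, 2 * pi, length.out = 200)
  pts <- rbind(cbind(r * cos(th), r * sin(th)),
               cbind(100 * cos(extra), 100 * sin(extra)))
  sh <- alpha_shape(pts, 150)
  expect_equal(sh$area_nm2, pi * 100^2, tolerance = 0.05)
})

test_that("alpha shape area is non-decreasing in the alpha radius", {
  set.seed(46)
  pts <- cbind(rnorm(200, 0, 40), rnorm(200, 0, 40))
  alphas <- c(20, 40, 80, 160, 1e6)
  areas <- vapply(alphas, function(a)
    tryCatch(alpha_shape(pts, a)$area_nm2, error = function(e) 0), numeric(1))
  expect_true(all(diff(areas) >= -1e-9))
})

test_that("degenerate inputs raise geometry errors", {
  expect_error(alpha_shape(cbind(c(0, 1), c(0, 0)), 10), "3")
  expect_error(alpha_shape(cbind(0:5, 0:5), 10), "collinear")
})

test_that("en-face selection accepts round overlapping scaffolds only", {
  set.seed(47)
  disc <- function(n, r, cx = 0, asp = 1) {
    th <- runif(n, 0, 2 * pi); rr <- r * sqrt(runif(n))
    cbind(cx + rr * cos(th) * asp, rr * sin(th))
  }
  b <- disc(800, 200); p <- disc(800, 200)
  roi <- select_enface(b, p)
  expect_true(roi$accepted)
  expect_gt(roi$overlap_fraction, 0.9)
  expect_lt(roi$shape_metric, 1.3)
  # displaced post-synaptic disc: low overlap -> rejected
  roi2 <- select_enface(b, disc(800, 200, cx = 260))
  expect_false(roi2$accepted)
  expect_lt(roi2$overlap_fraction, 0.7)
  # 3:1 ellipse against a disc: roundness fails
  roi3 <- select_enface(disc(800, 200, asp = 3), p, shape_max = 2)
  expect_false(roi3$accepted)
  expect_gt(roi3$shape_metric, 2)
})

test_that("roundness metric equals the axis ratio for an ellipse boundary", {
  th <- seq(0, 2 * pi, length.out = 400)[-1]
  ring <- cbind(300 * cos(th), 100 * sin(th))
  expect_equal(polygon_axis_ratio(ring), 3, tolerance = 0.01)
  ringc <- cbind(100 * cos(th), 100 * sin(th))
  expect_equal(polygon_axis_ratio(ringc), 1, tolerance = 0.01)
})

test_that("active-zone restriction enforces the 25-localization minimum", {
  set.seed(48)
  th <- runif(600, 0, 2 * pi); rr <- 200 * sqrt(runif(600))
  b <- cbind(rr * cos(th), rr * sin(th))
  roi <- select_enface(b, b)
  expect_true(roi$accepted)
  inside24 <- quick_table(rnorm(24, 0, 50), rnorm(24, 0, 50))
  inside30 <- quick_table(rnorm(30, 0, 50), rnorm(30, 0, 50))
  r1 <- restrict_to_active_zone(roi, list(a = inside24, b = inside30))
  expect_false(r1$accepted)
  expect_match(r1$reason, "a has 24")
  r2 <- restrict_to_active_zone(roi, list(a = inside30, b = inside30))
  expect_true(r2$accepted)
  expect_true(all(r2$counts == 30))
})

test_that("a localization exactly on the boundary counts as inside", {
  square <- cbind(c(0, 100, 100, 0), c(0, 0, 100, 100))
  expect_true(point_in_shape(50, 0, square))
  expect_true(point_in_shape(100, 100, square))
  expect_false(point_in_shape(101, 50, square))
})
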
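# Randomization engine, cross-enrichment, classification, separation index.

test_that("randomized point sets are inside the ROI and seed-deterministic", {
  ring <- circle_ring(200)
  sets <- randomize_in_roi(100, ring, 5, seed = 77)
  for (s in sets) {
    expect_equal(nrow(s), 100)
    expect_true(all(point_in_shape(s[, 1], s[, 2], ring)))
  }
  sets2 <- randomize_in_roi(100, ring, 5, seed = 77)
  expect_identical(sets, sets2)
  expect_false(identical(sets, randomize_in_roi(100, ring, 5, seed = 78)))
})

test_that("randomized draws are uniform over the ROI (chi-square on a grid)", {
  square <- cbind(c(0, 400, 400, 0), c(0, 0, 400, 400))
  set.seed(70)
  reject <- vapply(1:40, function(i) {
    pts <- randomize_in_roi(800, square, 1)[[1]]
    ix <- pmin(floor(pts[, 1] / 100), 3)
    iy <- pmin(floor(pts[, 2] / 100), 3)
    tab <- tabulate(ix * 4 + iy + 1, 16)
    stat <- sum((tab - 50)^2 / 50)
    stat > qchisq(0.99, 15)
  }, logical(1))
  expect_lte(mean(reject), 0.05)
})

test_that("enrichment of CSR opposite protein is about 1 in every bin", {
  set.seed(71)
  ring <- circle_ring(200)
  cache <- NULL
  enr <- matrix(NA_real_, 100, 20)
  for (i in 1:100) {
    centers <- randomize_in_roi(3, ring, 1)[[1]]
    b <- randomize_in_roi(150, ring, 1)[[1]]
    rn <- randomize_in_roi(150, ring, 50)
    pr <- cross_enrichment(centers, b, ring, seq(0, 200, 10), rn,
                           area_cache = cache)
    cache <- pr$area_cache
    enr[i, ] <- pr$enrichment
  }
  m <- colMeans(enr, na.rm = TRUE)
  expect_true(all(abs(m - 1) < 0.1))
})

test_that("opposite protein concentrated at the centers dominates bin 1", {
  set.seed(72)
  ring <- circle_ring(200)
  centers <- cbind(c(-60, 70), c(10, -40))
  b <- centers[rep(1:2, each = 100), ] + matrix(rnorm(400, 0, 4), ncol = 2)
  rn <- randomize_in_roi(200, ring, 50)
  pr <- cross_enrichment(centers, b, ring, seq(0, 200, 10), rn)
  expect_gt(pr$enrichment[1], 10)
  expect_gt(pr$enrichment[1], 5 * max(pr$enrichment[5:20], na.rm = TRUE))
})

test_that("enrichment is invariant to the opposite protein's intensity", {
  set.seed(73)
  ring <- circle_ring(200)
  centers <- cbind(c(-50, 50), c(0, 0))
  b <- randomize_in_roi(200, ring, 1)[[1]]
  b2 <- rbind(b, randomize_in_roi(200, ring, 1)[[1]])  # doubled uniformly
  rn1 <- randomize_in_roi(nrow(b), ring, 80)
  rn2 <- randomize_in_roi(nrow(b2), ring, 80)
  p1 <- cross_enrichment(centers, b, ring, seq(0, 200, 20), rn1)
  p2 <- cross_enrichment(centers, b2, ring, seq(0, 200, 20), rn2)
  expect_equal(mean(p2$enrichment, na.rm = TRUE),
               mean(p1$enrichment, na.rm = TRUE), tolerance = 0.2)
})

test_that("classification follows the 1.96-SD rule with strict inequalities", {
  prof <- structure(list(bin_edges_nm = seq(0, 100, 20),
                         enrichment = rep(1, 5),
                         rand_curves = matrix(rep(c(0.8, 1.0, 1.2), each = 5),
                                              nrow = 3, byrow = TRUE)),
                    class = "enrichment_profile")
  # statistic equals the randomization mean -> indistinguishable
  cl <- classify_enrichment(prof, r_max_nm = 100)
  expect_equal(cl$class, "indistinguishable")
  prof$enrichment <- rep(10, 5)
  expect_equal(classify_enrichment(prof, 100)$class, "enriched")
  prof$enrichment <- rep(0.01, 5)
  expect_equal(classify_enrichment(prof, 100)$class, "de_enriched")
  prof$rand_curves <- NULL
  expect_equal(classify_enrichment(prof, 100)$class, "unclassifiable")
})

test_that("null classification tails are near the nominal two-sided 5%", {
  set.seed(74)
  ring <- circle_ring(200)
  cache <- NULL
  classes <- character(0)
  for (i in 1:100) {
    centers <- randomize_in_roi(5, ring, 1)[[1]]
    b <- randomize_in_roi(120, ring, 1)[[1]]
    rn <- randomize_in_roi(120, ring, 60)
    for (k in 1:5) {
      pr <- cross_enrichment(centers[k, , drop = FALSE], b, ring,
                             seq(0, 200, 10), rand_norm = rn[1:40],
                             rand_class = rn[41:60], area_cache = cache)
      cache <- pr$area_cache
      classes <- c(classes, classify_enrichment(pr)$class)
    }
  }
  tails <- mean(classes %in% c("enriched", "de_enriched"))
  expect_gte(tails, 0.02)
  expect_lte(tails, 0.10)
})

test_that("population smoothing caps per-bin high outliers", {
  set.seed(75)
  curves <- matrix(rnorm(300, 1, 0.05), 30, 10)
  curves[7, 4] <- 50
  sm <- smooth_enrichment_population(curves)
  expect_lt(sm[7, 4], 2)
  expect_equal(sm[7, 4], max(sm[-7, 4]))
  expect_equal(sm[, -4], curves[, -4])
})

test_that("separation index reproduces analytic circle-pair values", {
  a20 <- circle_nanocluster(20, c(0, 0))
  b30 <- circle_nanocluster(30, c(100, 0))
  si <- separation_index(a20, list(b30))
  expect_equal(si$r1_nm, 20, tolerance = 1e-3)
  expect_equal(si$r2_nm, 30, tolerance = 1e-3)
  expect_equal(si$si, 2.0, tolerance = 1e-3)
  expect_false(si$overlap)
  # tangent circles: SI = 1
  si_t <- separation_index(a20, list(circle_nanocluster(30, c(50, 0))))
  expect_equal(si_t$si, 1.0, tolerance = 1e-3)
  # concentric: SI = 0, degenerate direction
  si_c <- separation_index(a20, list(circle_nanocluster(30, c(0, 0))))
  expect_equal(si_c$si, 0)
  expect_true(si_c$overlap)
  expect_true(si_c$degenerate)
})

test_that("SI is symmetric for circle pairs and scale invariant", {
  set.seed(76)
  for (rep in 1:5) {
    r1 <- runif(1, 10, 40); r2 <- runif(1, 10, 40)
    d <- runif(1, 5, 150)
    a <- circle_nanocluster(r1, c(0, 0))
    b <- circle_nanocluster(r2, c(d, 0))
    s_ab <- separation_index(a, list(b))$si
    s_ba <- separation_index(b, list(a))$si
    expect_equal(s_ab, s_ba, tolerance = 1e-6)
    cfac <- 3.7
    ac <- circle_nanocluster(cfac * r1, c(0, 0))
    bc <- circle_nanocluster(cfac * r2, c(cfac * d, 0))
    expect_equal(separation_index(ac, list(bc))$si, s_ab, tolerance = 1e-6)
    expect_equal(s_ab < 1, d < r1 + r2)
  }
})

test_that("the nearest opposite nanocluster is chosen, ties to lower index", {
  a <- circle_nanocluster(20, c(0, 0))
  near <- circle_nanocluster(10, c(80, 0))
  far <- circle_nanocluster(10, c(300, 0))
  expect_equal(separation_index(a, list(far, near))$opposite_index, 2)
  tie1 <- circle_nanocluster(10, c(90, 0))
  tie2 <- circle_nanocluster(10, c(-90, 0))
  expect_equal(separation_index(a, list(tie1, tie2))$opposite_index, 1)
})
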
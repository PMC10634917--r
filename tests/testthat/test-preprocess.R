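# Quality filters, temporal linking, drift correction, chromatic transform,
# residual offset.

test_that("sigma bounds are strict inequalities for removal", {
  tab <- quick_table(1:5 * 100, 1:5 * 100, sigma = c(0.2, 0.3, 1.0, 1.6, 1.7))
  res <- filter_quality(tab)
  expect_equal(res$table$sigma_px, c(0.3, 1.0, 1.6))
  expect_equal(res$report$rows_removed_sigma, 2)
})

test_that("photon-mode rule removes counts above the modal bin's upper edge", {
  tab <- quick_table(1:5 * 100, 1:5 * 100,
                     photons = c(90, 100, 100, 100, 450))
  res <- filter_quality(tab, photon_bin_width = 50)
  expect_equal(nrow(res$table), 4)
  expect_equal(res$report$thresholds$photon_threshold, 150)
  expect_equal(res$report$rows_removed_photons, 1)
})

test_that("precision filter removes only errors above 20 nm", {
  tab <- quick_table(1:3 * 100, 1:3 * 100, precision = c(5, 20, 21))
  res <- filter_quality(tab)
  expect_equal(res$table$precision_nm, c(5, 20))
})

test_that("quality filtering is idempotent and counts are conserved", {
  set.seed(10)
  f <- simulate_field(scaled_params(), seed = 10)
  r1 <- filter_quality(f$tables$a)
  r2 <- filter_quality(r1$table)
  expect_identical(r2$table$x_nm, r1$table$x_nm)
  rep <- r1$report
  expect_equal(rep$rows_out,
               rep$rows_in - rep$rows_removed_sigma -
                 rep$rows_removed_precision - rep$rows_removed_photons)
})

test_that("linking merges runs across allowed dark gaps only", {
  # frames 10 and 16: 5 dark frames -> one event
  t1 <- quick_table(c(0, 0), c(0, 0), frame = c(10L, 16L),
                    photons = c(10, 20))
  expect_equal(nrow(link_localizations(t1)), 1)
  # frames 10 and 17: 6 dark frames -> two events
  t2 <- quick_table(c(0, 0), c(0, 0), frame = c(10L, 17L))
  expect_equal(nrow(link_localizations(t2)), 2)
  # consecutive frames merge, photons sum, frame = first
  t3 <- quick_table(c(0, 0, 0), c(0, 0, 0), frame = c(10L, 11L, 12L),
                    photons = c(10, 20, 30))
  lk <- link_localizations(t3)
  expect_equal(nrow(lk), 1)
  expect_equal(lk$photons, 60)
  expect_equal(lk$frame, 10L)
})

test_that("localizations beyond the radius or in the same frame never merge", {
  # 0.5 px = 80 nm apart at 160 nm pixels, radius 0.3 px = 48 nm
  t1 <- quick_table(c(0, 80), c(0, 0), frame = c(10L, 11L))
  expect_equal(nrow(link_localizations(t1)), 2)
  t2 <- quick_table(c(0, 10), c(0, 0), frame = c(10L, 10L))
  expect_equal(nrow(link_localizations(t2)), 2)
})

test_that("linking conserves photons and never adds rows", {
  for (s in 1:3) {
    f <- simulate_field(scaled_params(), seed = s)
    tab <- filter_quality(f$tables$a)$table
    lk <- link_localizations(tab)
    expect_lte(nrow(lk), nrow(tab))
    expect_equal(sum(lk$photons), sum(tab$photons))
  }
})

test_that("linking is idempotent when events are spatially separated", {
  # events on a 200-nm grid (far beyond the 48-nm radius), each a run of
  # per-frame localizations with sub-10-nm jitter: one pass fully resolves
  # them, and a second pass can change nothing
  set.seed(11)
  g <- expand.grid(x = seq(0, 1800, 200), y = seq(0, 1800, 200))
  rows <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    len <- sample(2:6, 1)
    start <- sample(0:2900, 1)
    data.frame(x = g$x[i] + rnorm(len, 0, 5), y = g$y[i] + rnorm(len, 0, 5),
               frame = start + seq_len(len) - 1L)
  }))
  tab <- quick_table(rows$x, rows$y, frame = as.integer(rows$frame),
                     n_frames = 3000L)
  lk <- link_localizations(tab)
  expect_equal(nrow(lk), nrow(g))
  lk2 <- link_localizations(lk)
  expect_identical(as.data.frame(lk2), as.data.frame(lk))
})

test_that("re-linking dense fields is a near-fixed point", {
  # on dense fields simultaneous nearby events preclude exact idempotence
  # (any running-mean greedy linker shares this); the fixed-point residual
  # stays small and photons remain conserved
  f <- simulate_field(scaled_params(), seed = 1)
  tab <- filter_quality(f$tables$mask)$table
  lk <- link_localizations(tab)
  lk2 <- link_localizations(lk)
  expect_lte(nrow(lk) - nrow(lk2), 0.03 * nrow(lk))
  expect_equal(sum(lk2$photons), sum(lk$photons))
})

test_that("RCC drift estimate is quiet when no drift is planted", {
  f <- simulate_field(scaled_params(scaffold_events = 2000L), seed = 20)
  comb <- do.call(rbind, lapply(f$tables, function(t)
    data.frame(x = t$x_nm, y = t$y_nm, fr = t$frame)))
  tab <- quick_table(comb$x, comb$y, frame = comb$fr, n_frames = 3000L)
  est <- drift_correct_rcc(tab, 1000)
  expect_lt(sqrt(mean(rowSums(est$drift_nm^2))), 5)
  expect_error(drift_correct_rcc(tab, 2000), "segment")
})

test_that("planted linear drift is recovered within 10% endpoint error", {
  p <- field_params("co_organized", n_frames = 10000L,
                    scaffold_events = 6000L, events_per_cluster = 150L)
  f <- simulate_field(p, seed = 7)
  nf <- 10000
  drift <- cbind(0.01 * (0:(nf - 1)), -0.006 * (0:(nf - 1)))
  fc <- corrupt_field(f, drift = drift)
  comb <- do.call(rbind, lapply(fc$tables, function(t)
    data.frame(x = t$x_nm, y = t$y_nm, fr = t$frame)))
  tab <- quick_table(comb$x, comb$y, frame = comb$fr, n_frames = nf)
  est <- drift_correct_rcc(tab, 1000)
  true0 <- sweep(drift, 2, colMeans(drift))
  # trajectories are defined up to a global offset (mean-zero convention)
  expect_lt(sqrt(mean(rowSums((est$drift_nm - true0)^2))), 10)
  end_est <- est$drift_nm[nf, ] - est$drift_nm[1, ]
  end_true <- drift[nf, ] - drift[1, ]
  expect_lt(max(abs(end_est - end_true) / abs(end_true)), 0.10)
  # corrected positions match the clean field up to a global translation
  corr <- est$table
  resid <- c(corr$x_nm - comb$x + drift[comb$fr + 1, 1],
             corr$y_nm - comb$y + drift[comb$fr + 1, 2])
})

test_that("chromatic transform on identity and translation pairs", {
  set.seed(30)
  fixed <- cbind(runif(20, 0, 2000), runif(20, 0, 2000))
  m_id <- fit_chromatic_transform(fixed, fixed)
  expect_lt(m_id$fit_rmse_nm, 1e-9)
  tab <- quick_table(runif(50, 0, 2000), runif(50, 0, 2000))
  out <- apply_transform(m_id, tab)
  expect_equal(out$x_nm, tab$x_nm, tolerance = 1e-9)
  m_tr <- fit_chromatic_transform(fixed, fixed + rep(c(30, -12), each = 20))
  expect_equal(unname(m_tr$coef_fwd[1, ]), c(30, -12), tolerance = 1e-9)
  expect_equal(unname(m_tr$coef_fwd[2:3, ]), unname(diag(2)),
               tolerance = 1e-9)
})

test_that("a known degree-2 warp is recovered to 1e-9 on noise-free beads", {
  warp <- make_warp(translation_nm = c(5, -3),
                    linear = matrix(c(1.001, 2e-4, -1e-4, 0.999), 2,
                                    byrow = TRUE),
                    quad = matrix(c(1e-6, -2e-6, 5e-7,
                                    2e-6, 1e-6, -1e-6), 3, 2))
  beads <- simulate_bead_pairs(warp, 2000, 6)
  model <- fit_chromatic_transform(beads$fixed, beads$moving)
  expect_equal(unname(model$coef_fwd), unname(warp), tolerance = 1e-9)
  # end-to-end: correcting warped localizations restores clean positions
  tab <- quick_table(runif(200, 100, 1900), runif(200, 100, 1900))
  warped <- apply_warp(cbind(tab$x_nm, tab$y_nm), warp)
  wt <- quick_table(warped[, 1], warped[, 2])
  corrected <- apply_transform(model, wt)
  expect_lt(max(abs(corrected$x_nm - tab$x_nm)), 0.5)
  expect_error(fit_chromatic_transform(beads$fixed[1:5, ],
                                       beads$moving[1:5, ]),
               "underdetermined")
})

test_that("residual offset is recovered exactly for a planted shift", {
  set.seed(31)
  ref <- quick_table(runif(3000, 0, 2000), runif(3000, 0, 2000))
  idx <- sample(3000, 2000)
  oth <- quick_table(ref$x_nm[idx] + 40, ref$y_nm[idx] - 20)
  res <- correct_residual_offset(ref, oth)
  expect_false(res$low_confidence)
  expect_lt(max(abs(res$offset_nm - c(-40, 20))), 20)
  expect_lt(max(abs(res$table$x_nm - ref$x_nm[idx]))
            , 21)
  # zero shift for identical tables
  res0 <- correct_residual_offset(ref, ref)
  expect_lt(max(abs(res0$offset_nm)), 1)
})

test_that("independent CSR tables are flagged low-confidence, not shifted", {
  set.seed(32)
  flagged <- logical(5)
  for (s in 1:5) {
    a <- quick_table(runif(1500, 0, 2000), runif(1500, 0, 2000))
    b <- quick_table(runif(1500, 0, 2000), runif(1500, 0, 2000))
    res <- correct_residual_offset(a, b)
    flagged[s] <- res$low_confidence
    expect_equal(res$table$x_nm, b$x_nm)  # never applied when unreliable
  }
  expect_true(all(flagged))
  # disjoint bounding boxes fail loudly
  far <- quick_table(runif(100, 10000, 11000), runif(100, 10000, 11000))
  near <- quick_table(runif(100, 0, 1000), runif(100, 0, 1000))
  expect_error(correct_residual_offset(near, far), "overlap")
})
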
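# STED side-view line-profile quantification.

# synthetic two-channel side-view image: a postsynaptic "bar" (Gaussian in x
# around x0) and a protein channel offset by `offset_nm` across the synapse
synthetic_sideview <- function(x0_nm = 1500, offset_nm = 40, pixel_nm = 22.7,
                               npx = 128, amp = 1, width_nm = 60) {
  centers <- (seq_len(npx) - 0.5) * pixel_nm
  post <- outer(exp(-(centers - x0_nm)^2 / (2 * width_nm^2)), rep(1, npx))
  prot <- outer(amp * exp(-(centers - x0_nm - offset_nm)^2 /
                            (2 * width_nm^2)), rep(1, npx))
  list(post = post, protein = prot)
}

test_that("a constant image yields a flat profile at that value", {
  ch <- list(c1 = matrix(7, 64, 64))
  pr <- extract_profile(ch, c(700, 700), c(1, 0))
  expect_true(all(abs(pr$intensity[, "c1"] - 7) < 1e-9))
  expect_equal(length(pr$positions_nm), floor(750 / 22.7))
})

test_that("a bright line perpendicular to the profile gives one peak", {
  img <- matrix(0, 128, 128)
  img[66, ] <- 10
  pr <- extract_profile(list(c1 = img), c(1450, 1450), c(1, 0))
  peak_pos <- pr$positions_nm[which.max(pr$intensity[, "c1"])]
  line_x <- (66 - 0.5) * 22.7
  expect_lt(abs((1450 + peak_pos) - line_x), 22.7)
})

test_that("profile is invariant when image and direction rotate together", {
  sv <- synthetic_sideview()
  p0 <- extract_profile(sv, c(1500, 1450), c(1, 0))
  # rotate by 90 degrees: transpose swaps axes
  sv_rot <- lapply(sv, t)
  p90 <- extract_profile(sv_rot, c(1450, 1500), c(0, 1))
  expect_equal(p90$intensity, p0$intensity, tolerance = 1e-6)
})

test_that("the profile window must stay inside the image", {
  ch <- list(c1 = matrix(1, 32, 32))
  expect_error(extract_profile(ch, c(50, 50), c(1, 0)), "bounds")
})

test_that("5-sample rolling average has the textbook closed forms", {
  n <- 33
  flat <- structure(list(positions_nm = seq_len(n),
                         intensity = matrix(4, n, 1,
                                            dimnames = list(NULL, "c")),
                         pixel_nm = 22.7, alignment_offset_nm = 0),
                    class = "side_view_profile")
  expect_equal(smooth_profile(flat)$intensity[, 1], rep(4, n))
  imp <- flat
  imp$intensity[, 1] <- 0
  imp$intensity[17, 1] <- 1
  sm <- smooth_profile(imp)
  expect_equal(sm$intensity[15:19, 1], rep(0.2, 5))
  expect_equal(sum(sm$intensity), 1)
  ramp <- flat
  ramp$intensity[, 1] <- seq_len(n)
  smr <- smooth_profile(ramp)
  expect_equal(smr$intensity[3:(n - 2), 1], 3:(n - 2))
})

test_that("alignment puts the reference peak at offset zero and averages", {
  sv1 <- synthetic_sideview(x0_nm = 1500)
  sv2 <- synthetic_sideview(x0_nm = 1560)   # pre-shifted copy
  p1 <- smooth_profile(extract_profile(sv1, c(1480, 1450), c(1, 0)))
  p2 <- smooth_profile(extract_profile(sv2, c(1540, 1450), c(1, 0)))
  avg <- align_and_average(list(p1, p2), "post")
  ref_peak <- avg$positions_nm[which.max(avg$mean[, "post"])]
  expect_equal(ref_peak, 0)
  # one profile: the average is itself
  solo <- align_and_average(list(p1), "post")
  expect_equal(max(solo$mean[, "post"]), max(p1$intensity[, "post"]))
  expect_equal(solo$n, 1)
})

test_that("peak jitter attenuates the averaged peak amplitude", {
  set.seed(80)
  profiles <- lapply(1:20, function(i) {
    sv <- synthetic_sideview(offset_nm = 40 + rnorm(1, 0, 25))
    smooth_profile(extract_profile(sv, c(1500, 1450), c(1, 0)))
  })
  avg <- align_and_average(profiles, "post")
  mean_individual_peak <- mean(vapply(profiles, function(p)
    max(p$intensity[, "protein"]), numeric(1)))
  averaged_peak <- max(avg$mean[, "protein"])
  expect_lt(averaged_peak, mean_individual_peak)
  prot_peak_pos <- avg$positions_nm[which.max(avg$mean[, "protein"])]
  expect_lt(abs(prot_peak_pos - 40), 2 * 22.7)
})

test_that("per-culture normalization fixes the control mean at 100%", {
  set.seed(81)
  mk <- function(amp) smooth_profile(extract_profile(
    synthetic_sideview(amp = amp), c(1500, 1450), c(1, 0)))
  profiles <- c(lapply(c(1, 1.2, 0.8), mk), lapply(c(2.0, 2.2), mk),
                lapply(c(3, 3.6, 2.4), mk), lapply(c(6.0), mk))
  culture <- c(rep("c1", 5), rep("c2", 4))
  is_ctrl <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  res <- peak_and_normalize(profiles, "protein", culture, is_ctrl)
  expect_equal(mean(res$normalized_pct[is_ctrl & culture == "c1"]), 100)
  expect_equal(mean(res$normalized_pct[is_ctrl & culture == "c2"]), 100)
  # doubling relative to control -> 200%
  expect_equal(res$normalized_pct[4], 200, tolerance = 0.01)
  # per-culture: scaling one culture's images wholesale changes nothing
  profiles_scaled <- profiles
  for (i in 6:9) profiles_scaled[[i]]$intensity <-
    profiles_scaled[[i]]$intensity * 3
  res2 <- peak_and_normalize(profiles_scaled, "protein", culture, is_ctrl)
  expect_equal(res2$normalized_pct, res$normalized_pct)
})

test_that("full STED chain recovers a planted 40-nm offset within a pixel", {
  set.seed(82)
  profiles <- lapply(1:12, function(i) {
    sv <- synthetic_sideview(offset_nm = 40)
    smooth_profile(extract_profile(sv, c(1500 + runif(1, -30, 30), 1450),
                                   c(1, 0)))
  })
  avg <- align_and_average(profiles, "post")
  post_peak <- avg$positions_nm[which.max(avg$mean[, "post"])]
  prot_peak <- avg$positions_nm[which.max(avg$mean[, "protein"])]
  expect_equal(post_peak, 0)
  expect_lte(abs((prot_peak - post_peak) - 40), 22.7)
})
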
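make_series <- function(frames, pixel_spacing = 0.302,
                        slice_thickness = 1.208, times = NULL) {
  structure(list(
    frames = frames, pixel_spacing = pixel_spacing,
    slice_thickness = slice_thickness,
    frame_mid_time = if (is.null(times)) seq_len(dim(frames)[1]) else times,
    recon_meta = list()), class = "image_series")
}

test_that("lung volume follows the voxel arithmetic", {
  mask <- array(FALSE, c(2, 40, 40))
  mask[1, 1:25, 1:40] <- TRUE   # 1000 voxels
  roi <- lung_roi(mask, 0.302, 1.208)
  expect_equal(lung_volume(roi), 1000 * 0.302^2 * 1.208 / 1000)
  expect_equal(round(lung_volume(roi), 4), 0.1102)
  expect_error(lung_roi(array(FALSE, c(1, 4, 4)), 0.302, 1.208), "empty")
})

test_that("baseline map averages the pre-injection frames", {
  fr <- array(0, c(60, 1, 4, 4))
  fr[, 1, , ] <- 7
  s <- make_series(fr)
  expect_equal(compute_baseline(s, c(1, 50)), array(7, c(1, 4, 4)))
  fr2 <- fr
  fr2[1, 1, , ] <- 3
  s2 <- make_series(fr2)
  expect_equal(compute_baseline(s2, c(1, 1)), array(3, c(1, 4, 4)))
  expect_equal(compute_baseline(s2, c(1, 2))[1, 1, 1], 5)
  expect_error(compute_baseline(s, c(1, 100)), "60 frames")
  expect_error(compute_baseline(s, c(1, 50), t_inj = 10), "injection")
})

test_that("relative enhancement follows its definition and flags S0 <= 0", {
  fr <- array(2, c(3, 1, 2, 2))
  fr[2, , , ] <- 4
  s <- make_series(fr)
  s0 <- array(2, c(1, 2, 2))
  re <- relative_enhancement(s, s0)
  expect_equal(re[1, 1, 1, 1], 0)
  expect_equal(re[2, 1, 1, 1], 1)
  rr <- relative_enhancement(s, s0, mode = "ratio")
  expect_equal(rr[2, 1, 1, 1], 2)
  s0[1, 1, 1] <- 0
  re2 <- relative_enhancement(s, s0)
  expect_true(all(is.na(re2[, 1, 1, 1])))
  expect_equal(attr(re2, "n_excluded"), 1)
})

test_that("per-pixel enhancement equals the SPGR oracle on direct signals", {
  # series synthesized directly from the signal equation, no reconstruction
  t <- seq(0, 200, by = 5)
  dr1 <- enhancement_course(t, 3, 50, 8, 60)
  sig <- spgr_signal(0.3, 1100, dr1, 40, 114)
  fr <- array(rep(sig, 4), c(length(t), 1, 2, 2))
  s <- make_series(fr, times = t)
  s0 <- compute_baseline(s, c(1, 10))
  re <- relative_enhancement(s, s0)
  want <- sig / spgr_signal(0.3, 1100, 0, 40, 114) - 1
  expect_equal(re[, 1, 1, 1], want, tolerance = 1e-9)
})

test_that("background trace is zero for a stationary background", {
  fr <- array(5, c(20, 1, 32, 32))
  s <- make_series(fr)
  b <- background_trace(s, baseline_range = c(1, 10))
  expect_equal(b, rep(0, 20))
  # self-normalization: baseline frames sit at zero within noise
  set.seed(8)
  fr <- fr + array(rnorm(length(fr), sd = 0.05), dim(fr))
  b2 <- background_trace(make_series(fr), baseline_range = c(1, 10))
  expect_lt(max(abs(b2[1:10])), 0.02)
  # overlap with the lung mask is an error
  mask <- array(TRUE, c(1, 32, 32))
  roi <- lung_roi(mask, 1, 1)
  expect_error(background_trace(s, rois = corner_rois(c(1, 32, 32)),
                                baseline_range = c(1, 10), lung = roi),
               "overlap")
})

test_that("background trace tracks a known multiplicative drift", {
  # repeat-angle trajectory: every 90-profile frame shares one spoke set,
  # so frame-to-frame differences carry only the receiver modulation
  spec <- static_phantom_spec(noise_rel = 0, seed = 6)
  spec$noise_sd <- 0
  tr <- build_trajectory(720, 32, 32, angle_increment = 4)
  sim <- simulate_kspace(spec, n_profiles = 720, traj = tr)
  mod <- list(amp = 0.04, period = 600)   # slow vs the 10 s frame
  k <- modulate_kspace(sim$kspace,
                       modulation_trace(mod, sim$kspace$profile_time))
  plan <- plan_sliding_window(720, 90, 90, k$meta$tr_eff)
  series <- reconstruct_series(k, plan, "gridding", zero_fill = 1)
  b <- background_trace(series, baseline_range = c(1, 3))
  m <- modulation_trace(mod, series$frame_mid_time)
  m0 <- mean(m[1:3])
  expect_lt(max(abs(b - (m / m0 - 1))), 0.1 * mod$amp)
})

test_that("background correction is exact for multiplicative drift", {
  expect_equal(correct_background(c(1, 2, 3), c(0, 0, 0)), c(1, 2, 3))
  expect_equal(correct_background(c(0.1, 0.2), c(0.1, 0.2)), c(0, 0))
  re <- array(1, c(3, 1, 2, 2))
  expect_equal(correct_background(re, c(1, 1, 1)), array(0, dim(re)))
  expect_error(correct_background(re, c(0, 0)), "frame axes")

  # noise-free static phantom under 5% receiver drift: corrected lung
  # curve returns to zero within 1e-3 (repeat-angle frames, see above)
  spec <- static_phantom_spec(noise_rel = 0, seed = 2)
  spec$noise_sd <- 0
  tr <- build_trajectory(720, 32, 32, angle_increment = 4)
  sim <- simulate_kspace(spec, n_profiles = 720, traj = tr)
  k <- modulate_kspace(sim$kspace,
                       modulation_trace(list(amp = 0.05, period = 1200),
                                        sim$kspace$profile_time))
  plan <- plan_sliding_window(720, 90, 90, k$meta$tr_eff)
  series <- reconstruct_series(k, plan, "gridding", zero_fill = 1)
  roi <- lung_roi(sim$truth$lung_mask, series$pixel_spacing,
                  series$slice_thickness)
  s0 <- compute_baseline(series, c(1, 3))
  re <- relative_enhancement(series, s0)
  b <- background_trace(series, baseline_range = c(1, 3), lung = roi)
  curve <- mean_lung_curve(correct_background(re, b), roi)
  expect_lt(max(abs(curve)), 1e-3)
})

test_that("pixel binning matches a brute-force classifier", {
  thr <- c(1, 2, 3, 4, 8, 12)
  expect_equal(bin_pixels(array(0.5, c(1, 1, 1, 1)), 1, c(0, 2), thr)[1, 1, 1], 0L)
  expect_equal(bin_pixels(array(5, c(1, 1, 1, 1)), 1, c(0, 2), thr)[1, 1, 1], 4L)
  set.seed(3)
  re <- array(runif(6 * 2 * 5 * 5, -1, 20), c(6, 2, 5, 5))
  times <- 1:6
  got <- bin_pixels(re, times, c(2, 5), thr)
  for (s in 1:2) for (r in 1:5) for (cc in 1:5) {
    m <- max(re[2:5, s, r, cc])
    want <- sum(m >= thr)
    expect_identical(got[s, r, cc], as.integer(want))
  }
  expect_error(bin_pixels(re, times, c(10, 11), thr), "empty")
  expect_error(bin_pixels(re, times, c(2, 5), c(1, 1, 2)), "increasing")
})

test_that("known compartment peaks land in their intervals at default noise", {
  # module-level check on enhancement traces built from the ground truth
  spec <- desk_phantom_spec()
  spec$entries[[1]]$peak_re <- 0.5
  spec$entries[[2]]$peak_re <- 2.5
  spec$entries[[3]]$peak_re <- 9
  spec$entries[[4]]$peak_re <- 15
  spec <- phantom_spec(spec$entries, matrix_size = 64, n_slices = 4,
                       tr_profile = 0.003, t_inj = 36, duration = 48,
                       seed = 4)
  truth <- render_phantom(spec)
  times <- seq(30, 48, by = 0.72)
  truc <- true_re_curves(truth, times)
  tb <- true_bin_map(truth, times, c(36, 48))
  expect_equal(unname(tb$entry_class), c(0L, 2L, 5L, 6L))
  set.seed(10)
  for (i in 1:4) {
    n_pix <- sum(truth$entry_map == i)
    traces <- matrix(rep(truc[i, ], each = n_pix), n_pix) +
      matrix(rnorm(n_pix * length(times), sd = 0.1), n_pix)
    cls <- findInterval(apply(traces[, times >= 36], 1, max),
                        c(1, 2, 3, 4, 8, 12))
    expect_gte(mean(cls == tb$entry_class[i]), 0.95)
  }
})

test_that("bin volumes partition the lung and reproduce the fractions", {
  mask <- array(FALSE, c(2, 30, 30))
  mask[, 5:25, 5:25] <- TRUE
  roi <- lung_roi(mask, 0.302, 1.208)
  set.seed(2)
  bm <- array(NA_integer_, dim(mask))
  bm[mask] <- sample(0:6, sum(mask), replace = TRUE)
  bv <- bin_volumes(bm, roi)
  expect_equal(sum(bv$volumes_ml), bv$lung_volume_ml, tolerance = 1e-12)
  # all pixels in one class: that class carries the whole lung volume
  bm1 <- bm
  bm1[mask] <- 3L
  bv1 <- bin_volumes(bm1, roi)
  expect_equal(unname(bv1$volumes_ml["bin3"]), bv1$lung_volume_ml)
  expect_equal(bv1$low_fraction, 0)
})

test_that("mean curves and group averages", {
  fr <- array(0, c(4, 1, 3, 3))
  fr[, 1, 2, 2] <- c(1, 2, 3, 4)
  mask <- array(FALSE, c(1, 3, 3))
  mask[1, 2, 2] <- TRUE
  roi <- lung_roi(mask, 1, 1)
  expect_equal(mean_lung_curve(fr, roi), c(1, 2, 3, 4))
  g <- group_average(list(c(1, 2), c(1, 2), c(1, 2)))
  expect_equal(g$mean, c(1, 2))
  expect_equal(g$sem, c(0, 0))
  g2 <- group_average(list(c(0, 0), c(2, 2)))
  expect_equal(g2$sem, c(1, 1))
  expect_error(group_average(list(1:3, 1:4)), "differ")
})
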
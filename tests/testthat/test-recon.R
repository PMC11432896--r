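test_that("sliding-window plan reproduces the protocol timing", {
  plan <- plan_sliding_window(14736, 90, 60, tr_eff = 0.114)
  expect_equal(plan$frame_duration, 10.26)
  expect_equal(plan$frame_spacing, 6.84)
  # printed protocol values
  expect_lt(abs(plan$frame_duration - 10.2), 0.1)
  expect_lt(abs(plan$frame_spacing - 6.8), 0.1)
  expect_equal(38 * 0.003, 0.114)

  p1 <- plan_sliding_window(90, 90, 60)
  expect_equal(p1$n_frames, 1L)
  expect_equal(p1$frames[[1]], 1:90)

  p2 <- plan_sliding_window(150, 90, 60)
  expect_equal(p2$n_frames, 2L)
  expect_equal(p2$frames[[2]], 61:150)   # the protocol's "profiles 60-150"

  expect_error(plan_sliding_window(80, 90, 60), "empty plan")
  expect_error(plan_sliding_window(200, 50, 60), "window")
})

test_that("frame-count formula matches brute-force enumeration", {
  count_enum <- function(n, w, s) length(seq.int(0, n - w, by = s))
  # exhaustive at small sizes
  for (n in c(90, 91, 150, 151)) {
    for (w in seq(1, n, by = 7)) {
      for (s in seq(1, w, by = 5)) {
        expect_identical(plan_sliding_window(n, w, s, 0.114)$n_frames,
                         as.integer(count_enum(n, w, s)))
      }
    }
  }
  # randomized sweep up to the full range
  set.seed(1)
  for (i in 1:400) {
    n <- sample(1:1000, 1)
    w <- sample(1:n, 1)
    s <- sample(1:w, 1)
    expect_identical(plan_sliding_window(n, w, s, 0.114)$n_frames,
                     as.integer(count_enum(n, w, s)))
  }
})

test_that("sampling operator passes the adjoint test", {
  tr <- build_trajectory(50, 32, 32)
  for (zf in c(1, 2)) {
    op <- nufft_operator(tr, 1:50, zero_fill = zf)
    set.seed(7)
    M <- op$M
    x <- matrix(complex(real = rnorm(M^2), imaginary = rnorm(M^2)), M, M)
    y <- complex(real = rnorm(50 * 32), imaginary = rnorm(50 * 32))
    lhs <- sum(op$forward(x) * Conj(y))
    rhs <- sum(x * Conj(op$adjoint(y)))
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-6)
  }
})

test_that("gridding agrees with a direct nonuniform-DFT oracle", {
  m <- 32
  tr <- build_trajectory(120, m, m)
  pos <- expand.grid(r = 0:(m - 1) - m / 2, c = 0:(m - 1) - m / 2)
  disc <- pos$r^2 + pos$c^2 <= 10^2
  y <- oracle_nudft_forward(as.vector(tr$kx), as.vector(tr$ky),
                            pos$r[disc], pos$c[disc])
  w <- as.vector(density_weights(tr, "area"))
  img_o <- Mod(oracle_nudft_adjoint(as.vector(tr$kx), as.vector(tr$ky),
                                    w, y, m))
  dat <- array(0i, c(120, m, 1))
  dat[, , 1] <- matrix(y, 120, m)
  k <- kspace_series(dat, tr, n_slices = 1)
  img_g <- grid_reconstruct(k, 1:120, zero_fill = 1)[1, , ]
  expect_lt(nrmse_opt(img_o, img_g), 0.03)

  # energy of the disc object stays concentrated in its support
  inside <- matrix(disc, m, m)
  expect_gt(sum(img_g[inside]^2) / sum(img_g^2), 0.95)
  # ripple on a flat object, away from the edge
  interior <- matrix(pos$r^2 + pos$c^2 <= 6^2, m, m)
  expect_lt(sd(img_g[interior]) / mean(img_g[interior]), 0.05)
})

test_that("point-source PSF peaks at center with bounded sidelobes", {
  m <- 32
  n_sp <- 402
  tr <- build_trajectory(n_sp, m, m, angle_increment = 360 / n_sp)
  y <- oracle_nudft_forward(as.vector(tr$kx), as.vector(tr$ky), 0, 0)
  dat <- array(0i, c(n_sp, m, 1))
  dat[, , 1] <- matrix(y, n_sp, m)
  k <- kspace_series(dat, tr, n_slices = 1)
  img <- grid_reconstruct(k, 1:n_sp, zero_fill = 1)[1, , ]
  pk <- which(img == max(img), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(m / 2 + 1, m / 2 + 1))
  d2 <- outer((1:m - m / 2 - 1)^2, (1:m - m / 2 - 1)^2, "+")
  off <- img
  off[d2 <= 2^2] <- 0    # exclude the main lobe
  expect_lt(max(off) / max(img), 0.10)
})

test_that("undersampling artefact grows as spokes are removed", {
  sim <- fixture("static32", simulate_kspace(static_phantom_spec(),
                                             n_profiles = 900))
  k <- sim$kspace
  ref <- grid_reconstruct(k, 1:900, zero_fill = 1)
  g90 <- grid_reconstruct(k, 1:90, zero_fill = 1)
  g600 <- grid_reconstruct(k, 1:600, zero_fill = 1)
  expect_gt(nrmse_opt(ref[1, , ], g90[1, , ]),
            nrmse_opt(ref[1, , ], g600[1, , ]))
})

test_that("baseline reconstruction is deterministic and validates input", {
  sim <- fixture("static32", simulate_kspace(static_phantom_spec(),
                                             n_profiles = 900))
  b1 <- baseline_high_quality(sim$kspace, 600, zero_fill = 1)
  b2 <- baseline_high_quality(sim$kspace, 600, zero_fill = 1)
  expect_identical(b1, b2)
  expect_error(baseline_high_quality(sim$kspace, 3000), "900")
})

test_that("NaN input is rejected with the offending profile named", {
  sim <- fixture("static32", simulate_kspace(static_phantom_spec(),
                                             n_profiles = 900))
  k <- sim$kspace
  k$data[17, 3, 1] <- NaN
  expect_error(grid_reconstruct(k, 1:90, zero_fill = 1), "profile\\(s\\) 17")
  expect_error(grid_reconstruct(k, 20:40, zero_fill = 1), NA)
  expect_error(grid_reconstruct(k, integer(0)), "empty profile range")
})

test_that("phase correction rotates phases and round-trips", {
  sim <- fixture("static32", simulate_kspace(static_phantom_spec(),
                                             n_profiles = 900))
  k <- sim$kspace
  d <- dim(k$data)
  zero <- matrix(0, d[1], d[2])
  expect_equal(apply_phase_correction(k, zero)$data, k$data)
  halfturn <- matrix(pi, d[1], d[2])
  expect_equal(apply_phase_correction(k, halfturn)$data, -k$data)
  set.seed(5)
  ph <- matrix(runif(d[1] * d[2], -pi, pi), d[1], d[2])
  back <- apply_phase_correction(apply_phase_correction(k, ph), -ph)
  expect_equal(back$data, k$data, tolerance = 1e-12)
  expect_equal(Mod(apply_phase_correction(k, ph)$data), Mod(k$data),
               tolerance = 1e-12)
  expect_error(apply_phase_correction(k, matrix(0, 3, 3)), "shape")
})

test_that("a static object yields a time-invariant frame series", {
  spec <- static_phantom_spec(noise_rel = 1e-3)
  sim <- simulate_kspace(spec, n_profiles = 300)
  plan <- plan_sliding_window(300, 90, 60, sim$kspace$meta$tr_eff)
  series <- reconstruct_series(sim$kspace, plan, "gridding", zero_fill = 1)
  # frames share the object; differences are undersampling + noise only
  for (f in 2:plan$n_frames)
    expect_lt(nrmse_opt(series$frames[1, 1, , ], series$frames[f, 1, , ]),
              0.1)
  expect_equal(series$frame_mid_time,
               vapply(plan$frames, function(pr)
                 mean(sim$kspace$profile_time[range(pr)]), 0))
})

test_that("unregularized solve matches gridding on well-sampled data", {
  m <- 32
  tr <- build_trajectory(300, m, m)
  op <- nufft_operator(tr, 1:300, zero_fill = 1)
  set.seed(5)
  x <- matrix(rnorm(m^2), m, m)
  fr <- c(0:(m / 2), (m / 2 - 1):1) / m
  filt <- exp(-outer(fr^2, fr^2, "+") * (2 * pi * 3)^2 / 2)
  x <- Re(fft(fft(x) * filt, inverse = TRUE)) / m^2   # band-limited object
  y <- op$forward(x + 0i)
  dat <- array(0i, c(300, m, 1))
  dat[, , 1] <- matrix(y, 300, m)
  k <- kspace_series(dat, tr, n_slices = 1)
  g <- grid_reconstruct(k, 1:300, zero_fill = 1)
  r0 <- regularized_reconstruct(k, 1:300, l1_weight = 0, l2_weight = 0,
                                n_iter = 60, zero_fill = 1)
  expect_lt(nrmse_opt(g[1, , ], r0[1, , ]), 0.02)
})

test_that("regularized recon does not trail gridding on undersampled frames", {
  expect_equal(0.00536 / 0.0016, 3.35)
  spec <- static_phantom_spec(noise_rel = 2e-3)
  sim <- simulate_kspace(spec, n_profiles = 300)
  k <- sim$kspace
  ref <- grid_reconstruct(k, 1:300, zero_fill = 1)
  g90 <- grid_reconstruct(k, 1:90, zero_fill = 1)
  r90 <- regularized_reconstruct(k, 1:90, n_iter = 40, zero_fill = 1)
  obj <- attr(r90, "objective")[[1]]
  expect_true(all(diff(obj) <= 1e-6 * pmax(abs(obj[-length(obj)]), 1e-30)))
  expect_lte(nrmse_opt(ref[1, , ], r90[1, , ]),
             nrmse_opt(ref[1, , ], g90[1, , ]))
  expect_error(regularized_reconstruct(k, 1:90, n_iter = 0), "n_iter")
  expect_error(regularized_reconstruct(k, 1:90, l1_weight = -1), "weights")
})
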
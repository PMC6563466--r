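test_that("drift profile is a linear ramp anchored at zero", {
  expect_equal(drift_profile(0, c(-5, 0, 100)), c(0, 0, 0))
  expect_equal(drift_profile(4.6, 60), 4.6)
  expect_equal(drift_profile(4.6, -30), 0)
  # ~4.6 Hz/min over 13 minutes is the ~60 Hz drift regime
  expect_equal(drift_profile(4.6, 13 * 60), 59.8, tolerance = 1e-12)
})

test_that("coil profiles are smooth, positive in quadrature and reproducible", {
  set.seed(42)
  cp <- make_coil_profiles(8, c(24, 24))
  sos <- apply(cp$mag^2, c(2, 3), sum)
  expect_true(all(sos > 0))
  expect_true(all(cp$phase > -pi & cp$phase <= pi))
  set.seed(42)
  cp2 <- make_coil_profiles(8, c(24, 24))
  expect_identical(cp, cp2)
  flat <- make_coil_profiles(1, c(16, 16), flat = TRUE)
  expect_equal(unique(as.vector(flat$mag)), 1)
  expect_equal(unique(as.vector(flat$phase)), 0)
  expect_error(make_coil_profiles(2, c(16, 16), flat = TRUE), "single")
})

test_that("the same seed reproduces the acquisition bit for bit", {
  cfg <- tiny_cfg(grid = c(16, 16), n_channels = 2, snr = 80,
                  offsets_ppm = alternating_offsets(2, 1),
                  with_wassr = FALSE, seed = 7)
  a1 <- generate_acquisition(cfg)
  a2 <- generate_acquisition(cfg)
  expect_identical(a1$sat_images[[3]]$data, a2$sat_images[[3]]$data)
  expect_identical(a1$s0_image$data, a2$s0_image$data)
  expect_identical(a1$truth$b0_map, a2$truth$b0_map)
})

test_that("noiseless single-channel phase equals the forward model exactly", {
  acq <- tiny_noiseless_drift_acq()
  tr <- acq$truth
  k <- 5
  t_k <- acq$schedule$timestamp_s[k]
  field <- tr$b0_map + truth_drift(tr, t_k)
  img <- acq$sat_images[[k]]
  for (j in 1:2) {
    expected <- Arg(exp(1i * (2 * pi * field * img$echo_times[j] +
                              tr$coil_phase[2, , ])))
    got <- Arg(img$data[2, j, , ])
    err <- abs(Arg(exp(1i * (got - expected))))
    expect_lt(max(err[tr$support]), 1e-12)
  }
})

test_that("phase difference between echoes follows 2*pi*field*dTE", {
  # 10 Hz and TE 1.74/5.16 ms give 2*pi*10*0.00342 = 0.2149 rad
  cfg <- tiny_cfg(grid = c(16, 16), n_channels = 2,
                  offsets_ppm = alternating_offsets(2, 1),
                  b0_coef = c(c0 = 10), with_wassr = FALSE)
  acq <- generate_acquisition(cfg)
  dphi <- Arg(acq$gre_prescan$data[1, 2, , ] * Conj(acq$gre_prescan$data[1, 1, , ]))
  expect_equal(mean(dphi[acq$truth$support]), 0.2149, tolerance = 1e-4)
  expect_lt(diff(range(dphi[acq$truth$support])), 1e-12)
})

test_that("zero-noise flat-field Z-stack reproduces the clean ground truth", {
  cfg <- tiny_cfg(b0_coef = c(c0 = 0), with_wassr = FALSE)
  acq <- generate_acquisition(cfg)
  z <- build_zstack(acq)
  supp <- acq$truth$support
  sel <- array(supp, dim(z$values))
  expect_lt(max(abs(z$values - acq$truth$clean_zstack$values)[sel]), 1e-12)
})

test_that("a constant field offset is recovered from the prescan map", {
  cfg <- tiny_cfg(grid = c(16, 16), n_channels = 2,
                  offsets_ppm = alternating_offsets(2, 1),
                  b0_coef = c(c0 = 10), with_wassr = FALSE)
  acq <- generate_acquisition(cfg)
  fm <- dual_echo_map(acq$gre_prescan, acq$scanner, smooth = FALSE)
  expect_lt(max(abs(fm$values[[1]][acq$truth$support] - 10)), 1e-9)
  # flat zero field maps to zero
  cfg0 <- tiny_cfg(grid = c(16, 16), n_channels = 2,
                   offsets_ppm = alternating_offsets(2, 1),
                   b0_coef = c(c0 = 0), with_wassr = FALSE, seed = 3)
  acq0 <- generate_acquisition(cfg0)
  fm0 <- dual_echo_map(acq0$gre_prescan, acq0$scanner, smooth = FALSE)
  expect_lt(max(abs(fm0$values[[1]][acq0$truth$support])), 1e-9)
})

test_that("the default schedule emulates the scan-rescan protocol", {
  cfg <- sim_config()
  expect_length(cfg$offsets_ppm, 61)
  expect_equal(range(cfg$offsets_ppm), c(-4.5, 4.5))
  expect_equal(cfg$te_s, c(0.00174, 0.00516))
  expect_length(cfg$wassr_offsets_ppm, 33)
  # schedule duration ~13 min; default drift integrates to 60 Hz across it
  block <- cfg$nav_duration + cestb0:::train_duration(cfg$train) +
    cfg$grid[1] * cfg$tr_s + cfg$recovery_delay
  dur_min <- 61 * block / 60
  expect_gt(dur_min, 11); expect_lt(dur_min, 14)
  expect_equal(cfg$drift_total, 60)
})
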
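sc7 <- scanner_profile(7)
te2 <- c(0.00174, 0.00516)

test_that("2D unwrapping restores smooth fields and is congruent mod 2*pi", {
  # already-unwrapped input: unchanged up to a global 2*pi k
  ph <- matrix(0.3, 16, 16)
  out <- unwrap_2d(ph)
  expect_equal(out, ph)

  # wrapped linear ramp 0 -> 4*pi across the rows
  ramp <- matrix(seq(0, 4 * pi, length.out = 24), 24, 24)
  wrapped <- Arg(exp(1i * ramp))
  out <- unwrap_2d(wrapped)
  resid <- (out - ramp) / (2 * pi)
  expect_equal(resid, round(resid), tolerance = 1e-9)   # congruent
  expect_lt(diff(range(out - ramp)), 1e-9)              # single global k

  # random smooth polynomial phase, wrapped, over several draws
  set.seed(1)
  u <- matrix(seq(-1, 1, length.out = 32), 32, 32)
  v <- t(u)
  for (i in 1:5) {
    co <- runif(6, -3, 3)
    truephase <- co[1] + co[2] * u + co[3] * v + co[4] * u * v +
      co[5] * u^2 + co[6] * v^2
    out <- unwrap_2d(Arg(exp(1i * truephase)))
    d <- (out - truephase) / (2 * pi)
    expect_lt(max(abs(d - round(mean(d)))), 1e-9 / (2 * pi) + 1e-12)
  }
})

test_that("Hamming smoothing preserves constants, localises impulses, conserves mass", {
  cmap <- matrix(3.5, 12, 12)
  expect_equal(hamming_smooth(cmap, 5), cmap)
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  sm <- hamming_smooth(imp, 5)
  expect_true(all(sm[abs(row(sm) - 8) > 2 | abs(col(sm) - 8) > 2] == 0))
  expect_gt(sm[8, 8], sm[8, 10])
  w <- 0.54 - 0.46 * cos(2 * pi * (0:4) / 4)
  expect_equal(sm[8, 8], w[3]^2 / sum(w)^2)
  # periodic convolution conserves the total sum
  set.seed(2)
  m <- matrix(rnorm(20 * 20), 20, 20)
  expect_equal(sum(hamming_smooth(m, 5, periodic = TRUE)), sum(m))
  # NA voxels stay NA and do not poison neighbours
  m[3, 3] <- NA
  sm2 <- hamming_smooth(m, 3)
  expect_true(is.na(sm2[3, 3]))
  expect_false(anyNA(sm2[-3, ]))
  expect_error(hamming_smooth(m, 4), "width")
})

test_that("coil-constant phases cancel in the dual-echo Hermitian combination", {
  phases <- c(0.4, -2.8, 1.9)
  img0 <- uniform_field_image(0, te2, n_ch = 3, coil_phase = phases)
  fm <- dual_echo_map(img0, sc7, smooth = FALSE)
  expect_lt(max(abs(fm$values[[1]])), 1e-12)

  set.seed(3)
  imgA <- uniform_field_image(25, te2, n_ch = 3, coil_phase = phases,
                              noise_sd = 0.01)
  # add a different constant phase per channel to both echoes
  imgB <- imgA
  extra <- c(1.1, -0.7, 2.4)
  for (l in 1:3) imgB$data[l, , , ] <- imgB$data[l, , , ] * exp(1i * extra[l])
  fa <- dual_echo_map(imgA, sc7, smooth = FALSE)
  fb <- dual_echo_map(imgB, sc7, smooth = FALSE)
  expect_lt(max(abs(fa$values[[1]] - fb$values[[1]])), 1e-12)
})

test_that("a uniform in-range field is recovered exactly; out-of-range fields alias", {
  img <- uniform_field_image(10, te2)
  fm <- dual_echo_map(img, sc7, smooth = FALSE)
  expect_lt(max(abs(fm$values[[1]] - 10)), 1e-9)

  # 1/dTE = 292.4 Hz; a uniform 200 Hz field has no spatial wraps to exploit
  # and aliases to 200 - 292.4 = -92.4 Hz
  img200 <- uniform_field_image(200, te2)
  fm200 <- dual_echo_map(img200, sc7, smooth = FALSE)
  expect_equal(mean(fm200$values[[1]]), 200 - 1 / diff(te2), tolerance = 1e-6)

  # a ramp 0 -> 200 Hz wraps spatially and unwrapping restores it
  ramp <- matrix(seq(0, 200, length.out = 24), 24, 24, byrow = TRUE)
  imgr <- uniform_field_image(ramp, te2, grid = c(24, 24))
  fmr <- dual_echo_map(imgr, sc7, smooth = FALSE)
  expect_lt(max(abs(fmr$values[[1]] - ramp)), 1e-6)
  fmw <- dual_echo_map(imgr, sc7, smooth = FALSE, unwrap = FALSE)
  expect_gt(max(abs(fmw$values[[1]] - ramp)), 100)   # aliased without unwrap
  expect_error(dual_echo_map(first_echo(imgr), sc7), "2-echo")
})

test_that("the TE-extrapolation estimate of coil phase offsets cancels the field", {
  # single channel, constant offset 0.5 rad, any field: exact recovery
  for (f in c(0, 40, -120)) {
    img <- uniform_field_image(f, te2, n_ch = 1, coil_phase = 0.5)
    co <- coil_offsets(img, smooth = "none")
    expect_lt(max(abs(co$phi_rx - 0.5)), 1e-12)
  }
  img <- uniform_field_image(30, te2, n_ch = 2, coil_phase = c(0, 0))
  co <- coil_offsets(img, smooth = "none")
  expect_lt(max(abs(co$phi_rx)), 1e-12)
  expect_error(coil_offsets(first_echo(img)), "2-echo")
  zero <- uniform_field_image(0, te2, mag = 0)
  expect_error(coil_offsets(zero), "zero")
})

test_that("simulated polynomial coil offsets are recovered inside the mask", {
  acq <- tiny_noiseless_acq()
  co <- coil_offsets(acq$gre_prescan)
  err <- abs(Arg(exp(1i * (co$phi_rx - acq$truth$coil_phase))))
  sel <- array(rep(acq$truth$support & co$mask, each = dim(err)[1]), dim(err))
  expect_lt(max(err[sel]), 1e-6)
  # smoothing extrapolates finite values beyond the mask
  expect_true(all(is.finite(co$phi_rx)))
})

test_that("single-echo mapping with prescan offsets equals dual-echo mapping", {
  acq <- tiny_noiseless_acq()
  co <- coil_offsets(acq$gre_prescan)
  f2 <- dual_echo_map(acq$gre_prescan, acq$scanner, smooth = FALSE)
  f1 <- single_echo_map(first_echo(acq$gre_prescan), co, acq$scanner,
                        smooth = FALSE)
  supp <- acq$truth$support
  expect_lt(max(abs(f1$values[[1]] - f2$values[[1]])[supp]), 1e-9)
  expect_error(single_echo_map(first_echo(acq$gre_prescan), NULL, acq$scanner),
               "offset")
})

test_that("field-map estimator variance shrinks as channels are added", {
  set.seed(8)
  sds <- vapply(c(2, 4, 8, 16), function(L) {
    img <- uniform_field_image(10, te2, n_ch = L, grid = c(24, 24),
                               coil_phase = runif(L, -pi, pi), noise_sd = 0.1)
    stats::sd(dual_echo_map(img, sc7, smooth = FALSE)$values[[1]])
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("dynamic series reproduce the prescan map without drift and track it with drift", {
  acq <- tiny_noiseless_acq()         # no drift
  pres <- dual_echo_map(acq$gre_prescan, acq$scanner)
  supp <- erode_mask(acq$truth$support, 4)
  for (m in c("cestgre2te", "nav2te", "cestgre1te")) {
    ser <- dynamic_series(acq, m)
    expect_equal(n_maps(ser), nrow(acq$schedule))
    errs <- vapply(ser$values, function(v) max(abs(v - pres$values[[1]])[supp]),
                   numeric(1))
    expect_lt(max(errs), 1e-6)
  }
  # near-water maps are flagged for the intrinsic methods only
  ser_i <- dynamic_series(acq, "cestgre2te")
  expect_identical(ser_i$low_confidence,
                   which(abs(acq$schedule$offset_ppm) < 0.33))
  expect_length(dynamic_series(acq, "nav2te")$low_confidence, 0)

  # induced drift recovered from the intrinsic series within 2% (noiseless)
  acq_d <- tiny_noiseless_drift_acq()
  roi <- erode_mask(acq_d$truth$support, 4)
  fd <- fit_drift(dynamic_series(acq_d, "cestgre2te"), roi)
  expect_equal(fd$rate_hz_min, acq_d$truth$drift_rate_hz_min, tolerance = 0.02)
  expect_gt(fd$r2, 0.999)

  no_nav <- acq
  no_nav$nav_images <- NULL
  expect_error(dynamic_series(no_nav, "nav2te"), "navigator")
})
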
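sc7 <- scanner_profile(7)

test_that("Z-stack assembly normalises by the identically combined reference", {
  acq <- tiny_noiseless_acq()
  z <- build_zstack(acq)
  expect_equal(dim(z$values)[3], nrow(acq$schedule))
  # reference image as a saturated frame (Z = 1 truth) gives Z = 1
  acq1 <- acq
  acq1$sat_images <- rep(list(acq$s0_image), nrow(acq$schedule))
  z1 <- build_zstack(acq1)
  sel <- array(z1$mask, dim(z1$values))
  expect_lt(max(abs(z1$values[sel] - 1)), 1e-12)
  # single-echo degenerate case uses that echo alone
  acq2 <- acq
  acq2$sat_images <- lapply(acq$sat_images, first_echo)
  acq2$s0_image <- first_echo(acq$s0_image)
  z2 <- build_zstack(acq2)
  m1 <- sos_magnitude(first_echo(acq$sat_images[[4]]))
  expect_equal(z2$values[, , 4][z2$mask],
               (m1 / sos_magnitude(first_echo(acq$s0_image)))[z2$mask])
})

test_that("correcting with a zero map is the identity on the sorted grid", {
  acq <- tiny_noiseless_acq()
  z <- build_zstack(acq)
  zero <- field_map_series(matrix(0, 24, 24), 0, "gre2te")
  cz <- correct_static(z, zero, sc7)
  ord <- order(z$offsets_ppm)
  sel <- array(z$mask, dim(cz$values))
  expect_equal(cz$values[sel], (z$values[, , ord])[sel], tolerance = 1e-12)
})

test_that("correcting a shifted spectrum with the true shift restores the reference", {
  offs <- sort(alternating_offsets(3, 0.15))
  shift <- 0.2
  # linewidth matching the ~1.4 ppm FWHM of the 2-uT direct-saturation line
  mk <- function(ctr) lorentzian_zstack(matrix(ctr, 8, 8), offs,
                                        depth = 0.7, gamma = 1.4)
  zs <- mk(shift)
  map <- field_map_series(matrix(shift * sc7$hz_per_ppm, 8, 8), 0, "gre2te")
  cz <- correct_static(zs, map, sc7)
  ref <- mk(0)
  inside <- abs(offs) <= 3 - shift - 1e-9
  err <- abs(cz$values[, , inside] - ref$values[, , inside])
  expect_lt(max(err), 1e-3)
  # points shifted off-grid are flagged missing, not extrapolated
  expect_true(all(is.na(cz$values[, , offs > 3 - shift + 0.15])))
  # downstream MTRasym of the corrected symmetric spectrum is ~0
  a <- mtr_asym(cz, c(0.3, 1.0), roi = matrix(TRUE, 8, 8))
  expect_lt(abs(a$roi_mean), 0.05)
})

test_that("voxels with shifts beyond half the spectral span are uncorrectable", {
  offs <- sort(alternating_offsets(2, 0.25))
  z <- lorentzian_zstack(matrix(0, 8, 8), offs)
  big <- field_map_series(matrix(2.5 * sc7$hz_per_ppm, 8, 8), 0, "gre2te")
  cz <- correct_static(z, big, sc7)
  expect_true(all(is.na(cz$values)))
  expect_equal(cz$uncorrectable_n, 64)
})

test_that("a constant dynamic series reduces exactly to the static correction", {
  acq <- tiny_noiseless_drift_acq()
  z <- build_zstack(acq)
  n <- nrow(acq$schedule)
  cmap <- matrix(7.3, 24, 24)
  ser <- field_map_series(rep(list(cmap), n), acq$schedule$timestamp_s,
                         "cestgre2te", source_offsets = acq$schedule$offset_ppm)
  static <- field_map_series(cmap, 0, "gre2te")
  expect_identical(correct_dynamic(z, ser, sc7)$values,
                   correct_static(z, static, sc7)$values)
})

test_that("dynamic correction with exact maps equals static with the prescan map when drift is zero", {
  acq <- tiny_noiseless_acq()
  z <- build_zstack(acq)
  ser <- dynamic_series(acq, "nav2te", smooth = FALSE)
  cd <- correct_dynamic(z, ser, acq$scanner)
  cs <- correct_static(z, dual_echo_map(acq$gre_prescan, acq$scanner,
                                        smooth = FALSE), acq$scanner)
  sel <- array(erode_mask(z$mask, 1), dim(cd$values))
  sel <- sel & is.finite(cd$values) & is.finite(cs$values)
  expect_lt(max(abs(cd$values[sel] - cs$values[sel])), 1e-6)
})

test_that("MTRasym arithmetic, antisymmetry and grid checks", {
  offs <- c(-2, -1, 0, 1, 2)
  vals <- array(1, c(8, 8, 5))
  vals[, , 2] <- 0.6  # Z(-1)
  vals[, , 4] <- 0.5  # Z(+1)
  z <- z_stack(vals, offs, matrix(1, 8, 8))
  a <- mtr_asym(z, c(1, 1.5), roi = matrix(TRUE, 8, 8))
  expect_equal(unique(as.vector(a$values)), 10)   # percent
  expect_equal(a$roi_mean, 10)
  expect_equal(a$roi_sd, 0)

  # mirroring the spectrum flips the sign: mtr_asym(mirror(Z)) = -mtr_asym(Z)
  set.seed(4)
  vr <- array(runif(8 * 8 * 5, 0.2, 1), c(8, 8, 5))
  zf <- z_stack(vr, offs, matrix(1, 8, 8))
  zm <- z_stack(vr[, , 5:1], -offs[5:1], matrix(1, 8, 8))
  af <- mtr_asym(zf, c(0.5, 2))
  am <- mtr_asym(zm, c(0.5, 2))
  expect_equal(am$values, -af$values)

  # perfectly symmetric spectrum gives 0 everywhere
  vs <- vr; vs[, , 1] <- vr[, , 5]; vs[, , 2] <- vr[, , 4]
  as <- mtr_asym(z_stack(vs, offs, matrix(1, 8, 8)), c(0.5, 2))
  expect_equal(unique(as.vector(as$values)), 0)

  expect_error(mtr_asym(z_stack(vals, offs + 0.3, matrix(1, 8, 8)),
                        c(0.3, 1)), "symmetric")
})

test_that("ROI statistics match an independent two-pass computation", {
  set.seed(5)
  m <- matrix(rnorm(64, mean = 2), 8, 8)
  m[1, 1] <- NA
  mask <- matrix(rep(c(TRUE, FALSE), 32), 8, 8)
  st <- roi_stats(m, mask)
  v <- m[mask]; v <- v[is.finite(v)]
  mu <- sum(v) / length(v)
  expect_equal(st$mean, mu)
  expect_equal(st$sd, sqrt(sum((v - mu)^2) / (length(v) - 1)))
  expect_equal(st$n, length(v))
  expect_error(roi_stats(m, matrix(FALSE, 8, 8)), "empty")
  cmap <- mtr_asym_map(matrix(4.2, 8, 8), c(0.3, 1))
  expect_equal(roi_stats(cmap, mask), list(mean = 4.2, sd = 0, n = 32))
})

test_that("correcting with the ground-truth field nulls the MT-free asymmetry", {
  cfg <- tiny_cfg(pools = pool_model(water = c(T1 = 0.9, T2 = 0.15)),
                  offsets_ppm = alternating_offsets(2.2, 0.11),
                  snr = 100, seed = 1)
  acq <- generate_acquisition(cfg)
  roi <- erode_mask(default_roi(acq), 4)
  a <- mtr_asym(correct_acquisition(acq, "truth"), c(0.3, 1.0), roi = roi)
  expect_lt(abs(a$roi_mean), 3 * a$roi_sd / sqrt(a$roi_n) + 0.02)
})
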
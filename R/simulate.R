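#' Linear frequency-drift profile
#'
#' Models a scanner reference-frequency drift as a linear ramp that starts at
#' 0 at t = 0 (the time of the dual-echo prescan). Negative timestamps
#' (prescans acquired before the CEST scan) see no drift.
#'
#' @param rate_hz_min Drift rate in Hz per minute.
#' @param timestamps_s Timestamps in seconds.
#' @return Drift in Hz at each timestamp.
#' @examples
#' drift_profile(4.6, c(0, 60, 780))  # 0, 4.6, ~59.8 Hz
#' @export
drift_profile <- function(rate_hz_min, timestamps_s) {
  stopifnot(is.numeric(rate_hz_min), length(rate_hz_min) == 1L,
            is.finite(rate_hz_min))
  rate_hz_min * pmax(timestamps_s, 0) / 60
}

#' Synthetic receive-coil sensitivity profiles
#'
#' Generates smooth per-channel magnitude profiles (Gaussian lobes centred
#' around the field of view, guaranteeing a positive sum-of-squares
#' everywhere) and smooth low-order-polynomial receive phase offsets in
#' `(-pi, pi]`. Draws from the current RNG state, so results are reproducible
#' under `set.seed()`.
#'
#' @param n_channels Number of receive channels (>= 1).
#' @param grid `c(rows, cols)`.
#' @param flat If TRUE (requires `n_channels = 1`), return a uniform
#'   magnitude and zero phase.
#' @return List with `mag` and `phase`, both arrays `[channel, row, col]`.
#' @export
make_coil_profiles <- function(n_channels, grid, flat = FALSE) {
  stopifnot(n_channels >= 1, length(grid) == 2L, all(grid >= 8))
  r <- grid[1]; c <- grid[2]
  mag <- array(0, c(n_channels, r, c))
  phase <- array(0, c(n_channels, r, c))
  if (flat) {
    if (n_channels != 1L)
      stop("flat profiles are defined for a single channel", call. = FALSE)
    mag[1, , ] <- 1
    return(list(mag = mag, phase = phase))
  }
  u <- matrix(seq(-1, 1, length.out = r), r, c)         # row coordinate
  v <- matrix(seq(-1, 1, length.out = c), r, c, byrow = TRUE)
  for (l in seq_len(n_channels)) {
    th <- 2 * pi * (l - 1) / n_channels + stats::runif(1, -0.2, 0.2)
    cu <- 1.1 * cos(th); cv <- 1.1 * sin(th)
    w <- stats::runif(1, 0.6, 0.8)
    mag[l, , ] <- 0.2 + exp(-((u - cu)^2 + (v - cv)^2) / (2 * w^2))
    co <- c(stats::runif(1, -2.2, 2.2), stats::runif(2, -0.8, 0.8),
            stats::runif(3, -0.4, 0.4))
    ph <- co[1] + co[2] * u + co[3] * v + co[4] * u * v +
      co[5] * u^2 + co[6] * v^2
    mx <- max(abs(ph))
    if (mx > 0.9 * pi) ph <- ph * (0.9 * pi / mx)
    phase[l, , ] <- ph
  }
  list(mag = mag, phase = phase)
}

#' Simulation configuration
#'
#' Collects every parameter of the synthetic CEST acquisition. The defaults
#' emulate a 7 T single-slice protocol: 61 offsets between -4.5 and +4.5 ppm
#' in alternating descending order, dual-echo readout at TE 1.74/5.16 ms, a
#' train of four 100-ms Gaussian pulses at 50% duty and 2.0 uT RMS B1, a
#' WASSR prescan (+/-0.8 ppm in 0.05-ppm steps at 0.2 uT), a smooth spatial
#' field offset of up to ~20 Hz, and a 60-Hz linear drift spread over the
#' ~13-minute schedule.
#'
#' @param scanner A [scanner_profile()].
#' @param pools A [pool_model()]; the default is a white-matter-like water
#'   pool (T1 1.2 s, T2 40 ms) with an amide-like solute at +3.5 ppm
#'   (k = 30/s, fraction 9e-4).
#' @param train Saturation [pulse_train()].
#' @param grid `c(rows, cols)` of the single slice.
#' @param n_channels Number of receive channels.
#' @param te_s Dual-echo times of the CEST/gradient-echo readout in seconds.
#' @param nav_te_s Dual-echo times of the navigator readout.
#' @param offsets_ppm Applied offsets in acquisition order.
#' @param wassr_offsets_ppm WASSR prescan offsets in acquisition order.
#' @param wassr_train Low-power WASSR [pulse_train()].
#' @param b0_coef Spatial field polynomial coefficients in Hz, named
#'   `(c0, cu, cv, cuu, cvv, cuv)` over unit coordinates in `[-1, 1]`.
#' @param drift_total Total induced drift in Hz across the CEST schedule
#'   (used when `drift_rate` is NULL).
#' @param drift_rate Drift rate in Hz/min; overrides `drift_total`.
#' @param recovery_delay Recovery delay between Z-spectral points (s).
#' @param tr_s Readout repetition time per k-space line (s).
#' @param nav_duration Navigator duration (s).
#' @param snr Signal-to-noise ratio of the channel-combined unsaturated
#'   magnitude (Inf for noiseless).
#' @param noise_sd Per-component complex noise SD as a fraction of the mean
#'   combined unsaturated magnitude; overrides `snr`.
#' @param object_radius Radius of the simulated disc object as a fraction of
#'   the half field of view.
#' @param with_nav,with_wassr Include the navigator series / WASSR prescan.
#' @param zgrid_step_ppm Step of the fine offset grid on which the
#'   Bloch-McConnell spectrum is evaluated before voxel-wise shifting.
#' @param seed RNG seed: the same configuration and seed reproduce the
#'   acquisition bit for bit.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(scanner = scanner_profile(7),
                       pools = pool_model(
                         water = c(T1 = 1.2, T2 = 0.04),
                         solute = list(T1 = 1.3, T2 = 0.01, k = 30, f = 9e-4,
                                       offset_ppm = 3.5)),
                       train = pulse_train(4, 0.1, 0.5, 2.0, "gaussian"),
                       grid = c(64, 64),
                       n_channels = 8,
                       te_s = c(0.00174, 0.00516),
                       nav_te_s = c(0.0054, 0.0090),
                       offsets_ppm = alternating_offsets(4.5, 0.15),
                       wassr_offsets_ppm = alternating_offsets(0.8, 0.05),
                       wassr_train = pulse_train(1, 0.1, 1, 0.2, "gaussian"),
                       b0_coef = c(c0 = 4, cu = 8, cv = -6, cuu = -9,
                                   cvv = 7, cuv = 4),
                       drift_total = 60,
                       drift_rate = NULL,
                       recovery_delay = 10,
                       tr_s = 0.0095,
                       nav_duration = 1.0,
                       snr = 100,
                       noise_sd = NULL,
                       object_radius = 0.84,
                       with_nav = TRUE,
                       with_wassr = TRUE,
                       zgrid_step_ppm = 0.02,
                       seed = 1L) {
  stopifnot(inherits(scanner, "scanner_profile"), inherits(pools, "pool_model"),
            inherits(train, "pulse_train"), length(te_s) == 2L,
            diff(te_s) > 0, length(grid) == 2L, all(grid >= 8),
            n_channels >= 1)
  if (is.null(noise_sd)) noise_sd <- if (is.finite(snr)) 1 / snr else 0
  stopifnot(noise_sd >= 0)
  structure(list(scanner = scanner, pools = pools, train = train,
                 grid = as.integer(grid), n_channels = as.integer(n_channels),
                 te_s = te_s, nav_te_s = nav_te_s,
                 offsets_ppm = offsets_ppm,
                 wassr_offsets_ppm = wassr_offsets_ppm,
                 wassr_train = wassr_train,
                 b0_coef = b0_coef, drift_total = drift_total,
                 drift_rate = drift_rate, recovery_delay = recovery_delay,
                 tr_s = tr_s, nav_duration = nav_duration,
                 noise_sd = noise_sd, object_radius = object_radius,
                 with_nav = with_nav, with_wassr = with_wassr,
                 zgrid_step_ppm = zgrid_step_ppm, seed = as.integer(seed)),
            class = "sim_config")
}

#' Phantom-mode simulation configuration
#'
#' A homogeneous water-only phantom (no exchanging pool): 41 offsets over
#' +/-2.2 ppm (0.11-ppm steps) and a high-resolution WASSR prescan with
#' 0.01-ppm steps. In such an object the corrected MTR asymmetry should be
#' 0% up to noise, which makes it the reference for correction accuracy.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return An object of class `sim_config`.
#' @export
phantom_config <- function(...) {
  args <- list(...)
  defaults <- list(
    pools = pool_model(water = c(T1 = 0.9, T2 = 0.15)),
    offsets_ppm = alternating_offsets(2.2, 0.11),
    wassr_offsets_ppm = alternating_offsets(0.8, 0.01),
    drift_total = 0)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

# evaluate the spatial field polynomial on the unit grid
eval_b0_poly <- function(coef, grid) {
  r <- grid[1]; c <- grid[2]
  u <- matrix(seq(-1, 1, length.out = r), r, c)
  v <- matrix(seq(-1, 1, length.out = c), r, c, byrow = TRUE)
  co <- rep(0, 6); names(co) <- c("c0", "cu", "cv", "cuu", "cvv", "cuv")
  co[names(coef)] <- coef
  co[["c0"]] + co[["cu"]] * u + co[["cv"]] * v + co[["cuu"]] * u^2 +
    co[["cvv"]] * v^2 + co[["cuv"]] * u * v
}

# complex multi-coil image for one Z-weighting and field state
synth_image <- function(zmat, field_hz, te_s, timestamp, s0map, coil,
                        noise_sd) {
  nch <- dim(coil$mag)[1]; r <- nrow(zmat); c <- ncol(zmat)
  ne <- length(te_s)
  data <- array(complex(real = 0), c(nch, ne, r, c))
  base <- s0map * zmat
  for (l in seq_len(nch)) {
    amp <- coil$mag[l, , ] * base
    for (j in seq_len(ne)) {
      ph <- 2 * pi * field_hz * te_s[j] + coil$phase[l, , ]
      data[l, j, , ] <- amp * exp(1i * ph)
    }
  }
  if (noise_sd > 0) {
    n <- length(data)
    data <- data + complex(real = stats::rnorm(n, 0, noise_sd),
                           imaginary = stats::rnorm(n, 0, noise_sd))
  }
  multi_coil_image(data, te_s, timestamp)
}

#' Generate a synthetic CEST acquisition
#'
#' Synthesises a full multi-coil complex CEST experiment in image space with
#' known ground truth. For the saturated image at offset k (timestamp
#' \eqn{t_k}) the true field is the spatial polynomial plus the linear drift
#' at \eqn{t_k}; the Z-spectrum of each voxel is evaluated at the applied
#' offset minus the voxel's field expressed in ppm; and the per-channel
#' complex signal is
#' \deqn{S_{l,j} = m_l \, S_0 \, Z \, e^{i(2\pi \Delta B_0 TE_j + \Phi_{RX,l})} + \epsilon,}
#' with i.i.d. complex Gaussian noise \eqn{\epsilon}. Navigator images are
#' generated identically with Z = 1 just before each labelling block; the
#' dual-echo prescan and the unsaturated reference are acquired at t = 0
#' before drift onset; the WASSR prescan runs before that with its own
#' low-power train.
#'
#' @param cfg A [sim_config()].
#' @return A [cest_acquisition()] with populated ground truth.
#' @export
generate_acquisition <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  sc <- cfg$scanner
  r <- cfg$grid[1]; c <- cfg$grid[2]
  u <- matrix(seq(-1, 1, length.out = r), r, c)
  v <- matrix(seq(-1, 1, length.out = c), r, c, byrow = TRUE)
  support <- (u^2 + v^2) <= cfg$object_radius^2
  s0map <- ifelse(support, 1, 0)
  coil <- make_coil_profiles(cfg$n_channels, cfg$grid)
  b0 <- eval_b0_poly(cfg$b0_coef, cfg$grid)

  # schedule: navigator + labelling + readout + recovery per Z-point
  block <- cfg$nav_duration + train_duration(cfg$train) + r * cfg$tr_s +
    cfg$recovery_delay
  n_off <- length(cfg$offsets_ppm)
  tk <- seq_len(n_off) * block
  schedule <- saturation_schedule(cfg$offsets_ppm, tk)
  rate <- if (!is.null(cfg$drift_rate)) cfg$drift_rate
          else if (cfg$drift_total == 0) 0
          else cfg$drift_total / (max(tk) / 60)

  # noise-free Z-spectrum on a fine offset grid, shifted per voxel
  shift_margin <- max(abs(b0)) / sc$hz_per_ppm +
    abs(drift_profile(rate, max(tk))) / sc$hz_per_ppm + 0.1
  zgrid <- seq(min(cfg$offsets_ppm) - shift_margin,
               max(cfg$offsets_ppm) + shift_margin, by = cfg$zgrid_step_ppm)
  zfun <- stats::splinefun(zgrid, zspectrum_bm(cfg$pools, cfg$train, zgrid,
                                               0, sc), method = "natural")
  noise_ref <- mean((s0map * sqrt(apply(coil$mag^2, c(2, 3), sum)))[support])
  sigma <- cfg$noise_sd * noise_ref

  ones <- matrix(1, r, c)
  gre_prescan <- synth_image(ones, b0, cfg$te_s, 0, s0map, coil, sigma)
  s0_image <- synth_image(ones, b0, cfg$te_s, 0, s0map, coil, sigma)

  sat_images <- vector("list", n_off)
  nav_images <- if (cfg$with_nav) vector("list", n_off) else NULL
  cleanZ <- array(0, c(r, c, n_off))
  for (k in seq_len(n_off)) {
    field <- b0 + drift_profile(rate, tk[k])
    zmat <- matrix(zfun(cfg$offsets_ppm[k] - field / sc$hz_per_ppm), r, c)
    # Mz can be transiently negative right on resonance; the scanner records
    # it as a pi phase flip, and magnitude detection measures |Mz|
    cleanZ[, , k] <- abs(zmat)
    if (cfg$with_nav) {
      t_nav <- tk[k] - (train_duration(cfg$train) + r * cfg$tr_s)
      field_nav <- b0 + drift_profile(rate, t_nav)
      nav_images[[k]] <- synth_image(ones, field_nav, cfg$nav_te_s, t_nav,
                                     s0map, coil, sigma)
    }
    sat_images[[k]] <- synth_image(zmat, field, cfg$te_s, tk[k], s0map, coil,
                                   sigma)
  }

  wassr <- NULL
  if (cfg$with_wassr) {
    n_w <- length(cfg$wassr_offsets_ppm)
    w_block <- train_duration(cfg$wassr_train) + r * 0.0045 + 6
    tw <- (seq_len(n_w) - n_w - 1) * w_block          # all < 0: before drift
    w_margin <- max(abs(b0)) / sc$hz_per_ppm + 0.1
    wgrid <- seq(min(cfg$wassr_offsets_ppm) - w_margin,
                 max(cfg$wassr_offsets_ppm) + w_margin,
                 by = min(cfg$zgrid_step_ppm, 0.01))
    wfun <- stats::splinefun(wgrid, zspectrum_bm(cfg$pools, cfg$wassr_train,
                                                 wgrid, 0, sc),
                             method = "natural")
    wmag <- array(0, c(r, c, n_w))
    for (k in seq_len(n_w)) {
      zmat <- matrix(wfun(cfg$wassr_offsets_ppm[k] - b0 / sc$hz_per_ppm), r, c)
      img <- synth_image(zmat, b0, cfg$te_s[1], tw[k], s0map, coil, sigma)
      wmag[, , k] <- sos_magnitude(img)
    }
    w_s0 <- sos_magnitude(synth_image(ones, b0, cfg$te_s[1],
                                      tw[1] - w_block, s0map, coil, sigma))
    wassr <- list(schedule = saturation_schedule(cfg$wassr_offsets_ppm, tw),
                  magnitude = wmag, s0 = w_s0)
  }

  s0_sos_clean <- s0map * sqrt(apply(coil$mag^2, c(2, 3), sum))
  truth <- ground_truth(
    b0_map = b0, drift_rate_hz_min = rate,
    coil_phase = coil$phase, coil_mag = coil$mag,
    clean_zstack = z_stack(cleanZ, cfg$offsets_ppm, s0_sos_clean,
                           mask = support, timestamps_s = tk),
    support = support, noise_sd = sigma)

  cest_acquisition(schedule, sat_images, s0_image, gre_prescan, sc,
                   nav_images = nav_images, wassr = wassr, truth = truth)
}
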
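# Shared fixtures: small simulated acquisitions, cached per test run so the
# heavier generation happens once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small desk-scale configuration for module tests
tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(
    grid = c(24, 24), n_channels = 4,
    offsets_ppm = alternating_offsets(3, 0.3),
    wassr_offsets_ppm = alternating_offsets(0.8, 0.1),
    zgrid_step_ppm = 0.03, snr = Inf, drift_total = 0, seed = 1L)
  defaults[names(args)] <- args
  do.call(sim_config, defaults)
}

tiny_noiseless_acq <- function() {
  fixture("tiny_noiseless", generate_acquisition(tiny_cfg()))
}

tiny_noiseless_drift_acq <- function() {
  fixture("tiny_noiseless_drift",
          generate_acquisition(tiny_cfg(drift_total = 30,
                                        offsets_ppm = alternating_offsets(3, 0.15))))
}

tiny_noisy_acq <- function() {
  fixture("tiny_noisy", generate_acquisition(tiny_cfg(snr = 100)))
}

# single-pool continuous-wave steady-state Z (independent closed form)
cw_steady_state_z <- function(T1, T2, b1_ut, offset_ppm, scanner) {
  R1 <- 1 / T1; R2 <- 1 / T2
  w1 <- 2 * pi * scanner$gyromagnetic_ratio * b1_ut
  d <- 2 * pi * scanner$hz_per_ppm * offset_ppm
  R1 * (R2^2 + d^2) / (R1 * (R2^2 + d^2) + w1^2 * R2)
}

# symmetric Lorentzian dip Z-spectrum on a voxel grid, used as an analytic
# stand-in where full Bloch-McConnell physics is not the point
lorentzian_zstack <- function(centers, offsets, depth = 0.8, gamma = 0.6,
                              noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- dim(centers)
  vals <- array(0, c(d[1], d[2], length(offsets)))
  for (k in seq_along(offsets))
    vals[, , k] <- 1 - depth * gamma^2 /
      (gamma^2 + 4 * (offsets[k] - centers)^2)
  if (noise_sd > 0)
    vals <- vals + array(rnorm(length(vals), 0, noise_sd), dim(vals))
  z_stack(vals, offsets, s0 = matrix(1, d[1], d[2]),
          mask = matrix(TRUE, d[1], d[2]))
}

# uniform-field multi-coil image built directly (no simulator)
uniform_field_image <- function(field_hz, te_s, n_ch = 3, grid = c(12, 12),
                                coil_phase = NULL, mag = 1, noise_sd = 0,
                                timestamp = 0) {
  if (is.null(coil_phase)) coil_phase <- rep(0, n_ch)
  data <- array(complex(real = 0), c(n_ch, length(te_s), grid[1], grid[2]))
  for (l in seq_len(n_ch))
    for (j in seq_along(te_s))
      data[l, j, , ] <- mag * exp(1i * (2 * pi * field_hz * te_s[j] +
                                        coil_phase[l]))
  if (noise_sd > 0) {
    n <- length(data)
    data <- data + complex(real = rnorm(n, 0, noise_sd),
                           imaginary = rnorm(n, 0, noise_sd))
  }
  multi_coil_image(data, te_s, timestamp)
}
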
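# Phase-based field mapping: dual-echo Hermitian-inner-product combination,
# per-channel receive phase offsets, and single-echo mapping.

#' Dual-echo field map with Hermitian-inner-product coil combination
#'
#' Estimates the field offset per voxel from a dual-echo multi-coil image as
#' \deqn{\Delta B_0 = \angle \sum_l M_{2,l} M_{1,l} e^{i(\Phi_{2,l} - \Phi_{1,l})} / (2\pi\,\Delta TE),}
#' i.e. the angle of the magnitude-weighted channel sum of the echo phase
#' difference divided by the echo spacing. Any per-channel phase offset that
#' is common to both echoes cancels exactly in the echo difference. The
#' phase-difference map is unwrapped in 2D before conversion to Hz and
#' optionally smoothed with a spatial Hamming window. Fields beyond
#' `1/(2 dTE)` in magnitude alias unless the spatial unwrapping resolves
#' them.
#'
#' @param img Dual-echo [multi_coil_image()].
#' @param scanner A [scanner_profile()] (kept for interface symmetry; the
#'   conversion uses only the echo spacing).
#' @param smooth Apply Hamming smoothing to the map.
#' @param hamming_width Window width in voxels.
#' @param unwrap Apply 2D phase unwrapping before scaling.
#' @param method_tag Tag recorded in the returned series.
#' @return A [field_map_series()] with a single map in Hz.
#' @export
dual_echo_map <- function(img, scanner = scanner_profile(), smooth = TRUE,
                          hamming_width = 5, unwrap = TRUE,
                          method_tag = "gre2te") {
  stopifnot(inherits(img, "multi_coil_image"))
  if (n_echoes(img) != 2L)
    stop("dual_echo_map requires a 2-echo image", call. = FALSE)
  dte <- diff(img$echo_times)
  s1 <- img$data[, 1, , , drop = FALSE]
  s2 <- img$data[, 2, , , drop = FALSE]
  h <- apply(s2 * Conj(s1), c(3, 4), sum)
  psi <- Arg(h)
  if (unwrap) psi <- unwrap_2d(psi)
  map <- psi / (2 * pi * dte)
  if (smooth) map <- hamming_smooth(map, hamming_width)
  field_map_series(map, img$timestamp, method_tag)
}

#' Per-channel receive phase offsets
#'
#' Estimates the echo-time-independent phase each receive channel adds,
#' from a dual-echo prescan, by linear extrapolation of the two echo phases
#' to TE = 0:
#' \deqn{\Phi_{RX,l} = (TE_1 \Phi_{2,l} - TE_2 \Phi_{1,l}) / (TE_1 - TE_2).}
#' The field-induced phase cancels algebraically in this combination, so the
#' result is independent of the local field. The second echo phase is first
#' unwrapped along the echo dimension relative to the first. Voxels with
#' combined magnitude below 5% of its 99th percentile are masked; outside
#' the mask the offsets are extrapolated from a generalised-cross-validated
#' tensor-product spline smooth fitted to the unit phasor of the masked
#' offsets (`smooth = "full"` additionally replaces the values inside the
#' mask by the smooth).
#'
#' @param gre_prescan Dual-echo [multi_coil_image()].
#' @param smooth `"extrapolate"` (default), `"full"`, or `"none"`.
#' @param mask_frac Magnitude threshold as a fraction of the 99th-percentile
#'   combined magnitude.
#' @return An object of class `coil_offset_maps` with elements `phi_rx`
#'   (array `[channel, row, col]`, radians), `mask` and `smoothed`.
#' @export
coil_offsets <- function(gre_prescan, smooth = c("extrapolate", "full", "none"),
                         mask_frac = 0.05) {
  smooth <- match.arg(smooth)
  stopifnot(inherits(gre_prescan, "multi_coil_image"))
  if (n_echoes(gre_prescan) != 2L)
    stop("coil offset estimation requires a 2-echo prescan", call. = FALSE)
  te <- gre_prescan$echo_times
  sos <- sos_magnitude(gre_prescan)
  if (max(sos) == 0)
    stop("prescan magnitude is zero everywhere", call. = FALSE)
  thr <- mask_frac * stats::quantile(sos, 0.99, names = FALSE)
  mask <- sos > thr
  nch <- n_channels(gre_prescan)
  d <- grid_dim(gre_prescan)
  phi <- array(NA_real_, c(nch, d[1], d[2]))
  for (l in seq_len(nch)) {
    s1 <- gre_prescan$data[l, 1, , ]
    s2 <- gre_prescan$data[l, 2, , ]
    p1 <- Arg(s1)
    dphi <- Arg(s2 * Conj(s1))          # echo-dimension unwrap of phi2 - phi1
    phi[l, , ] <- wrap_phase(p1 - te[1] * dphi / diff(te))
  }
  if (smooth != "none") {
    for (l in seq_len(nch)) {
      sm <- smooth_phasor(phi[l, , ], mask)
      if (smooth == "full") phi[l, , ] <- sm
      else phi[l, , ][!mask] <- sm[!mask]
    }
  }
  structure(list(phi_rx = phi, mask = mask, smoothed = smooth != "none"),
            class = "coil_offset_maps")
}

# GCV tensor-product spline smooth of a phase map through its unit phasor,
# fitted on masked voxels and predicted everywhere
smooth_phasor <- function(ph, mask) {
  r <- nrow(ph); c <- ncol(ph)
  df <- data.frame(x = as.vector(row(ph)), y = as.vector(col(ph)),
                   re = as.vector(cos(ph)), im = as.vector(sin(ph)),
                   m = as.vector(mask))
  kk <- min(8, floor(sqrt(sum(mask)) / 2))
  kk <- max(kk, 3)
  fit_re <- mgcv::gam(re ~ te(x, y, k = kk), data = df[df$m, ],
                      method = "GCV.Cp")
  fit_im <- mgcv::gam(im ~ te(x, y, k = kk), data = df[df$m, ],
                      method = "GCV.Cp")
  pre <- stats::predict(fit_re, newdata = df)
  pim <- stats::predict(fit_im, newdata = df)
  matrix(atan2(pim, pre), r, c)
}

#' Single-echo field map using prescan coil offsets
#'
#' Dynamic field mapping from a single-echo readout: the per-channel receive
#' phase offsets (assumed time-invariant, estimated once from a dual-echo
#' prescan) are subtracted before the magnitude-weighted channel combination,
#' \deqn{\Delta B_0 = \angle \sum_l M_{1,l} e^{i(\Phi_{1,l} - \Phi_{RX,l})} / (2\pi\,TE_1).}
#' The aliasing period is `1/TE1` (about 575 Hz at TE1 = 1.74 ms).
#'
#' @param img Single-echo [multi_coil_image()] (a dual-echo image is reduced
#'   with [first_echo()] by the caller).
#' @param offsets A `coil_offset_maps` object covering the same grid.
#' @param scanner A [scanner_profile()].
#' @param smooth,hamming_width,unwrap As in [dual_echo_map()].
#' @param method_tag Tag recorded in the returned series.
#' @return A [field_map_series()] with a single map in Hz.
#' @export
single_echo_map <- function(img, offsets, scanner = scanner_profile(),
                            smooth = TRUE, hamming_width = 5, unwrap = TRUE,
                            method_tag = "cestgre1te") {
  stopifnot(inherits(img, "multi_coil_image"))
  if (n_echoes(img) != 1L)
    stop("single_echo_map requires a 1-echo image", call. = FALSE)
  if (is.null(offsets) || !inherits(offsets, "coil_offset_maps"))
    stop("per-channel coil offset maps are required", call. = FALSE)
  d <- grid_dim(img)
  if (!identical(dim(offsets$phi_rx)[2:3], d) ||
      dim(offsets$phi_rx)[1] != n_channels(img))
    stop("coil offset maps do not cover this image grid", call. = FALSE)
  te1 <- img$echo_times[1]
  h <- matrix(complex(real = 0), d[1], d[2])
  for (l in seq_len(n_channels(img)))
    h <- h + img$data[l, 1, , ] * exp(-1i * offsets$phi_rx[l, , ])
  psi <- Arg(h)
  if (unwrap) psi <- unwrap_2d(psi)
  map <- psi / (2 * pi * te1)
  if (smooth) map <- hamming_smooth(map, hamming_width)
  field_map_series(map, img$timestamp, method_tag)
}

#' Per-offset dynamic field-map series
#'
#' Builds one field map per saturation offset from the acquisition itself:
#' `"cestgre2te"` applies [dual_echo_map()] to each saturated dual-echo CEST
#' readout, `"cestgre1te"` applies [single_echo_map()] to the first echo of
#' each readout using coil offsets from the prescan, and `"nav2te"` applies
#' [dual_echo_map()] to the interleaved navigator images. For the intrinsic
#' methods (`cestgre2te`, `cestgre1te`) the maps measured while saturating
#' near water (|offset| below `near_water_ppm`) are corrupted by the low SNR
#' of the saturated signal; they are flagged low-confidence and replaced,
#' voxel-wise, by linear temporal interpolation between the nearest valid
#' maps.
#'
#' @param acq A [cest_acquisition()].
#' @param method `"cestgre2te"`, `"cestgre1te"` or `"nav2te"`.
#' @param smooth,hamming_width As in [dual_echo_map()].
#' @param near_water_ppm Exclusion half-width around water for intrinsic
#'   methods (the navigator is unaffected by the labelling and is not
#'   excluded).
#' @return A [field_map_series()] with one map per offset.
#' @export
dynamic_series <- function(acq, method = c("cestgre2te", "cestgre1te",
                                           "nav2te"),
                           smooth = TRUE, hamming_width = 5,
                           near_water_ppm = 0.33) {
  method <- match.arg(method)
  stopifnot(inherits(acq, "cest_acquisition"))
  sch <- acq$schedule
  n <- nrow(sch)
  if (method == "nav2te" && is.null(acq$nav_images))
    stop("nav2te requires navigator images", call. = FALSE)
  offs <- if (method == "cestgre1te")
    coil_offsets(acq$gre_prescan) else NULL
  maps <- vector("list", n)
  ts <- numeric(n)
  for (k in seq_len(n)) {
    fm <- switch(method,
      cestgre2te = dual_echo_map(acq$sat_images[[k]], acq$scanner,
                                 smooth, hamming_width,
                                 method_tag = "gre2te"),
      nav2te = dual_echo_map(acq$nav_images[[k]], acq$scanner,
                             smooth, hamming_width, method_tag = "gre2te"),
      cestgre1te = single_echo_map(first_echo(acq$sat_images[[k]]), offs,
                                   acq$scanner, smooth, hamming_width))
    maps[[k]] <- fm$values[[1]]
    ts[k] <- fm$timestamps[1]
  }
  low <- integer(0)
  if (method != "nav2te") {
    low <- which(abs(sch$offset_ppm) < near_water_ppm)
    maps <- interp_excluded_maps(maps, ts, low)
  }
  field_map_series(maps, ts, method, source_offsets = sch$offset_ppm,
                   low_confidence = low)
}

# replace excluded maps by voxel-wise linear temporal interpolation between
# the nearest valid neighbours (constant extrapolation at the ends)
interp_excluded_maps <- function(maps, ts, excluded) {
  if (length(excluded) == 0L) return(maps)
  valid <- setdiff(seq_along(maps), excluded)
  if (length(valid) < 2L) return(maps)
  tv <- ts[valid]
  for (k in excluded) {
    t0 <- ts[k]
    if (t0 <= min(tv)) {
      maps[[k]] <- maps[[valid[which.min(tv)]]]
    } else if (t0 >= max(tv)) {
      maps[[k]] <- maps[[valid[which.max(tv)]]]
    } else {
      i2 <- which(tv > t0)[1]
      i1 <- max(which(tv < t0))
      w <- (t0 - tv[i1]) / (tv[i2] - tv[i1])
      maps[[k]] <- (1 - w) * maps[[valid[i1]]] + w * maps[[valid[i2]]]
    }
  }
  maps
}
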
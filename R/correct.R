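# Z-stack assembly, static and dynamic field correction, and MTR-asymmetry
# quantification.

#' Assemble the Z-stack of an acquisition
#'
#' For every voxel and offset, the Z value is the echo-averaged
#' sum-of-squares channel-combined saturated magnitude divided by the
#' reference magnitude computed identically from the unsaturated image.
#' Single-echo readouts use that echo alone. Voxels whose reference
#' magnitude falls below `s0_frac` of its maximum are excluded by the mask.
#'
#' @param acq A [cest_acquisition()].
#' @param s0_frac Reference-magnitude mask threshold (fraction of maximum).
#' @return A [z_stack()] carrying the applied offsets and timestamps.
#' @export
build_zstack <- function(acq, s0_frac = 0.2) {
  stopifnot(inherits(acq, "cest_acquisition"))
  s0 <- sos_magnitude(acq$s0_image)
  mask <- s0 > s0_frac * max(s0)
  n <- nrow(acq$schedule)
  d <- dim(s0)
  vals <- array(NA_real_, c(d[1], d[2], n))
  for (k in seq_len(n))
    vals[, , k] <- sos_magnitude(acq$sat_images[[k]]) / s0
  z_stack(vals, acq$schedule$offset_ppm, s0, mask = mask,
          timestamps_s = acq$schedule$timestamp_s)
}

# Shared resampling core. delta_ppm is a [voxel, offset] matrix of apparent
# shifts; the measured value at applied offset w is a sample of the true
# spectrum at w - delta, so the knots (applied - delta, Z) are interpolated
# with a shape-preserving monotone Hermite spline onto the nominal (sorted)
# offset grid (a polynomial spline overshoots on the steep walls of the
# direct-saturation dip and leaks spurious asymmetry into MTRasym).
# Queries outside the covered range give NA. Both correction modes run
# through this function, so a constant per-offset series reproduces the
# static path bit for bit.
resample_zstack <- function(z, delta_ppm, uncorrectable = NULL) {
  d <- dim(z$s0)
  offs <- z$offsets_ppm
  nominal <- sort(offs)
  n <- length(offs)
  vals <- matrix(z$values, prod(d), n)
  out <- matrix(NA_real_, prod(d), n)
  span <- diff(range(offs))
  lin <- which(z$mask)
  for (i in seq_along(lin)) {
    vx <- lin[i]
    if (!is.null(uncorrectable) && uncorrectable[vx]) next
    dl <- delta_ppm[vx, ]
    if (any(!is.finite(dl))) next
    kx <- offs - dl
    ky <- vals[vx, ]
    ord <- order(kx)
    kx <- kx[ord]; ky <- ky[ord]
    # average duplicated knots (possible after large drift)
    if (any(diff(kx) < 1e-9)) {
      grp <- cumsum(c(TRUE, diff(kx) >= 1e-9))
      kx <- tapply(kx, grp, mean)
      ky <- tapply(ky, grp, mean)
    }
    f <- stats::splinefun(kx, ky, method = "monoH.FC")
    inside <- nominal >= kx[1] - 1e-12 & nominal <= kx[length(kx)] + 1e-12
    out[vx, inside] <- f(nominal[inside])
  }
  flagged <- if (is.null(uncorrectable)) NULL else sum(uncorrectable & z$mask)
  zz <- z_stack(array(out, c(d[1], d[2], n)), nominal, z$s0, mask = z$mask)
  zz$uncorrectable_n <- flagged
  zz$span_ppm <- span
  zz
}

#' Static field correction of a Z-stack
#'
#' Shifts each voxel's entire Z-spectrum by a single apparent displacement
#' \eqn{\delta\omega = \Delta B_0 / \gamma} derived from one field map: the
#' corrected value at nominal offset \eqn{\Delta\omega} is the measured
#' curve resampled (shape-preserving monotone Hermite spline) at applied
#' offset
#' \eqn{\Delta\omega + \delta\omega}. Points shifted outside the sampled
#' range become `NA`; voxels with `|delta| > span/2` are flagged
#' uncorrectable and left `NA` entirely.
#'
#' @param z A [z_stack()].
#' @param map A single-map [field_map_series()] (Hz).
#' @param scanner A [scanner_profile()] for the Hz-to-ppm conversion.
#' @return A corrected [z_stack()] on the sorted nominal offset grid.
#' @export
correct_static <- function(z, map, scanner = scanner_profile()) {
  stopifnot(inherits(z, "z_stack"), inherits(map, "field_map_series"))
  if (n_maps(map) != 1L)
    stop("static correction takes exactly one field map", call. = FALSE)
  delta <- as.vector(map$values[[1]]) / scanner$hz_per_ppm
  span <- diff(range(z$offsets_ppm))
  uncor <- is.finite(delta) & abs(delta) > span / 2
  dmat <- matrix(delta, length(delta), length(z$offsets_ppm))
  resample_zstack(z, dmat, uncorrectable = uncor)
}

#' Dynamic (per-offset) field correction of a Z-stack
#'
#' Corrects each Z-spectral point with its own field map: the point measured
#' at applied offset \eqn{\Delta\omega_k} is located at true offset
#' \eqn{\Delta\omega_k - \delta\omega_k} and the resulting scatter is
#' interpolated (shape-preserving monotone Hermite spline, after sorting by
#' true offset and
#' averaging duplicates) onto the nominal offset grid. A constant series
#' reduces exactly to [correct_static()].
#'
#' @param z A [z_stack()].
#' @param series A [field_map_series()] with one map per offset, in the
#'   acquisition order of `z$offsets_ppm`.
#' @param scanner A [scanner_profile()].
#' @return A corrected [z_stack()] on the sorted nominal offset grid.
#' @export
correct_dynamic <- function(z, series, scanner = scanner_profile()) {
  stopifnot(inherits(z, "z_stack"), inherits(series, "field_map_series"))
  n <- length(z$offsets_ppm)
  if (n_maps(series) != n)
    stop("dynamic correction needs one field map per offset", call. = FALSE)
  nv <- prod(dim(z$s0))
  dmat <- matrix(NA_real_, nv, n)
  for (k in seq_len(n))
    dmat[, k] <- as.vector(series$values[[k]]) / scanner$hz_per_ppm
  resample_zstack(z, dmat)
}

#' MTR-asymmetry map
#'
#' Computes the asymmetric magnetisation transfer ratio
#' \deqn{MTR_{asym}(\Delta\omega) = Z(-\Delta\omega) - Z(+\Delta\omega)}
#' (the Z values are already S0-normalised) and averages it over the nominal
#' offsets falling inside the positive integration range (endpoints
#' inclusive), reported in percent. The offset grid must be symmetric about
#' 0; missing (`NA`) corrected points are excluded from the range mean.
#'
#' @param z A corrected [z_stack()].
#' @param range Positive integration range `c(ppm_lo, ppm_hi)`.
#' @param roi Optional logical ROI matrix for the summary statistics.
#' @param method_tag Tag carried into the map.
#' @return An [mtr_asym_map()].
#' @export
mtr_asym <- function(z, range = c(0.3, 1.0), roi = NULL,
                     method_tag = "truth") {
  stopifnot(inherits(z, "z_stack"), length(range) == 2L)
  offs <- z$offsets_ppm
  srt <- sort(offs)
  if (max(abs(srt + rev(srt))) > 1e-9)
    stop("offset grid is not symmetric about 0 ppm", call. = FALSE)
  pos <- srt[srt >= range[1] - 1e-12 & srt <= range[2] + 1e-12]
  if (length(pos) == 0L)
    stop("no offsets inside the integration range", call. = FALSE)
  d <- dim(z$s0)
  acc <- matrix(0, d[1], d[2]); cnt <- matrix(0, d[1], d[2])
  for (p in pos) {
    ip <- which.min(abs(offs - p))
    im <- which.min(abs(offs + p))
    dv <- z$values[, , im] - z$values[, , ip]
    okv <- is.finite(dv)
    acc[okv] <- acc[okv] + dv[okv]
    cnt[okv] <- cnt[okv] + 1
  }
  vals <- 100 * acc / cnt
  vals[cnt == 0] <- NA_real_
  vals[!z$mask] <- NA_real_
  m <- mtr_asym_map(vals, range, method_tag)
  if (!is.null(roi)) {
    if (any(is.finite(vals[roi]))) {
      st <- roi_stats(m, roi)
      m$roi_mean <- st$mean; m$roi_sd <- st$sd; m$roi_n <- st$n
    } else {
      warning("no finite MTRasym voxels inside the ROI", call. = FALSE)
      m$roi_n <- 0L
    }
  }
  m
}

#' ROI summary of an MTR-asymmetry map
#'
#' @param map An [mtr_asym_map()] (or plain matrix).
#' @param mask Logical ROI matrix; must select at least one finite voxel.
#' @return List with `mean`, `sd` and `n` over the finite masked voxels.
#' @export
roi_stats <- function(map, mask) {
  vals <- if (inherits(map, "mtr_asym_map")) map$values else map
  stopifnot(is.matrix(vals), is.logical(mask),
            identical(dim(mask), dim(vals)))
  if (!any(mask)) stop("ROI mask is empty", call. = FALSE)
  v <- vals[mask]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("ROI contains no finite voxels", call. = FALSE)
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}
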
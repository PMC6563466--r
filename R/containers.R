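#' CEST acquisition container
#'
#' Bundles everything one CEST experiment produces: the saturation schedule,
#' one saturated multi-coil image per applied offset, the unsaturated
#' reference image, the dual-echo gradient-echo prescan, and optionally a
#' per-offset navigator series, a WASSR prescan, and (for simulated data)
#' the ground truth.
#'
#' @param schedule A [saturation_schedule()].
#' @param sat_images List of [multi_coil_image()], one per schedule row.
#' @param s0_image Unsaturated reference [multi_coil_image()].
#' @param gre_prescan Dual-echo gradient-echo prescan [multi_coil_image()].
#' @param scanner A [scanner_profile()].
#' @param nav_images Optional list of navigator images, one per offset.
#' @param wassr Optional WASSR prescan: a list with elements `schedule`
#'   (a [saturation_schedule()]), `magnitude` (array `[row, col, offset]` of
#'   channel-combined magnitudes) and `s0` (matrix of unsaturated combined
#'   magnitude).
#' @param truth Optional [ground_truth()].
#' @return An object of class `cest_acquisition`.
#' @export
cest_acquisition <- function(schedule, sat_images, s0_image, gre_prescan,
                             scanner, nav_images = NULL, wassr = NULL,
                             truth = NULL) {
  stopifnot(inherits(schedule, "saturation_schedule"),
            inherits(s0_image, "multi_coil_image"),
            inherits(gre_prescan, "multi_coil_image"),
            inherits(scanner, "scanner_profile"))
  if (length(sat_images) != nrow(schedule))
    stop("sat_images length must equal the schedule length", call. = FALSE)
  if (!all(vapply(sat_images, inherits, TRUE, "multi_coil_image")))
    stop("sat_images must all be multi_coil_image objects", call. = FALSE)
  if (!is.null(nav_images)) {
    if (length(nav_images) != nrow(schedule))
      stop("nav_images, when present, must match the schedule length",
           call. = FALSE)
    if (!all(vapply(nav_images, inherits, TRUE, "multi_coil_image")))
      stop("nav_images must all be multi_coil_image objects", call. = FALSE)
  }
  if (n_echoes(gre_prescan) != 2L)
    stop("gre_prescan must have exactly 2 echoes", call. = FALSE)
  if (!is.null(wassr)) {
    stopifnot(is.list(wassr),
              inherits(wassr$schedule, "saturation_schedule"),
              is.array(wassr$magnitude),
              length(dim(wassr$magnitude)) == 3L,
              dim(wassr$magnitude)[3] == nrow(wassr$schedule),
              is.matrix(wassr$s0))
  }
  if (!is.null(truth)) stopifnot(inherits(truth, "cest_ground_truth"))
  structure(list(schedule = schedule, sat_images = sat_images,
                 s0_image = s0_image, gre_prescan = gre_prescan,
                 scanner = scanner, nav_images = nav_images,
                 wassr = wassr, truth = truth),
            class = "cest_acquisition")
}

#' @export
print.cest_acquisition <- function(x, ...) {
  g <- grid_dim(x$s0_image)
  cat(sprintf(
    "<cest_acquisition> %d offsets [%.3g..%.3g ppm], %d channel(s), %dx%d grid\n",
    nrow(x$schedule), min(x$schedule$offset_ppm), max(x$schedule$offset_ppm),
    n_channels(x$s0_image), g[1], g[2]))
  cat(sprintf("  navigator: %s, WASSR: %s, ground truth: %s\n",
              if (is.null(x$nav_images)) "no" else "yes",
              if (is.null(x$wassr)) "no" else "yes",
              if (is.null(x$truth)) "no" else "yes"))
  invisible(x)
}

#' Simulation ground truth
#'
#' Carried alongside simulated acquisitions so that estimators can be tested
#' by parameter recovery. The temporal drift is linear at `drift_rate_hz_min`
#' Hz/min, starting at 0 at t = 0 (prescans acquired at t <= 0 see no drift).
#'
#' @param b0_map True static field offset map in Hz, `[row, col]`.
#' @param drift_rate_hz_min Linear drift rate in Hz per minute.
#' @param coil_phase True per-channel receive phase offsets (radians) in
#'   `(-pi, pi]`, array `[channel, row, col]`.
#' @param coil_mag Per-channel magnitude sensitivity, array
#'   `[channel, row, col]`.
#' @param clean_zstack The noise-free magnitude-detected [z_stack()] actually
#'   generated (including any field shift and drift, before noise).
#' @param support Logical matrix marking the simulated object.
#' @param noise_sd Standard deviation of the complex noise added per
#'   real/imaginary component.
#' @return An object of class `cest_ground_truth`.
#' @export
ground_truth <- function(b0_map, drift_rate_hz_min, coil_phase, coil_mag,
                         clean_zstack = NULL, support = NULL, noise_sd = 0) {
  stopifnot(is.matrix(b0_map), all(is.finite(b0_map)),
            is.numeric(drift_rate_hz_min), length(drift_rate_hz_min) == 1L,
            is.array(coil_phase), length(dim(coil_phase)) == 3L,
            is.array(coil_mag), identical(dim(coil_mag), dim(coil_phase)))
  if (any(coil_phase <= -pi - 1e-12) || any(coil_phase > pi + 1e-12))
    stop("coil phase offsets must lie in (-pi, pi]", call. = FALSE)
  if (!is.null(clean_zstack)) stopifnot(inherits(clean_zstack, "z_stack"))
  structure(list(b0_map = b0_map, drift_rate_hz_min = drift_rate_hz_min,
                 coil_phase = coil_phase, coil_mag = coil_mag,
                 clean_zstack = clean_zstack, support = support,
                 noise_sd = noise_sd),
            class = "cest_ground_truth")
}

#' True drift at a set of timestamps
#'
#' @param truth A [ground_truth()].
#' @param t Timestamps in seconds.
#' @return Drift in Hz (0 for t <= 0).
#' @export
truth_drift <- function(truth, t) drift_profile(truth$drift_rate_hz_min, t)

valid_method_tags <- c("minz", "wassr", "gre2te",
                       "cestgre2te", "cestgre1te", "nav2te", "truth")

#' Field-map series
#'
#' One field map in Hz per saturation offset (dynamic methods) or a single
#' map (static methods), each with a timestamp and, for dynamic maps, the
#' saturation offset that was applied while it was measured. `NA` voxels mark
#' estimates flagged invalid; infinite values are rejected.
#'
#' @param values List of field maps (matrices, Hz) or a single matrix.
#' @param timestamps Timestamp in seconds per map.
#' @param method_tag One of `"minz"`, `"wassr"`, `"gre2te"`, `"cestgre2te"`,
#'   `"cestgre1te"`, `"nav2te"`, `"truth"`.
#' @param source_offsets Applied offset in ppm per map (`NA` for static maps).
#' @param low_confidence Optional integer indices of maps flagged
#'   low-confidence (e.g. near-water intrinsic maps replaced by temporal
#'   interpolation).
#' @return An object of class `field_map_series`.
#' @export
field_map_series <- function(values, timestamps, method_tag,
                             source_offsets = NA_real_,
                             low_confidence = integer(0)) {
  if (is.matrix(values)) values <- list(values)
  stopifnot(is.list(values), length(values) >= 1L,
            all(vapply(values, is.matrix, TRUE)))
  method_tag <- match.arg(method_tag, valid_method_tags)
  n <- length(values)
  timestamps <- rep_len(as.numeric(timestamps), n)
  source_offsets <- rep_len(as.numeric(source_offsets), n)
  if (any(vapply(values, function(v) any(is.infinite(v)), TRUE)))
    stop("field maps must not contain infinite values", call. = FALSE)
  static <- method_tag %in% c("minz", "wassr", "gre2te", "truth")
  if (static && n != 1L)
    stop("static methods yield exactly one map", call. = FALSE)
  structure(list(values = values, timestamps = timestamps,
                 method_tag = method_tag, source_offsets = source_offsets,
                 low_confidence = as.integer(low_confidence)),
            class = "field_map_series")
}

#' @export
print.field_map_series <- function(x, ...) {
  rng <- range(unlist(lapply(x$values, function(v) range(v, na.rm = TRUE))))
  cat(sprintf("<field_map_series> method %s, %d map(s), range [%.2f, %.2f] Hz\n",
              x$method_tag, length(x$values), rng[1], rng[2]))
  invisible(x)
}

#' @rdname field_map_series
#' @param x A `field_map_series`.
#' @export
n_maps <- function(x) length(x$values)

#' Z-stack
#'
#' Normalised Z-spectrum values per voxel and applied offset: the echo-
#' averaged, sum-of-squares channel-combined saturated magnitude divided by
#' the reference magnitude computed identically.
#'
#' @param values Array `[row, col, offset]` of dimensionless Z values.
#' @param offsets_ppm Applied-offset axis in ppm (acquisition order allowed).
#' @param s0 Reference magnitude matrix `[row, col]`.
#' @param mask Logical matrix of voxels with usable reference signal.
#' @param timestamps_s Optional acquisition timestamp per offset.
#' @return An object of class `z_stack`.
#' @export
z_stack <- function(values, offsets_ppm, s0, mask = NULL, timestamps_s = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L,
            length(offsets_ppm) == dim(values)[3],
            is.matrix(s0), identical(dim(s0), dim(values)[1:2]))
  if (is.null(mask)) mask <- s0 > 0
  stopifnot(is.logical(mask), identical(dim(mask), dim(s0)))
  if (any(s0[mask] <= 0))
    stop("reference magnitude must be positive inside the mask", call. = FALSE)
  if (!is.null(timestamps_s))
    stopifnot(length(timestamps_s) == length(offsets_ppm))
  structure(list(values = values, offsets_ppm = as.numeric(offsets_ppm),
                 s0 = s0, mask = mask, timestamps_s = timestamps_s),
            class = "z_stack")
}

#' @export
print.z_stack <- function(x, ...) {
  cat(sprintf("<z_stack> %dx%d voxels, %d offsets [%.3g..%.3g ppm]\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$offsets_ppm), max(x$offsets_ppm)))
  invisible(x)
}

#' MTR-asymmetry map
#'
#' Per-voxel asymmetric magnetisation transfer ratio in percent, averaged
#' over a stated positive integration range, with an optional ROI summary.
#'
#' @param values Matrix of MTRasym values in percent.
#' @param range Integration range `c(ppm_lo, ppm_hi)`, both positive.
#' @param method_tag Correction method that produced the underlying Z-stack.
#' @param roi_mean,roi_sd,roi_n Optional ROI summary statistics.
#' @return An object of class `mtr_asym_map`.
#' @export
mtr_asym_map <- function(values, range, method_tag = "truth",
                         roi_mean = NA_real_, roi_sd = NA_real_,
                         roi_n = NA_integer_) {
  stopifnot(is.matrix(values), length(range) == 2L)
  if (!(range[1] < range[2]) || any(range <= 0))
    stop("integration range must satisfy 0 < ppm_lo < ppm_hi", call. = FALSE)
  structure(list(values = values, range = as.numeric(range),
                 method_tag = method_tag, roi_mean = roi_mean,
                 roi_sd = roi_sd, roi_n = roi_n),
            class = "mtr_asym_map")
}

#' @export
print.mtr_asym_map <- function(x, ...) {
  cat(sprintf("<mtr_asym_map> range %.2f-%.2f ppm (%s)", x$range[1],
              x$range[2], x$method_tag))
  if (is.finite(x$roi_mean))
    cat(sprintf(", ROI %.3f +/- %.3f %% (n=%d)", x$roi_mean, x$roi_sd, x$roi_n))
  cat("\n")
  invisible(x)
}
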
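#' Scanner profile
#'
#' Describes the static field of the scanner and the proton gyromagnetic
#' ratio, from which the Hz-per-ppm conversion factor for the water resonance
#' is derived. At 7 T the factor is about 298 Hz/ppm, so a 0.05 ppm offset
#' step corresponds to roughly 15 Hz.
#'
#' @param static_field Static field strength in tesla (must be positive).
#' @param gyromagnetic_ratio Proton gyromagnetic ratio in MHz per tesla
#'   (equivalently Hz per microtesla).
#' @return An object of class `scanner_profile` with elements `static_field`,
#'   `gyromagnetic_ratio` and the derived `hz_per_ppm`.
#' @examples
#' sc <- scanner_profile(7)
#' sc$hz_per_ppm  # ~298 Hz/ppm
#' @export
scanner_profile <- function(static_field = 7, gyromagnetic_ratio = 42.577) {
  stopifnot(is.numeric(static_field), length(static_field) == 1L,
            is.finite(static_field),
            is.numeric(gyromagnetic_ratio), length(gyromagnetic_ratio) == 1L,
            is.finite(gyromagnetic_ratio), gyromagnetic_ratio > 0)
  if (static_field <= 0)
    stop("static_field must be > 0 tesla", call. = FALSE)
  structure(
    list(static_field = static_field,
         gyromagnetic_ratio = gyromagnetic_ratio,
         hz_per_ppm = static_field * gyromagnetic_ratio),
    class = "scanner_profile")
}

#' @export
print.scanner_profile <- function(x, ...) {
  cat(sprintf("<scanner_profile> %.3g T, gamma %.4g MHz/T, %.4g Hz/ppm\n",
              x$static_field, x$gyromagnetic_ratio, x$hz_per_ppm))
  invisible(x)
}

#' Convert between Hz and ppm for a scanner
#'
#' All unit conversions in the package go through the scanner profile so that
#' field maps (Hz) and spectral offsets (ppm) stay consistent.
#'
#' @param x Numeric vector/array to convert.
#' @param scanner A [scanner_profile()].
#' @return Converted numeric of the same shape.
#' @export
hz_to_ppm <- function(x, scanner) x / scanner$hz_per_ppm

#' @rdname hz_to_ppm
#' @export
ppm_to_hz <- function(x, scanner) x * scanner$hz_per_ppm

#' Alternating descending saturation-offset ordering
#'
#' Builds the offset ordering used for Z-spectral sampling: alternating signs
#' with decreasing magnitude, starting from the negative extreme and ending at
#' 0 ppm, e.g. (-4.5, +4.5, -4.35, +4.35, ..., 0). Sampling mirrored offsets
#' back-to-back minimises the differential field drift between the two sides
#' of the Z-spectrum.
#'
#' @param max_ppm Largest absolute offset in ppm.
#' @param step_ppm Offset increment in ppm.
#' @return Numeric vector of offsets in acquisition order.
#' @examples
#' alternating_offsets(4.5, 0.15)  # 61 offsets
#' @export
alternating_offsets <- function(max_ppm, step_ppm) {
  stopifnot(max_ppm > 0, step_ppm > 0)
  mags <- seq(max_ppm, 0, by = -step_ppm)
  out <- numeric(0)
  for (m in mags) {
    if (m < step_ppm / 2) out <- c(out, 0)
    else out <- c(out, -m, m)
  }
  out
}

is_alternating_descending <- function(offsets, tol = 1e-9) {
  n <- length(offsets)
  if (n < 2L) return(TRUE)
  a <- abs(offsets)
  if (any(diff(a) > tol)) return(FALSE)
  s <- sign(offsets[abs(offsets) > tol])
  if (length(s) >= 2L && any(s[-1] == s[-length(s)] &
                             abs(diff(a[seq_along(s)])) < tol)) {
    # mirrored pair must alternate sign
    return(FALSE)
  }
  TRUE
}

#' Saturation schedule
#'
#' An ordered table of applied saturation offsets with their acquisition
#' timestamps. Offsets are expected in the alternating descending-magnitude
#' order produced by [alternating_offsets()]; timestamps must be strictly
#' increasing.
#'
#' @param offsets_ppm Applied offsets in acquisition order (ppm).
#' @param timestamps_s Acquisition timestamps in seconds, strictly increasing.
#' @param check_order Reject orderings that are not alternating-descending.
#' @return A data frame of class `saturation_schedule` with columns
#'   `index`, `offset_ppm`, `timestamp_s`.
#' @export
saturation_schedule <- function(offsets_ppm, timestamps_s, check_order = TRUE) {
  stopifnot(is.numeric(offsets_ppm), is.numeric(timestamps_s),
            length(offsets_ppm) == length(timestamps_s),
            length(offsets_ppm) >= 1L,
            all(is.finite(offsets_ppm)), all(is.finite(timestamps_s)))
  if (any(diff(timestamps_s) <= 0))
    stop("schedule timestamps must be strictly increasing", call. = FALSE)
  if (check_order && !is_alternating_descending(offsets_ppm))
    stop("offsets do not follow alternating descending-magnitude order",
         call. = FALSE)
  structure(
    data.frame(index = seq_along(offsets_ppm),
               offset_ppm = offsets_ppm,
               timestamp_s = timestamps_s),
    class = c("saturation_schedule", "data.frame"))
}
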
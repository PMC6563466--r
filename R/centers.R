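# Magnitude-based water-line referencing: Z-spectrum minimum and WASSR
# Lorentzian fitting.

#' Water-line position from the Z-spectrum minimum
#'
#' For each voxel, fits a smoothing spline (generalised cross-validation,
#' with a degrees-of-freedom cap that prevents the spline from chasing
#' noise) through the Z-spectrum and locates the minimum on a dense offset
#' grid. The minimum location is the apparent water-line displacement
#' in ppm. Voxels whose minimum falls on the boundary of the sampled range
#' are flagged invalid (`NA`); exact ties are broken towards the smallest
#' absolute displacement.
#'
#' @param z A [z_stack()]; offsets must span the water line with at least 7
#'   points.
#' @param mask Logical matrix of voxels to process (defaults to the
#'   Z-stack mask).
#' @param grid_step_ppm Search grid step (at most 0.001 ppm).
#' @param df_cap Upper bound on the spline's effective degrees of freedom.
#' @return Matrix of water-line displacements in ppm (`NA` where invalid or
#'   outside the mask).
#' @export
minz_center <- function(z, mask = NULL, grid_step_ppm = 0.001, df_cap = 25) {
  stopifnot(inherits(z, "z_stack"))
  offs <- z$offsets_ppm
  if (length(offs) < 7L)
    stop("minz referencing needs at least 7 Z-spectral points", call. = FALSE)
  if (max(offs) <= 0 || min(offs) >= 0)
    stop("offsets must span the water line", call. = FALSE)
  if (is.null(mask)) mask <- z$mask
  ord <- order(offs)
  x <- offs[ord]
  dense <- seq(x[1], x[length(x)], by = min(grid_step_ppm, 0.001))
  out <- matrix(NA_real_, nrow(z$s0), ncol(z$s0))
  vals <- matrix(z$values, prod(dim(z$s0)), length(offs))
  lin <- which(mask)
  for (i in seq_along(lin)) {
    y <- vals[lin[i], ord]
    if (any(!is.finite(y))) next
    fit <- stats::smooth.spline(x, y, cv = FALSE)
    if (fit$df > df_cap)
      fit <- stats::smooth.spline(x, y, df = df_cap)
    p <- stats::predict(fit, dense)$y
    mn <- min(p)
    cand <- dense[p <= mn + 1e-12]
    ctr <- cand[which.min(abs(cand))]
    if (ctr <= dense[1] + 1e-12 || ctr >= dense[length(dense)] - 1e-12)
      next                                   # boundary minimum: invalid
    out[lin[i]] <- ctr
  }
  out
}

#' Water-line position by WASSR Lorentzian fitting
#'
#' Fits the direct-saturation line of a low-power, narrow-range Z-series
#' voxel-wise with the Lorentzian dip
#' \deqn{S(\Delta\omega) = b - a\,\Gamma^2 / (\Gamma^2 + 4(\Delta\omega - \delta\omega)^2)}
#' by Levenberg-Marquardt least squares and returns the centre
#' \eqn{\delta\omega} in ppm. Non-converged voxels are flagged `NA`.
#'
#' @param wassr_z A [z_stack()] holding the WASSR series (typically +/-0.8
#'   ppm in 0.05-ppm steps at low power).
#' @param mask Logical matrix of voxels to process.
#' @return A list with `center` (ppm matrix, `NA` where invalid), `rss`
#'   (residual sum of squares) and `ok` (logical convergence matrix).
#' @export
wassr_center <- function(wassr_z, mask = NULL) {
  stopifnot(inherits(wassr_z, "z_stack"))
  offs <- wassr_z$offsets_ppm
  if (is.null(mask)) mask <- wassr_z$mask
  ord <- order(offs)
  x <- offs[ord]
  ctr <- matrix(NA_real_, nrow(wassr_z$s0), ncol(wassr_z$s0))
  rss <- matrix(NA_real_, nrow(ctr), ncol(ctr))
  ok <- matrix(FALSE, nrow(ctr), ncol(ctr))
  vals <- matrix(wassr_z$values, prod(dim(ctr)), length(offs))
  lin <- which(mask)
  for (i in seq_along(lin)) {
    y <- vals[lin[i], ord]
    if (any(!is.finite(y))) next
    b0 <- max(y); a0 <- b0 - min(y)
    d0 <- x[which.min(y)]
    # width guess: offsets where the dip exceeds half depth
    deep <- x[y <= b0 - a0 / 2]
    g0 <- max(diff(range(deep)), diff(range(x)) / 10)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ b - a * g^2 / (g^2 + 4 * (x - d)^2),
                        start = list(b = b0, a = a0, g = g0, d = d0),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    co <- stats::coef(fit)
    if (!is.finite(co[["d"]]) || co[["d"]] < x[1] || co[["d"]] > x[length(x)])
      next
    ctr[lin[i]] <- co[["d"]]
    rss[lin[i]] <- sum(stats::residuals(fit)^2)
    ok[lin[i]] <- TRUE
  }
  list(center = ctr, rss = rss, ok = ok)
}

#' WASSR prescan as a Z-stack
#'
#' @param acq A [cest_acquisition()] carrying a WASSR prescan.
#' @param s0_frac Mask threshold as a fraction of the maximum reference
#'   magnitude.
#' @return A [z_stack()] of the WASSR series.
#' @export
wassr_zstack <- function(acq, s0_frac = 0.2) {
  stopifnot(inherits(acq, "cest_acquisition"))
  if (is.null(acq$wassr))
    stop("acquisition has no WASSR prescan", call. = FALSE)
  w <- acq$wassr
  mask <- w$s0 > s0_frac * max(w$s0)
  vals <- sweep(w$magnitude, c(1, 2), w$s0, "/")
  z_stack(vals, w$schedule$offset_ppm, w$s0, mask = mask,
          timestamps_s = w$schedule$timestamp_s)
}
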
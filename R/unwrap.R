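# Spatial phase processing: 2D unwrapping and Hamming-window smoothing.

# wrap to (-pi, pi]
wrap_phase <- function(x) Arg(exp(1i * x))

#' Fast 2D phase unwrapping
#'
#' Least-squares phase unwrapping on a 2D grid: the divergence of the
#' wrapped phase gradients is inverted through a discrete Poisson solve with
#' reflective (Neumann) boundaries, computed by FFT on the even-symmetric
#' extension of the grid. A final congruence step rounds the smooth solution
#' back onto the input phase, so the output differs from the input by exact
#' multiples of 2 pi in every voxel; smooth wrapped fields are restored up to
#' one global 2 pi k constant (chosen so that most voxels keep their wrapped
#' value).
#'
#' @param phase Matrix of phase values in radians.
#' @return Matrix of unwrapped phase, congruent with the input modulo 2 pi.
#' @export
unwrap_2d <- function(phase) {
  stopifnot(is.matrix(phase), all(is.finite(phase)))
  m <- nrow(phase); n <- ncol(phase)
  if (m < 2L || n < 2L) return(phase)
  dx <- rbind(wrap_phase(phase[-1, , drop = FALSE] -
                         phase[-m, , drop = FALSE]), 0)
  dy <- cbind(wrap_phase(phase[, -1, drop = FALSE] -
                         phase[, -n, drop = FALSE]), 0)
  rho <- dx - rbind(0, dx[-m, , drop = FALSE]) +
         dy - cbind(0, dy[, -n, drop = FALSE])
  # even-symmetric extension -> periodic Poisson solve respects zero flux
  ext <- rbind(rho, rho[m:1, , drop = FALSE])
  ext <- cbind(ext, ext[, n:1, drop = FALSE])
  lam <- outer(2 * cos(pi * (seq_len(2 * m) - 1) / m),
               2 * cos(pi * (seq_len(2 * n) - 1) / n), "+") - 4
  Fr <- stats::fft(ext) / lam
  Fr[1, 1] <- 0
  sol <- Re(stats::fft(Fr, inverse = TRUE)) / (4 * m * n)
  sol <- sol[seq_len(m), seq_len(n), drop = FALSE]
  k <- round((sol - phase) / (2 * pi))
  k <- k - round(stats::median(k))
  phase + 2 * pi * k
}

#' Spatial Hamming-window smoothing
#'
#' Separable 2D convolution with a Hamming window. At the image edges the
#' window is renormalised over the available voxels (partial-window weights),
#' so constant maps are preserved exactly; with `periodic = TRUE` the
#' convolution wraps around and conserves the map's total sum. `NA` voxels
#' are excluded from the window and left `NA` in the output.
#'
#' @param map Numeric matrix (e.g. a field map in Hz).
#' @param width Odd window width in voxels, at least 3.
#' @param periodic Use circular boundary conditions.
#' @return Smoothed matrix of the same dimensions.
#' @export
hamming_smooth <- function(map, width = 5, periodic = FALSE) {
  stopifnot(is.matrix(map), width >= 3, width %% 2 == 1)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(width) - 1) / (width - 1))
  half <- (width - 1) / 2
  ok <- !is.na(map)
  num <- ifelse(ok, map, 0)
  den <- ok * 1
  conv1 <- function(x, along) {
    out <- 0 * x
    for (s in -half:half) {
      wt <- w[s + half + 1]
      out <- out + wt * shift_mat(x, s, along, periodic)
    }
    out
  }
  num <- conv1(conv1(num, 1), 2)
  den <- conv1(conv1(den, 1), 2)
  res <- num / den
  res[den == 0] <- NA_real_
  res[!ok] <- NA_real_
  res
}

# shift a matrix by s along dimension `along`, padding with zeros or wrapping
shift_mat <- function(x, s, along, periodic) {
  if (s == 0) return(x)
  n <- dim(x)[along]
  idx <- seq_len(n) - s
  if (periodic) idx <- ((idx - 1) %% n) + 1
  keep <- idx >= 1 & idx <= n
  out <- array(0, dim(x))
  if (along == 1) out[keep, ] <- x[idx[keep], ]
  else out[, keep] <- x[, idx[keep]]
  out
}
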
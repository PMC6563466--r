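#' Multi-coil complex image
#'
#' The raw unit of acquisition: one complex image per receive channel and
#' echo, on a single 2D slice, with the echo times of the readout and an
#' acquisition timestamp. By convention the first spatial dimension is the
#' phase-encode direction (rows) and the second the readout (columns).
#'
#' @param data Complex array indexed `[channel, echo, row, col]`.
#' @param echo_times Echo times in seconds, strictly increasing, length 1 or 2.
#' @param timestamp Acquisition time in seconds relative to the start of the
#'   experiment (the dual-echo prescan defines t = 0).
#' @return An object of class `multi_coil_image`.
#' @export
multi_coil_image <- function(data, echo_times, timestamp = 0) {
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("data must be a 4D array [channel, echo, row, col]", call. = FALSE)
  if (!is.complex(data))
    stop("data must be complex-valued", call. = FALSE)
  d <- dim(data)
  if (d[1] < 1L)
    stop("need at least one channel", call. = FALSE)
  if (!(d[2] %in% c(1L, 2L)))
    stop("supported readouts have 1 or 2 echoes", call. = FALSE)
  if (length(echo_times) != d[2])
    stop("length(echo_times) must equal the echo dimension", call. = FALSE)
  if (any(echo_times <= 0) || (d[2] == 2L && diff(echo_times) <= 0))
    stop("echo_times must be positive and strictly increasing", call. = FALSE)
  if (any(d[3:4] < 8L))
    stop("spatial dimensions must be at least 8x8", call. = FALSE)
  stopifnot(is.numeric(timestamp), length(timestamp) == 1L, is.finite(timestamp))
  structure(list(data = data, echo_times = as.numeric(echo_times),
                 timestamp = as.numeric(timestamp)),
            class = "multi_coil_image")
}

#' @export
print.multi_coil_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multi_coil_image> %d channel(s), %d echo(es) (TE %s ms), %dx%d, t=%.2f s\n",
              d[1], d[2], paste(sprintf("%.3g", 1e3 * x$echo_times), collapse = "/"),
              d[3], d[4], x$timestamp))
  invisible(x)
}

#' @rdname multi_coil_image
#' @param img A `multi_coil_image`.
#' @export
n_channels <- function(img) dim(img$data)[1]

#' @rdname multi_coil_image
#' @export
n_echoes <- function(img) dim(img$data)[2]

#' @rdname multi_coil_image
#' @export
grid_dim <- function(img) dim(img$data)[3:4]

#' Keep only the first echo of a dual-echo image
#'
#' Used by the single-echo intrinsic mapping method, which deliberately
#' ignores the second echo of the CEST readout.
#'
#' @param img A [multi_coil_image()].
#' @return A single-echo `multi_coil_image`.
#' @export
first_echo <- function(img) {
  multi_coil_image(img$data[, 1L, , , drop = FALSE], img$echo_times[1L],
                   img$timestamp)
}

#' Sum-of-squares channel combination of the magnitude signal
#'
#' Returns the root-sum-of-squares magnitude over channels, averaged over
#' echoes when `average_echoes` is TRUE (each dual-echo magnitude pair is
#' averaged before Z-spectrum normalisation).
#'
#' @param img A [multi_coil_image()].
#' @param average_echoes Average the per-echo combined magnitudes.
#' @return Matrix `[row, col]` (or array `[row, col, echo]` when
#'   `average_echoes = FALSE`).
#' @export
sos_magnitude <- function(img, average_echoes = TRUE) {
  d <- dim(img$data)
  m <- apply(abs(img$data)^2, c(3, 4, 2), sum)       # [row, col, echo]
  dim(m) <- c(d[3], d[4], d[2])
  m <- sqrt(m)
  if (average_echoes) {
    out <- m[, , 1]
    if (d[2] > 1L) out <- (out + m[, , 2]) / 2
    out
  } else m
}
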
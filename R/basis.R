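#' Direction-tuned channel basis
#'
#' Constructs the set of idealized direction tuning curves ("channels") used
#' by the inverted encoding model. Each channel is a half-wave rectified
#' cosine raised to an even power, centred on one of `n_channels` directions
#' evenly spaced over the design span. With the default
#' `period = "full_circle"` the sinusoid lives on the physical 360-degree
#' direction circle, so opposite motions (e.g. −45 and 135 degrees, both
#' among the localizer directions) map to distinct amplitude patterns.
#' `period = "half_circle_doubled"` instead treats the 180-degree design
#' span as one full sinusoid cycle, which tiles the span seamlessly but
#' aliases directions 180 degrees apart.
#'
#' @param n_channels number of hypothetical channels (default 21).
#' @param span numeric length-2, degrees; channel centres are spaced evenly
#'   over `[span[1], span[2])` (default `c(-45, 135)`).
#' @param exponent positive even integer; the power applied to the rectified
#'   cosine (default 6). Larger exponents give narrower tuning.
#' @param period `"full_circle"` (default) or `"half_circle_doubled"`; see
#'   Details.
#' @param grid_step degrees; resolution of the readout grid used by
#'   [readout_direction()] (default 0.1).
#' @return An object of class `"direction_basis"` with elements `centers`
#'   (degrees), `exponent`, `period`, `span` and `grid_step`.
#' @seealso [channel_amplitudes()], [readout_direction()], [iem()]
#' @examples
#' b <- direction_basis()
#' round(b$centers[1:4], 3)
#' channel_amplitudes(b, c(27, 63))[1:4, ]
#' @export
direction_basis <- function(n_channels = 21L, span = c(-45, 135),
                            exponent = 6L,
                            period = c("full_circle", "half_circle_doubled"),
                            grid_step = 0.1) {
  period <- match.arg(period)
  if (n_channels < 2L) stop("n_channels must be at least 2")
  if (exponent <= 0L || exponent %% 2L != 0L)
    stop("exponent must be a positive even integer")
  width <- span[2] - span[1]
  if (period == "half_circle_doubled" && abs(width - 180) > 1e-9)
    stop("span must cover exactly 180 degrees when period = \"half_circle_doubled\"")
  if (grid_step <= 0) stop("grid_step must be positive")
  centers <- span[1] + width * (seq_len(n_channels) - 1L) / n_channels
  structure(
    list(centers = centers, exponent = as.integer(exponent),
         period = period, span = as.numeric(span),
         grid_step = grid_step),
    class = "direction_basis")
}

#' @export
print.direction_basis <- function(x, ...) {
  cat(sprintf(
    "Direction channel basis: %d channels over [%g, %g) deg\n",
    length(x$centers), x$span[1], x$span[2]))
  cat(sprintf("  tuning: rectified cosine^%d, period mode \"%s\"\n",
              x$exponent, x$period))
  cat(sprintf("  readout grid step: %g deg\n", x$grid_step))
  invisible(x)
}

# Tuning-curve value of every channel at every direction.
# Returns channels x directions. The half_circle_doubled mode maps the
# 180-deg span onto a full cosine cycle (angle doubling).
basis_matrix <- function(basis, directions) {
  stopifnot(inherits(basis, "direction_basis"))
  if (any(!is.finite(directions))) stop("directions must be finite")
  per <- if (basis$period == "half_circle_doubled") 180 else 360
  d <- outer(basis$centers, directions, function(c, th) th - c)
  f <- pmax(0, cos(2 * pi * d / per))^basis$exponent
  dim(f) <- c(length(basis$centers), length(directions))
  f
}

#' Hypothesized channel amplitudes for a set of directions
#'
#' Expresses each presented direction as an amplitude on every channel of the
#' basis: the design matrix `C` (channels x trials) of the encoding model.
#'
#' @param basis a [direction_basis()] object.
#' @param directions numeric vector of presented directions in degrees.
#' @return numeric matrix, channels x trials; column `t` holds the basis
#'   values at `directions[t]`.
#' @examples
#' b <- direction_basis()
#' C <- channel_amplitudes(b, c(-45, 27, 63))
#' dim(C)
#' @export
channel_amplitudes <- function(basis, directions) {
  C <- basis_matrix(basis, directions)
  rownames(C) <- sprintf("ch%02d", seq_along(basis$centers))
  C
}
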
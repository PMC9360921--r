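#' Wrap orientations to the half-open interval [-90, 90)
#'
#' Orientation (as opposed to direction) is 180-degree periodic: a grating at
#' 100 degrees is the same stimulus as one at -80 degrees. All orientations in
#' this package live on \code{[-90, 90)} degrees.
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Angles wrapped to \code{[-90, 90)}.
#' @export
#' @examples
#' wrap_orientation(c(0, 90, 100, -95, 270))
wrap_orientation <- function(theta) {
  stopifnot(is.numeric(theta))
  ((theta + 90) %% 180) - 90
}

#' Circular difference between two orientations
#'
#' The absolute orientation difference, computed on the doubled-angle circle
#' and halved, so the result lies in \code{[0, 90]} degrees (or
#' \code{[0, pi/2]} radians). Two orthogonal orientations are maximally
#' different; orientations 180 degrees apart are identical.
#'
#' @param a,b Orientations in degrees (recycled against each other).
#' @param unit Return unit, `"deg"` or `"rad"`.
#' @return Non-negative differences, in the requested unit.
#' @export
#' @examples
#' orientation_diff(80, -80)   # 20, not 160
#' orientation_diff(0, 90)     # 90: orthogonal
orientation_diff <- function(a, b, unit = c("deg", "rad")) {
  unit <- match.arg(unit)
  d2 <- (a - b) * 2 * pi / 180
  d <- abs(atan2(sin(d2), cos(d2))) / 2
  if (unit == "deg") d * 180 / pi else d
}

#' Equally spaced orientation grid
#'
#' @param n_stimuli Number of grid points (>= 2).
#' @return Numeric vector of `n_stimuli` orientations equally spaced on
#'   \code{[-90, 90)} degrees, starting at -90.
#' @export
#' @examples
#' stimulus_grid(8)  # the 22.5-degree grating grid
stimulus_grid <- function(n_stimuli) {
  stopifnot(length(n_stimuli) == 1, is.finite(n_stimuli), n_stimuli >= 2)
  seq(-90, 90, length.out = n_stimuli + 1)[seq_len(n_stimuli)]
}

#' Squared wrapped orientation error
#'
#' Per-trial squared error between estimated and true orientation, with
#' wrapping on the doubled-angle circle: the error for an 80-degree estimate
#' of a -80-degree stimulus is 20 degrees, not 160. Errors are returned in
#' squared radians (of orientation, so the maximum is \code{(pi/2)^2}).
#'
#' @param estimates,truths Orientations in degrees (equal length or scalar).
#' @return Numeric vector of squared errors in rad^2.
#' @export
#' @examples
#' orientation_sq_error(80, -80)  # (20 deg)^2 in rad^2, ~0.1218
orientation_sq_error <- function(estimates, truths) {
  if (length(estimates) != length(truths) &&
      length(estimates) != 1 && length(truths) != 1) {
    stop("'estimates' and 'truths' must have equal length (or be scalar)")
  }
  orientation_diff(estimates, truths, unit = "rad")^2
}
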
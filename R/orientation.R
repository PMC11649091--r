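#' Fold an orientation into the half-circle domain
#'
#' Stimulus orientations live on a 180-degree-periodic half circle. This folds
#' arbitrary angles into the canonical domain `[-90, 90)`.
#'
#' @param theta Numeric vector of orientations in degrees.
#' @return Numeric vector in `[-90, 90)`.
#' @export
#' @examples
#' fold_orientation(c(95, -95, 180, 270))
fold_orientation <- function(theta) {
  ((theta + 90) %% 180) - 90
}

#' Circular distance between orientations
#'
#' Distance on the orientation half circle (period 180 degrees):
#' `d(a, b) = min(|a - b| mod 180, 180 - |a - b| mod 180)`.
#'
#' @param a,b Numeric vectors of orientations in degrees (recycled).
#' @return Non-negative distances in degrees, at most 90.
#' @export
orientation_distance <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Orientation-tuned synaptic activity
#'
#' Gaussian tuning curve of a single synapse, normalized to peak activity 1 at
#' its preferred orientation: `exp(-d^2 / (2 sigma^2))` where `d` is the
#' circular orientation distance (period 180 degrees) between stimulus and
#' preference.
#'
#' @param delta_theta Offset between stimulus and preferred orientation,
#'   degrees. Folded onto the half circle internally, so any real value is
#'   accepted.
#' @param tuning_width Tuning-curve width `sigma_tuning` in degrees
#'   (default 11).
#' @return Activity in `[0, 1]`.
#' @export
#' @examples
#' synapse_activity(0)            # 1 at the preferred orientation
#' synapse_activity(11)           # exp(-1/2)
synapse_activity <- function(delta_theta, tuning_width = 11) {
  if (any(!is.finite(tuning_width)) || any(tuning_width <= 0)) {
    stop("`tuning_width` must be a positive finite number")
  }
  d <- orientation_distance(delta_theta, 0)
  exp(-d^2 / (2 * tuning_width^2))
}
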
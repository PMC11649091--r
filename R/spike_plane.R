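#' Linear spike-threshold plane
#'
#' The minimum potassium reversal shift needed to trigger a dendritic spike
#' is modelled as a plane in the segment's synapse count `N` and mean
#' synaptic activity `w`:
#' `shift(N, w) = alpha * w + beta * N + nu`,
#' with negative required shifts meaning the segment spikes without any
#' shift. `alpha` and `beta` are negative for any physically sensible fit
#' (more drive lowers the required shift).
#'
#' `spike_plane()` constructs the object directly; [fit_spike_plane()]
#' estimates it from a [threshold_surface()]; [reference_spike_plane()]
#' returns the published reference coefficients (-38.43, -2.08, 52.32),
#' under which one extra synapse lowers the required shift by 2.08 mV and a
#' 0.1 increase in `w` lowers it by about 3.8 mV.
#'
#' @param alpha mV per unit of mean activity `w`.
#' @param beta mV per synapse.
#' @param nu Offset, mV.
#' @return Object of class `spike_plane`.
#' @export
spike_plane <- function(alpha, beta, nu) {
  structure(list(coefficients = c(alpha = alpha, beta = beta, nu = nu)),
            class = "spike_plane")
}

#' @rdname spike_plane
#' @export
reference_spike_plane <- function() {
  plane <- spike_plane(-38.43, -2.08, 52.32)
  plane$source <- "reference"
  plane
}

#' @export
coef.spike_plane <- function(object, ...) object$coefficients

#' @export
print.spike_plane <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "<spike_plane> shift(N, w) = %.4g w + %.4g N + %.4g  [mV]\n",
    cf["alpha"], cf["beta"], cf["nu"]))
  if (!is.null(x$rms)) cat(sprintf("  residual RMS = %.3g mV on %d points\n",
                                   x$rms, x$n))
  invisible(x)
}

#' Fit the spike-threshold plane to threshold-surface outcomes
#'
#' Ordinary least squares of the minimal spiking shift on `(w, N)`; rows
#' whose cells never spiked within the scanned range are dropped.
#'
#' @param surface data.frame with columns `N`, `w`, `min_shift_mV` (as
#'   returned by [threshold_surface()]).
#' @return A `spike_plane` with residual diagnostics (`rms`, `residuals`,
#'   `n`).
#' @export
fit_spike_plane <- function(surface) {
  ok <- is.finite(surface$min_shift_mV)
  if (sum(ok) < 3) stop("need at least 3 finite (N, w, shift) points")
  A <- cbind(w = surface$w[ok], N = surface$N[ok], 1)
  if (qr(A)$rank < 3) stop("rank-deficient design: vary both N and w")
  b <- surface$min_shift_mV[ok]
  cf <- qr.solve(A, b)
  plane <- spike_plane(cf[1], cf[2], cf[3])
  plane$residuals <- b - drop(A %*% cf)
  plane$rms <- sqrt(mean(plane$residuals^2))
  plane$n <- sum(ok)
  plane
}

#' Required reversal shift for dendritic spiking
#'
#' Evaluates the plane at `(N, w)` and clamps negative values to zero (a
#' negative requirement means the segment spikes with no shift).
#'
#' @param plane A `spike_plane`.
#' @param N Synapse count(s).
#' @param w Mean synaptic activity in `[0, 1]` (recycled against `N`).
#' @return Required shift(s), mV, >= 0.
#' @export
#' @examples
#' required_shift(reference_spike_plane(), N = 10, w = 0.59)  # 8.85 mV
required_shift <- function(plane, N, w) {
  stopifnot(inherits(plane, "spike_plane"))
  cf <- plane$coefficients
  pmax(0, cf["alpha"] * w + cf["beta"] * N + cf["nu"])
}

#' Orientation-resolved dendritic spike probability
#'
#' Samples similarly tuned segments at each orientation, computes each
#' segment's required shift from the plane, and reports the fraction whose
#' requirement is met by the available shift. The available shift equals
#' `EK_at_target` at the target orientation and is scaled at other
#' orientations by the normalized similar/diverse activity factor.
#'
#' @param plane A `spike_plane`.
#' @param EK_at_target Reversal shift available at the target orientation,
#'   mV.
#' @param theta_grid Orientations, degrees (default 0..90 by 5).
#' @param n_segments Segments sampled per orientation (default 1e4).
#' @param factor_fun Function mapping orientation to the normalized activity
#'   factor (see [normalized_activity_factor()]); if `NULL` it is estimated
#'   from `n_factor` sampled segments.
#' @param n_factor Segments per regime used when estimating the factor
#'   internally (default 1e4).
#' @param seed Integer seed.
#' @param ... Passed to [sample_segment()].
#' @return Object of class `tuning_result`: data.frame with `theta_deg`,
#'   `response` (spike probability), `se` (binomial standard error), plus an
#'   `osi` attribute computed by [orientation_selectivity()].
#' @export
spike_probability <- function(plane, EK_at_target,
                              theta_grid = seq(0, 90, by = 5),
                              n_segments = 1e4,
                              factor_fun = NULL,
                              n_factor = 1e4,
                              seed = NULL, ...) {
  stopifnot(inherits(plane, "spike_plane"))
  if (EK_at_target < 0) stop("`EK_at_target` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(factor_fun)) {
    af <- activity_factor(theta_grid = theta_grid, n_segments = n_factor, ...)
    factor_fun <- normalized_activity_factor(af)
  }
  rows <- lapply(theta_grid, function(th) {
    available <- EK_at_target * factor_fun(th)
    segs <- replicate(n_segments, sample_segment("similar", ...),
                      simplify = FALSE)
    need <- vapply(segs, function(s) {
      required_shift(plane, length(s$preferred),
                     segment_mean_activity(s, th))
    }, numeric(1))
    p <- mean(need <= available)
    data.frame(theta_deg = th, response = p,
               se = sqrt(p * (1 - p) / n_segments))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tuning_result", "data.frame")
  attr(out, "osi") <- orientation_selectivity(out$theta_deg, out$response)
  attr(out, "EK_at_target") <- EK_at_target
  out
}

#' Orientation selectivity index (1 - circular variance)
#'
#' `OSI = |sum_k r_k exp(-2 i theta_k)| / sum_k r_k` with angles in radians
#' and doubled because orientation has period 180 degrees. Responses sampled
#' on `[0, 90]` are first mirrored to `[-90, 90]` (the response is symmetric
#' about the target by construction); already-mirrored input (containing
#' negative orientations) is used as is.
#'
#' @param theta Orientations, degrees.
#' @param response Non-negative responses (spike probability or firing
#'   rate), same length as `theta`; must not be all zero.
#' @return OSI in `[0, 1]`: 1 for a response concentrated at one orientation,
#'   0 for a uniform response.
#' @export
#' @examples
#' orientation_selectivity(c(0, 45, 90), c(1, 0, 0))   # fully selective
#' orientation_selectivity(c(0, 45, 90), c(1, 1, 1))   # untuned
orientation_selectivity <- function(theta, response) {
  if (length(theta) < 2) stop("need at least 2 orientations")
  if (any(response < 0)) stop("responses must be non-negative")
  if (all(response == 0)) stop("OSI undefined for an all-zero response")
  if (all(theta >= 0)) {
    # mirror, without duplicating 0 (the target itself) or 90 (identified
    # with -90 on the orientation circle)
    keep <- theta > 0 & theta < 90
    theta <- c(-theta[keep], theta)
    response <- c(response[keep], response)
  }
  z <- sum(response * exp(-2i * theta * pi / 180)) / sum(response)
  Mod(z)
}

#' @export
print.tuning_result <- function(x, ...) {
  cat(sprintf("<tuning_result> %d orientations, OSI = %.3f\n",
              nrow(x), attr(x, "osi")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
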
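#' Sample a dendritic segment populated with orientation-tuned synapses
#'
#' A dendritic segment is a 10 um cylinder carrying 7 to 13 excitatory
#' synapses. In the "similar" tuning regime synapse orientation preferences are
#' drawn from a half-circular normal distribution (sd `sigma_pref`) about the
#' target orientation; in the "diverse" regime they are uniform on the
#' orientation half circle. All synapses share the tuning width `sigma_tuning`.
#'
#' Sampling uses R's global RNG; seed with [set.seed()] (top-level pipeline
#' functions take explicit `seed` arguments).
#'
#' @param regime `"similar"` or `"diverse"`.
#' @param target_orientation Target (somatic preferred) orientation, degrees.
#' @param sigma_pref Preference spread for the similar regime, degrees
#'   (default 15).
#' @param sigma_tuning Tuning-curve width for every synapse, degrees
#'   (default 11).
#' @param n_synapses Optional fixed synapse count; by default drawn uniformly
#'   from `n_range`.
#' @param n_range Integer range of synapse counts (default `7:13`).
#' @param length,radius Segment geometry in um (defaults 10 and 1).
#' @return An object of class `dendritic_segment`: list with `preferred`
#'   (degrees, folded to `[-90, 90)`), `tuning_width`, `regime`, `length`,
#'   `radius`, `target`.
#' @export
#' @examples
#' set.seed(1)
#' seg <- sample_segment("similar")
#' segment_mean_activity(seg, 0)
sample_segment <- function(regime = c("similar", "diverse"),
                           target_orientation = 0,
                           sigma_pref = 15,
                           sigma_tuning = 11,
                           n_synapses = NULL,
                           n_range = 7:13,
                           length = 10,
                           radius = 1) {
  regime <- match.arg(regime)
  n <- if (is.null(n_synapses)) sample(n_range, 1L) else as.integer(n_synapses)
  if (n < 1L) stop("segment must carry at least one synapse")
  pref <- if (regime == "similar") {
    stats::rnorm(n, mean = target_orientation, sd = sigma_pref)
  } else {
    stats::runif(n, min = -90, max = 90)
  }
  structure(
    list(
      preferred = fold_orientation(pref),
      tuning_width = sigma_tuning,
      regime = regime,
      length = length,
      radius = radius,
      target = target_orientation
    ),
    class = "dendritic_segment"
  )
}

#' @export
print.dendritic_segment <- function(x, ...) {
  cat(sprintf(
    "<dendritic_segment> %s regime, %d synapses, L = %g um, R1 = %g um\n",
    x$regime, length(x$preferred), x$length, x$radius
  ))
  cat("  preferences (deg):", paste(sprintf("%.1f", x$preferred), collapse = ", "), "\n")
  invisible(x)
}

#' Mean synaptic activity of a segment
#'
#' The segment-level drive `w(theta)`: arithmetic mean over the segment's
#' synapses of each synapse's Gaussian tuning-curve activity at stimulus
#' orientation `theta`.
#'
#' @param segment A `dendritic_segment`.
#' @param theta Stimulus orientation(s), degrees.
#' @return `w` in `[0, 1]`, one value per element of `theta`.
#' @export
segment_mean_activity <- function(segment, theta) {
  if (!inherits(segment, "dendritic_segment")) {
    stop("`segment` must be a dendritic_segment")
  }
  if (length(segment$preferred) == 0L) stop("segment has no synapses")
  vapply(theta, function(th) {
    mean(synapse_activity(orientation_distance(th, segment$preferred),
                          segment$tuning_width))
  }, numeric(1))
}

#' Kernel-density distribution of segment-mean activity
#'
#' Samples `n_segments` dendritic segments of one regime, evaluates their mean
#' activity `w(theta)` and returns a Gaussian kernel density estimate of the
#' activity distribution on a linear grid in `[0, 1]`, together with the
#' expectation value `E(X) = sum(x_i p_i)` computed on that grid.
#'
#' @inheritParams sample_segment
#' @param theta Stimulus orientation, degrees.
#' @param n_segments Number of segments to sample (>= 2; default 1e4).
#' @param grid_n Number of grid points in `[0, 1]` (default 512).
#' @param ... Passed on to [sample_segment()].
#' @return List with `x` (grid), `density`, `expectation`, `samples`.
#' @details The kernel bandwidth follows Scott's rule ([stats::bw.nrd()]); the
#'   density is renormalized on `[0, 1]` so that it integrates to 1 there.
#' @export
activity_distribution <- function(regime, theta, n_segments = 1e4,
                                  grid_n = 512, ...) {
  if (n_segments < 2) stop("`n_segments` must be at least 2")
  w <- replicate(n_segments,
                 segment_mean_activity(sample_segment(regime, ...), theta))
  bw <- stats::bw.nrd(w)
  if (!is.finite(bw) || bw <= 0) bw <- 1e-3  # degenerate (point-mass) samples
  x <- seq(0, 1, length.out = grid_n)
  dens <- stats::density(w, bw = bw, from = 0, to = 1, n = grid_n)$y
  p <- dens / sum(dens)
  list(
    x = x,
    density = dens / (sum(dens) * (x[2] - x[1])),
    expectation = sum(x * p),
    samples = w
  )
}

#' Expected diverse-regime activity by quadrature
#'
#' Closed-route oracle for the expected single-synapse (hence segment-mean)
#' activity when orientation preferences are uniform on the half circle:
#' `(1/180) * integral of exp(-d(theta, phi)^2 / (2 sigma^2)) d phi`. The
#' value is independent of the stimulus orientation.
#'
#' @param sigma_tuning Tuning width, degrees (default 11).
#' @return Expected activity (about 0.153 for the default width).
#' @export
diverse_expected_activity <- function(sigma_tuning = 11) {
  f <- function(d) exp(-d^2 / (2 * sigma_tuning^2))
  # preference uniform on half circle -> distance to stimulus uniform on [0, 90]
  stats::integrate(f, 0, 90)$value / 90
}

#' Similar-vs-diverse synaptic activity factor
#'
#' For each stimulus orientation, the ratio `E(S) / E(D)` between the expected
#' segment-mean activity of similarly and diversely tuned segments. Near the
#' target orientation the factor lies in the 2-5x band; beyond roughly 45
#' degrees it drops below 1.
#'
#' @param theta_grid Stimulus orientations, degrees (default 0..90 in steps
#'   of 5).
#' @param n_segments Segments sampled per regime and orientation
#'   (default 1e4).
#' @param seed Integer seed for reproducibility (optional).
#' @param use_kde If `TRUE` (default) expectations are taken from the kernel
#'   density estimate on the unit grid; otherwise the plain sample mean is
#'   used (the two agree within Monte-Carlo error).
#' @inheritParams sample_segment
#' @param ... Passed to [sample_segment()].
#' @return Object of class `activity_factor`: data.frame with columns
#'   `theta_deg`, `expected_similar`, `expected_diverse`, `factor`.
#' @export
#' @examples
#' af <- activity_factor(theta_grid = c(0, 45, 90), n_segments = 500, seed = 1)
#' af$factor[af$theta_deg == 0] > 1
activity_factor <- function(theta_grid = seq(0, 90, by = 5),
                            n_segments = 1e4,
                            seed = NULL,
                            use_kde = TRUE,
                            sigma_pref = 15,
                            sigma_tuning = 11,
                            ...) {
  if (!is.null(seed)) set.seed(seed)
  # One fixed population per regime, evaluated across orientations: matches
  # the sampling design (same synapse-count distribution for both regimes).
  segs_s <- replicate(n_segments, sample_segment(
    "similar", sigma_pref = sigma_pref, sigma_tuning = sigma_tuning, ...
  ), simplify = FALSE)
  segs_d <- replicate(n_segments, sample_segment(
    "diverse", sigma_pref = sigma_pref, sigma_tuning = sigma_tuning, ...
  ), simplify = FALSE)
  expectation <- function(w) {
    if (!use_kde) return(mean(w))
    bw <- stats::bw.nrd(w)
    if (!is.finite(bw) || bw <= 0) bw <- 1e-3
    x <- seq(0, 1, length.out = 512)
    dens <- stats::density(w, bw = bw, from = 0, to = 1, n = 512)$y
    sum(x * dens / sum(dens))
  }
  rows <- lapply(theta_grid, function(th) {
    ws <- vapply(segs_s, segment_mean_activity, numeric(1), theta = th)
    wd <- vapply(segs_d, segment_mean_activity, numeric(1), theta = th)
    es <- expectation(ws)
    ed <- expectation(wd)
    if (ed < 1e-6) stop("diverse-regime expectation is numerically zero")
    data.frame(theta_deg = th, expected_similar = es,
               expected_diverse = ed, factor = es / ed)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("activity_factor", "data.frame")
  out
}

#' Normalized activity factor as a function of orientation
#'
#' Interpolates `factor(theta) / factor(0)` from an [activity_factor()] table;
#' used to scale the target-orientation reversal shift to other orientations.
#'
#' @param af An `activity_factor` table.
#' @return Function mapping orientation (degrees, folded) to the normalized
#'   factor.
#' @export
normalized_activity_factor <- function(af) {
  stopifnot(inherits(af, "activity_factor"))
  f0 <- af$factor[which.min(abs(af$theta_deg))]
  fun <- stats::approxfun(af$theta_deg, af$factor / f0, rule = 2)
  function(theta) fun(abs(fold_orientation(theta)))
}
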
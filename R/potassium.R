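#' Cylinder-in-cylinder extracellular geometry
#'
#' The dendritic segment is a cylinder of radius `R1` enclosed by an outer
#' cylinder of radius `R2`; the annular shell between them is the local
#' extracellular space. Both share length `L`.
#'
#' @param R1 Dendrite radius, um (default 1).
#' @param R2 Outer cylinder radius, um (default 2); must exceed `R1`.
#' @param L Segment length, um (default 10).
#' @return Object of class `k_geometry`.
#' @export
k_geometry <- function(R1 = 1, R2 = 2, L = 10) {
  if (!(R1 > 0) || !(L > 0)) stop("R1 and L must be positive")
  if (!(R2 > R1)) stop("R2 must exceed R1 (volume ratio undefined for R2 <= R1)")
  structure(list(R1 = R1, R2 = R2, L = L), class = "k_geometry")
}

#' @export
print.k_geometry <- function(x, ...) {
  cat(sprintf("<k_geometry> R1 = %g um, R2 = %g um, L = %g um, V_R = %.4g\n",
              x$R1, x$R2, x$L, volume_ratio(x)))
  invisible(x)
}

#' Intracellular-to-extracellular volume ratio
#'
#' `V_R = V_int / V_ext = R1^2 / (R2^2 - R1^2)`; the conversion factor between
#' an intracellular concentration loss and the extracellular concentration
#' gain. Diverges as `R2 -> R1` and vanishes as `R2 -> Inf`.
#'
#' @param geom A [k_geometry()].
#' @return Dimensionless ratio.
#' @export
volume_ratio <- function(geom) {
  stopifnot(inherits(geom, "k_geometry"))
  geom$R1^2 / (geom$R2^2 - geom$R1^2)
}

#' Extracellular K+ rise from an intracellular loss
#'
#' `delta_K_out = |delta_K_in| * V_R`: the well-mixed extracellular
#' concentration change produced by moving `delta_K_in` (magnitude) out of the
#' dendrite.
#'
#' @param delta_k_in Magnitude of the intracellular concentration change, mM.
#' @param geom A [k_geometry()].
#' @return Extracellular concentration change, mM.
#' @export
delta_k_out <- function(delta_k_in, geom) {
  if (any(delta_k_in < 0)) stop("`delta_k_in` is a magnitude; must be >= 0")
  abs(delta_k_in) * volume_ratio(geom)
}

#' Baseline ionic concentrations for the Nernst helper
#'
#' @param K_out Resting extracellular concentration, mM (default 3; the in
#'   vivo resting range is roughly 2.7-3.5 mM).
#' @param K_in Resting intracellular concentration, mM (default 140).
#' @param prefactor Nernst prefactor RT/F at physiological temperature, mV
#'   (default 26.7).
#' @param valence Ion valence `z` (default 1 for K+); the prefactor is divided
#'   by `z`, so divalent ions halve it.
#' @return Object of class `ion_baseline`.
#' @export
ion_baseline <- function(K_out = 3, K_in = 140, prefactor = 26.7, valence = 1) {
  if (!(K_out > 0) || !(K_in > 0)) stop("concentrations must be positive")
  if (valence == 0) stop("valence must be nonzero")
  structure(list(K_out = K_out, K_in = K_in, prefactor = prefactor,
                 valence = valence),
            class = "ion_baseline")
}

#' Nernst reversal potential
#'
#' `E = -(prefactor / z) * ln(C_in / C_out)`; about -102.7 mV for K+ at the
#' default 140 / 3 mM baseline.
#'
#' @param baseline An [ion_baseline()].
#' @param delta_in,delta_out Concentration changes applied to the inside
#'   (subtracted, a loss) and outside (added), mM.
#' @return Reversal potential in mV.
#' @export
nernst_potential <- function(baseline, delta_in = 0, delta_out = 0) {
  stopifnot(inherits(baseline, "ion_baseline"))
  cin <- baseline$K_in - delta_in
  cout <- baseline$K_out + delta_out
  if (any(cin <= 0) || any(cout <= 0)) {
    stop("concentration driven non-positive; shift outside the physical domain")
  }
  -(baseline$prefactor / baseline$valence) * log(cin / cout)
}

#' Reversal-potential shift from concentration changes
#'
#' `delta_E = E(after) - E(before)`; positive (depolarizing) when the
#' extracellular concentration rises and/or the intracellular falls.
#'
#' @inheritParams nernst_potential
#' @param delta_in Intracellular loss magnitude, mM.
#' @param delta_out Extracellular gain, mM.
#' @return Shift in mV.
#' @export
#' @examples
#' b <- ion_baseline()
#' nernst_shift(b, delta_in = 1, delta_out = 3)  # about 18.7 mV
nernst_shift <- function(baseline, delta_in = 0, delta_out = 0) {
  nernst_potential(baseline, delta_in, delta_out) - nernst_potential(baseline)
}

#' Reversal-shift heat map over intracellular loss and extracellular size
#'
#' Sweeps the two free parameters of the analytical model -- the intracellular
#' concentration loss and the outer cylinder radius -- and tabulates the
#' extracellular K+ rise and reversal shift for the diverse regime, and for
#' the similar regime after scaling the diverse extracellular rise by the
#' activity factor at the target orientation.
#'
#' @param delta_k_in_grid Intracellular loss magnitudes, mM.
#' @param R2_grid Outer radii, um.
#' @param baseline An [ion_baseline()].
#' @param factor_at_target Similar/diverse activity factor at the target
#'   orientation (> 0).
#' @param R1,L Inner cylinder geometry, um.
#' @param in_vivo_band Extracellular-rise band (mM) used to flag the
#'   parameter subset consistent with in vivo microelectrode measurements
#'   (default `c(0.25, 1)`).
#' @param couple_intracellular If `TRUE` (default) the similar-regime Nernst
#'   shift also scales the intracellular loss by the factor; the default
#'   matches the mean-field treatment where the intracellular side is the
#'   source of the scaled efflux.
#' @return data.frame with one row per grid cell: `delta_k_in_mM`, `R2_um`,
#'   `dKo_diverse_mM`, `dKo_similar_mM`, `dEK_diverse_mV`, `dEK_similar_mV`,
#'   `in_vivo` (logical flag on the diverse extracellular rise).
#' @export
shift_heatmap <- function(delta_k_in_grid, R2_grid,
                          baseline = ion_baseline(),
                          factor_at_target = 1,
                          R1 = 1, L = 10,
                          in_vivo_band = c(0.25, 1),
                          couple_intracellular = TRUE) {
  if (length(delta_k_in_grid) == 0 || length(R2_grid) == 0) {
    stop("grids must be non-empty")
  }
  if (!(factor_at_target > 0)) stop("`factor_at_target` must be positive")
  grid <- expand.grid(delta_k_in_mM = delta_k_in_grid, R2_um = R2_grid)
  vr <- vapply(grid$R2_um, function(r2) volume_ratio(k_geometry(R1, r2, L)),
               numeric(1))
  dko_d <- grid$delta_k_in_mM * vr
  dko_s <- factor_at_target * dko_d
  dki_s <- if (couple_intracellular) factor_at_target * grid$delta_k_in_mM else
    grid$delta_k_in_mM
  grid$dKo_diverse_mM <- dko_d
  grid$dKo_similar_mM <- dko_s
  grid$dEK_diverse_mV <- mapply(function(din, dout)
    nernst_shift(baseline, din, dout), grid$delta_k_in_mM, dko_d)
  grid$dEK_similar_mV <- mapply(function(din, dout)
    nernst_shift(baseline, din, dout), dki_s, dko_s)
  grid$in_vivo <- dko_d >= in_vivo_band[1] & dko_d <= in_vivo_band[2]
  grid
}
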
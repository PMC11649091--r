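#' Channel kinetics tables
#'
#' Both membrane models (the single-compartment point dendrite and the
#' multi-compartment fractal neuron) draw their intrinsic currents from a
#' common first-order gating scheme. Each channel contributes
#' `gbar * m^p * h^q * (E - Vm)` with gates relaxing as
#' `dx/dt = (x_inf(V) - x) / tau_x`, `x_inf` a Boltzmann function
#' `1 / (1 + exp(-(V - vh)/k))` (negative `k` for inactivation-like voltage
#' dependence) and a voltage-independent time constant. Channels flagged
#' `is_k` reverse at the potassium Nernst potential and are the ones moved by
#' an imposed reversal shift.
#'
#' Kinetic parameters are standard values for visual-cortex dendritic
#' channels; the maximal conductances were calibrated (see the methods
#' vignette) so that at the target orientation and no reversal shift the point
#' dendrite fires an NMDA spike on roughly half the stimulation events.
#'
#' @param E_K Resting potassium reversal, mV. Default derives from the
#'   default [ion_baseline()] (about -102.7 mV).
#' @param gbar_scale Named numeric vector of per-channel multipliers applied
#'   to the default maximal conductances (useful for sensitivity sweeps).
#' @return data.frame with one row per channel and columns `name`, `gbar`
#'   (mS/cm^2), `erev` (mV), `is_k`, `p`, `act_vh`, `act_k`, `act_tau`, `q`,
#'   `inact_vh`, `inact_k`, `inact_tau`.
#' @export
point_dendrite_channels <- function(E_K = nernst_potential(ion_baseline()),
                                    gbar_scale = NULL) {
  ch <- data.frame(
    name     = c("K_leak", "Na_V", "K_V", "K_M", "K_A", "K_Ca", "Ca_V", "HCN"),
    gbar     = c(0.06,     0.35,   1.20,  0.35,  3.00,  0.35,   0.15,  0.09),
    erev     = c(E_K,      60,     E_K,   E_K,   E_K,   E_K,    120,   -45),
    is_k     = c(TRUE,     FALSE,  TRUE,  TRUE,  TRUE,  TRUE,   FALSE, FALSE),
    p        = c(0,        3,      1,     1,     1,     1,      2,     1),
    act_vh   = c(NA,       -30,    -15,   -35,   -50,   -20,    -30,   -82),
    act_k    = c(NA,       6,      10,    6,     15,    10,     7,     -7),
    act_tau  = c(NA,       0.15,   3,     60,    2,     80,     1.5,   50),
    q        = c(0,        1,      0,     0,     1,     0,      1,     0),
    inact_vh = c(NA,       -55,    NA,    NA,    -75,   NA,     -60,   NA),
    inact_k  = c(NA,       -7,     NA,    NA,    -7,    NA,     -8,    NA),
    inact_tau = c(NA,      10,     NA,    NA,    25,    NA,     60,    NA),
    stringsAsFactors = FALSE
  )
  apply_gbar_scale(ch, gbar_scale)
}

#' @rdname point_dendrite_channels
#' @details `neuron_channels()` is the complement used by the fractal neuron
#'   model: persistent/transient Na+ and K+ currents, a delayed rectifier,
#'   low- and high-voltage-activated Ca2+ currents, slow K+ currents and HCN.
#'   Region-specific densities (soma/trunk vs dendritic tree) are applied in
#'   [build_fractal_neuron()].
#' @export
neuron_channels <- function(E_K = nernst_potential(ion_baseline()),
                            gbar_scale = NULL) {
  ch <- data.frame(
    name     = c("K_leak", "Na_P", "Na_T", "K_P", "K_T", "K_DR", "K_Ca",
                 "K_M", "Ca_LVA", "Ca_HVA", "HCN"),
    gbar     = c(0.06,     0.30,   48,     1.2,   3.0,   7,      0.35,
                 0.35,    0.10,    0.10,   0.09),
    erev     = c(E_K,      60,     60,     E_K,   E_K,   E_K,    E_K,
                 E_K,     120,     120,    -45),
    is_k     = c(TRUE,     FALSE,  FALSE,  TRUE,  TRUE,  TRUE,   TRUE,
                 TRUE,    FALSE,   FALSE,  FALSE),
    p        = c(0,        1,      3,      1,     1,     1,      1,
                 1,       2,       2,      1),
    act_vh   = c(NA,       -50,    -45,    -15,   -50,   -25,    -20,
                 -35,     -50,     -20,    -82),
    act_k    = c(NA,       5,      6,      10,    15,    10,     10,
                 6,       6,       7,      -7),
    act_tau  = c(NA,       5,      0.1,    3,     2,     1.5,    80,
                 60,      5,       1.5,    50),
    q        = c(0,        0,      1,      0,     1,     0,      0,
                 0,       1,       1,      0),
    inact_vh = c(NA,       NA,     -50,    NA,    -75,   NA,     NA,
                 NA,      -80,     -65,    NA),
    inact_k  = c(NA,       NA,     -6,     NA,    -7,    NA,     NA,
                 NA,      -6,      -8,     NA),
    inact_tau = c(NA,      NA,     1,      NA,    25,    NA,     NA,
                 NA,      100,     60,     NA),
    stringsAsFactors = FALSE
  )
  apply_gbar_scale(ch, gbar_scale)
}

apply_gbar_scale <- function(ch, gbar_scale) {
  if (!is.null(gbar_scale)) {
    bad <- setdiff(names(gbar_scale), ch$name)
    if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
    i <- match(names(gbar_scale), ch$name)
    ch$gbar[i] <- ch$gbar[i] * unname(gbar_scale)
  }
  ch
}

#' Synaptic receptor kinetics
#'
#' Double-exponential conductance time courses (difference of decay and rise
#' exponentials, normalized to the stated peak conductance). The NMDA
#' conductance is additionally multiplied by the voltage-dependent magnesium
#' block [mg_block()].
#'
#' Peak conductances are per synapse (nS) and were calibrated together with
#' the channel densities (methods vignette); the AMPA and NMDA conductances of
#' each synapse are scaled by that synapse's orientation-tuned activity.
#'
#' @param g_ampa,g_nmda,g_gaba Peak conductances, nS.
#' @return data.frame with one row per receptor type: `name`, `g_nS`,
#'   `tau_rise`, `tau_decay` (ms), `erev` (mV), `is_nmda`.
#' @export
synapse_kinetics <- function(g_ampa = 0.25, g_nmda = 0.86, g_gaba = 0.5) {
  data.frame(
    name      = c("AMPA", "NMDA", "GABA_A"),
    g_nS      = c(g_ampa, g_nmda, g_gaba),
    tau_rise  = c(0.2,    2,      0.5),
    tau_decay = c(2,      75,     8),
    erev      = c(0,      0,      -70),
    is_nmda   = c(FALSE,  TRUE,   FALSE),
    stringsAsFactors = FALSE
  )
}

#' Voltage-dependent magnesium block of the NMDA receptor
#'
#' Standard sigmoidal form `1 / (1 + [Mg] / 3.57 * exp(-0.062 V))` with the
#' extracellular magnesium concentration in mM.
#'
#' @param v Membrane potential, mV.
#' @param mg Magnesium concentration, mM (default 1).
#' @return Unblocked fraction in `(0, 1]`.
#' @export
mg_block <- function(v, mg = 1) {
  1 / (1 + mg / 3.57 * exp(-0.062 * v))
}

# peak value of exp(-t/taud) - exp(-t/taur); used to normalize double
# exponentials so the stated conductance is the true peak
dexp_peak <- function(tau_rise, tau_decay) {
  tp <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  exp(-tp / tau_decay) - exp(-tp / tau_rise)
}

# surface area (cm^2) of a cylinder given length and radius in um
cylinder_area_cm2 <- function(length_um, radius_um) {
  2 * pi * (radius_um * 1e-4) * (length_um * 1e-4)
}
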
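#' Instantaneous current-voltage curve of the point-dendrite system
#'
#' Net membrane current density as a function of voltage,
#' `I(V) = sum_i g_i(V) (E_i - V) + sum_syn g_syn (E_syn - V)`, with the sign
#' convention that positive (inward) current depolarizes, so `dV/dt = I / C`.
#' Gates can be evaluated at their voltage steady state (instantaneous-curve
#' convention), frozen at supplied trajectory values, or mixed (fast gates at
#' steady state, slow gates frozen) -- the convention is recorded in the
#' result.
#'
#' @param channels Channel table ([point_dendrite_channels()]).
#' @param syn_g Named vector of synaptic conductance densities (mS/cm^2),
#'   e.g. `c(NMDA = 0.6, AMPA = 0.2)`. NMDA is passed through [mg_block()].
#' @param delta_EK Imposed potassium reversal shift, mV.
#' @param V_grid Voltage grid, mV (default -90..10 by 0.25).
#' @param gate_mode `"steady"`, `"frozen"` or `"mixed"`.
#' @param gate_values List with `act`, `inact` per-channel values (required
#'   for `"frozen"`/`"mixed"`).
#' @param tau_fast Gate time constants at or below this (ms) count as fast in
#'   `"mixed"` mode (default 5).
#' @param kin Receptor kinetics.
#' @param time Optional time stamp (ms) carried through to the result.
#' @return Object of class `iv_curve`: data.frame `V_mV`, `I` (mS/cm^2 * mV,
#'   i.e. uA/cm^2), with attributes `delta_EK`, `gate_mode`, `time`.
#' @export
iv_curve <- function(channels, syn_g = NULL, delta_EK = 0,
                     V_grid = seq(-90, 10, by = 0.25),
                     gate_mode = c("steady", "frozen", "mixed"),
                     gate_values = NULL, tau_fast = 5,
                     kin = synapse_kinetics(), time = NA_real_) {
  gate_mode <- match.arg(gate_mode)
  if (!length(V_grid)) stop("empty voltage grid")
  if (gate_mode != "steady" && is.null(gate_values)) {
    stop("`gate_values` required for frozen/mixed gate modes")
  }
  m <- channel_matrix(channels)
  I <- numeric(length(V_grid))
  for (i in seq_len(nrow(m))) {
    use_frozen_act <- gate_mode == "frozen" ||
      (gate_mode == "mixed" && m[i, "act_tau"] > tau_fast)
    use_frozen_inact <- gate_mode == "frozen" ||
      (gate_mode == "mixed" && m[i, "inact_tau"] > tau_fast)
    a <- if (m[i, "p"] > 0) {
      if (use_frozen_act) rep(gate_values$act[i], length(V_grid))
      else 1 / (1 + exp(-(V_grid - m[i, "act_vh"]) / m[i, "act_k"]))
    } else rep(1, length(V_grid))
    h <- if (m[i, "q"] > 0) {
      if (use_frozen_inact) rep(gate_values$inact[i], length(V_grid))
      else 1 / (1 + exp(-(V_grid - m[i, "inact_vh"]) / m[i, "inact_k"]))
    } else rep(1, length(V_grid))
    g <- m[i, "gbar"] * a^m[i, "p"] * h^m[i, "q"]
    e <- m[i, "erev"] + if (m[i, "is_k"] > 0) delta_EK else 0
    I <- I + g * (e - V_grid)
  }
  if (!is.null(syn_g)) {
    for (nm in names(syn_g)) {
      row <- which(kin$name == nm)
      g <- rep(syn_g[[nm]], length(V_grid))
      if (kin$is_nmda[row]) g <- g * mg_block(V_grid)
      I <- I + g * (kin$erev[row] - V_grid)
    }
  }
  out <- data.frame(V_mV = V_grid, I = I)
  class(out) <- c("iv_curve", "data.frame")
  attr(out, "delta_EK") <- delta_EK
  attr(out, "gate_mode") <- gate_mode
  attr(out, "time") <- time
  out
}

#' Locate and classify the fixed points of an I-V curve
#'
#' Scans the curve for sign changes of the net current, refines each root by
#' bisection of the underlying linear interpolant to `tol` (mV), and
#' classifies stability from the local slope: with positive current
#' depolarizing, a fixed point is stable when `dI/dV < 0`.
#'
#' @param curve An [iv_curve()].
#' @param tol Bisection tolerance in mV (default 1e-3).
#' @return data.frame with `V_star_mV`, `stability` (`"stable"` /
#'   `"unstable"`), `I_residual`; zero rows when the curve has no zero
#'   crossing.
#' @export
find_fixed_points <- function(curve, tol = 1e-3) {
  stopifnot(inherits(curve, "iv_curve"))
  V <- curve$V_mV
  I <- curve$I
  f <- stats::approxfun(V, I)
  res_tol <- 1e-9 * max(abs(I))
  sgn <- sign(I)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  roots <- lapply(idx, function(i) {
    lo <- V[i]
    hi <- V[i + 1]
    # refine until both the bracket and the current residual are tiny
    while ((hi - lo > tol || abs(f((lo + hi) / 2)) > res_tol) &&
           hi - lo > 1e-12) {
      mid <- (lo + hi) / 2
      if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
    }
    v_star <- (lo + hi) / 2
    slope <- (f(min(max(V), v_star + 0.5)) - f(max(min(V), v_star - 0.5)))
    data.frame(V_star_mV = v_star,
               stability = if (slope < 0) "stable" else "unstable",
               I_residual = f(v_star))
  })
  exact <- which(I == 0)
  if (length(exact)) {
    roots <- c(roots, lapply(exact, function(i) {
      slope <- if (i < length(V)) I[i + 1] - I[i] else I[i] - I[i - 1]
      data.frame(V_star_mV = V[i],
                 stability = if (slope < 0) "stable" else "unstable",
                 I_residual = 0)
    }))
  }
  if (!length(roots)) {
    return(data.frame(V_star_mV = numeric(0), stability = character(0),
                      I_residual = numeric(0)))
  }
  out <- do.call(rbind, roots)
  out[order(out$V_star_mV), , drop = FALSE]
}

#' Time-resolved I-V attractor landscape over one stimulation event
#'
#' Simulates the point dendrite through a single synchronous stimulation
#' event (all synapses at t = 0) to obtain the gate and synaptic-conductance
#' trajectories, then stacks instantaneous I-V curves over the trial
#' timebase, tracking every fixed point. Under a positive reversal shift the
#' down-state fixed point sits depolarized, the voltage barrier (unstable
#' minus down-stable fixed point) is lower, and the bi-/up-stable epoch lasts
#' longer.
#'
#' @param delta_EK Reversal shift applied throughout, mV.
#' @param n_synapses Number of active synapses (default 10).
#' @param w Common synaptic weight (default 0.8).
#' @param t_max,dt_curve Timebase: curves are computed every `dt_curve` ms up
#'   to `t_max` (defaults 100 and 1).
#' @param channels,kin Model tables.
#' @param V_grid Voltage grid, mV.
#' @param gate_mode Gate convention for the curves (default `"mixed"`).
#' @param dt Integration step for the companion trajectory, ms.
#' @return Object of class `iv_landscape`: list with `t_ms`, `V_grid`,
#'   `current` (time x voltage matrix), `fixed_points` (data.frame `t_ms`,
#'   `V_star_mV`, `stability`), `trace` (companion V_m trajectory),
#'   `delta_EK`.
#' @export
iv_landscape <- function(delta_EK = 0, n_synapses = 10, w = 0.8,
                         t_max = 100, dt_curve = 1,
                         channels = point_dendrite_channels(),
                         kin = synapse_kinetics(),
                         V_grid = seq(-90, 10, by = 0.25),
                         gate_mode = "mixed",
                         dt = 0.025) {
  area <- cylinder_area_cm2(10, 1)
  # synchronous activation at t = 0; conductance densities per type
  amp_density <- function(type) {
    row <- which(kin$name == type)
    n_synapses * w * kin$g_nS[row] * 1e-6 / area /
      dexp_peak(kin$tau_rise[row], kin$tau_decay[row])
  }
  v0 <- resting_potential(channels, delta_EK)
  ev_time <- c(0, 0)
  ev_type <- c(which(kin$name == "AMPA"), which(kin$name == "NMDA")) - 1L
  ev_amp <- c(amp_density("AMPA"), amp_density("NMDA"))
  record_every <- max(1L, round(dt_curve / dt))
  res <- cpp_point_dendrite(channel_matrix(channels), 2, v0,
                            ev_time, as.integer(ev_type), ev_amp,
                            syn_matrix(kin), 0, delta_EK,
                            dt, t_max, record_every, 1.0)
  nch <- nrow(channels)
  t_ms <- res$t_ms
  syn_density <- function(type, t) {
    row <- which(kin$name == type)
    norm <- dexp_peak(kin$tau_rise[row], kin$tau_decay[row])
    base <- n_synapses * w * kin$g_nS[row] * 1e-6 / area / norm
    ifelse(t < 0, 0, base * (exp(-t / kin$tau_decay[row]) -
                               exp(-t / kin$tau_rise[row])))
  }
  current <- matrix(NA_real_, nrow = length(t_ms), ncol = length(V_grid))
  fp <- list()
  for (i in seq_along(t_ms)) {
    gv <- list(act = res$gates[i, seq_len(nch)],
               inact = res$gates[i, nch + seq_len(nch)])
    curve <- iv_curve(channels,
                      syn_g = c(AMPA = syn_density("AMPA", t_ms[i]),
                                NMDA = syn_density("NMDA", t_ms[i])),
                      delta_EK = delta_EK, V_grid = V_grid,
                      gate_mode = gate_mode, gate_values = gv,
                      kin = kin, time = t_ms[i])
    current[i, ] <- curve$I
    pts <- find_fixed_points(curve)
    if (nrow(pts)) {
      pts$t_ms <- t_ms[i]
      fp[[length(fp) + 1L]] <- pts
    }
  }
  fixed_points <- if (length(fp)) do.call(rbind, fp) else
    data.frame(V_star_mV = numeric(0), stability = character(0),
               I_residual = numeric(0), t_ms = numeric(0))
  structure(list(t_ms = t_ms, V_grid = V_grid, current = current,
                 fixed_points = fixed_points,
                 trace = data.frame(t_ms = t_ms, v_mV = res$v_mV),
                 delta_EK = delta_EK, n_synapses = n_synapses, w = w),
            class = "iv_landscape")
}

#' @export
print.iv_landscape <- function(x, ...) {
  n_multi <- sum(tapply(x$fixed_points$V_star_mV, x$fixed_points$t_ms,
                        length) >= 3)
  cat(sprintf(
    "<iv_landscape> delta_EK = %g mV; %d time points, %d with >= 3 fixed points\n",
    x$delta_EK, length(x$t_ms), n_multi))
  invisible(x)
}

#' Duration of bistable and up-stable epochs of a landscape
#'
#' Counts the time points whose fixed-point structure is not the single
#' hyperpolarized down-state: either three fixed points (bistable) or a
#' single depolarized stable point (up-stable, above `up_threshold` mV).
#'
#' @param landscape An [iv_landscape()].
#' @param up_threshold Voltage above which a lone stable fixed point counts
#'   as the up state (default -40 mV).
#' @return Total epoch duration in ms.
#' @export
excitable_epoch <- function(landscape, up_threshold = -40) {
  fps <- landscape$fixed_points
  if (!nrow(fps)) return(0)
  dt <- diff(landscape$t_ms)[1]
  per_t <- split(fps, fps$t_ms)
  sum(vapply(per_t, function(d) {
    nrow(d) >= 3 || (nrow(d) == 1 && d$stability == "stable" &&
                       d$V_star_mV > up_threshold)
  }, logical(1))) * dt
}
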
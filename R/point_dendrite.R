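#' Stimulation protocol for the point-dendrite model
#'
#' Three stimulation events separated by a constant inter-event interval; in
#' each event every synapse is activated once, at the event onset plus an
#' exponentially distributed delay (mean `delay_mean_ms`). The first event is
#' the control condition at resting reversal; from the second event onward the
#' potassium reversal is shifted as a step function.
#'
#' @param n_events Number of stimulation events (default 3).
#' @param inter_event_ms Interval between event onsets, ms (default 300).
#' @param delay_mean_ms Mean per-synapse activation delay, ms (default 80).
#' @param t_total Total simulated time, ms (default 1000, leaving a tail
#'   after the last 300-ms event window).
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(n_events = 3, inter_event_ms = 300,
                              delay_mean_ms = 80, t_total = 1000) {
  if (n_events < 1) stop("need at least one event")
  structure(list(n_events = n_events, inter_event_ms = inter_event_ms,
                 delay_mean_ms = delay_mean_ms, t_total = t_total,
                 onsets = (seq_len(n_events) - 1) * inter_event_ms),
            class = "stimulus_protocol")
}

# build sorted synaptic event table for one trial.
# weights: per-synapse activity scaling for AMPA and NMDA (same factor).
# Returns data.frame(time, type0 (0-based row into synapse_kinetics), amp_nS).
synaptic_events <- function(weights, protocol, kin,
                            gaba_times = NULL, gaba_g_nS = NULL) {
  ev <- list()
  for (onset in protocol$onsets) {
    delays <- stats::rexp(length(weights), rate = 1 / protocol$delay_mean_ms)
    for (k in c("AMPA", "NMDA")) {
      row <- which(kin$name == k)
      ev[[length(ev) + 1L]] <- data.frame(
        time = onset + delays,
        type0 = row - 1L,
        amp_nS = weights * kin$g_nS[row] / dexp_peak(kin$tau_rise[row],
                                                     kin$tau_decay[row])
      )
    }
  }
  if (!is.null(gaba_times) && length(gaba_times)) {
    row <- which(kin$name == "GABA_A")
    ev[[length(ev) + 1L]] <- data.frame(
      time = gaba_times,
      type0 = row - 1L,
      amp_nS = gaba_g_nS / dexp_peak(kin$tau_rise[row], kin$tau_decay[row])
    )
  }
  ev <- do.call(rbind, ev)
  ev[order(ev$time), , drop = FALSE]
}

channel_matrix <- function(channels) {
  m <- as.matrix(channels[, c("gbar", "erev", "is_k", "p", "act_vh", "act_k",
                              "act_tau", "q", "inact_vh", "inact_k",
                              "inact_tau")])
  storage.mode(m) <- "double"
  m[is.na(m)] <- 0
  m
}

syn_matrix <- function(kin) {
  m <- as.matrix(data.frame(kin$tau_rise, kin$tau_decay, kin$erev,
                            as.numeric(kin$is_nmda)))
  storage.mode(m) <- "double"
  m
}

# resting potential of a channel table: solve sum g_i(V)(E_i - V) = 0
resting_potential <- function(channels, delta_EK = 0) {
  cm <- channel_matrix(channels)
  f <- function(v) {
    tot <- 0
    for (i in seq_len(nrow(cm))) {
      g <- cm[i, "gbar"]
      if (cm[i, "p"] > 0) {
        g <- g * (1 / (1 + exp(-(v - cm[i, "act_vh"]) / cm[i, "act_k"])))^cm[i, "p"]
      }
      if (cm[i, "q"] > 0) {
        g <- g * 1 / (1 + exp(-(v - cm[i, "inact_vh"]) / cm[i, "inact_k"]))
      }
      e <- cm[i, "erev"] + if (cm[i, "is_k"] > 0) delta_EK else 0
      tot <- tot + g * (e - v)
    }
    tot
  }
  stats::uniroot(f, c(-110, -20))$root
}

#' One exponential-Euler step of the membrane equation
#'
#' Advances the membrane potential by `V(t+dt) = V_inf + (V - V_inf)
#' exp(-dt / tau)` where `V_inf` is the conductance-weighted mean reversal
#' potential and `tau = C_m / g_total`; gate states are advanced by their own
#' exponential updates. This is the scheme used (in compiled form) by
#' [point_dendrite_trial()]; the R version exists for transparency and
#' testing.
#'
#' @param state List with `v` (mV), `act`, `inact` (per-channel gate values).
#' @param channels Channel table ([point_dendrite_channels()]).
#' @param syn_g Named vector of instantaneous synaptic conductance densities
#'   (mS/cm^2) per receptor type, e.g. `c(AMPA = 0, NMDA = 0.5, GABA_A = 0)`.
#'   NMDA is multiplied by [mg_block()] at the current potential.
#' @param dt Time step, ms (default 0.025).
#' @param cm Specific capacitance, uF/cm^2 (default 2, accounting for spine
#'   membrane).
#' @param delta_EK Imposed potassium reversal shift, mV.
#' @param kin Receptor kinetics ([synapse_kinetics()]), used for reversal
#'   potentials and the NMDA flag.
#' @return Updated `state` list, with `v_inf` and `tau` attached.
#' @export
exp_euler_step <- function(state, channels, syn_g = NULL, dt = 0.025,
                           cm = 2, delta_EK = 0, kin = synapse_kinetics()) {
  if (dt <= 0) stop("`dt` must be positive")
  m <- channel_matrix(channels)
  nch <- nrow(m)
  act <- state$act
  inact <- state$inact
  v <- state$v
  if (is.null(act)) act <- init_gates(m, v)$act
  if (is.null(inact)) inact <- init_gates(m, v)$inact
  gsum <- 0
  gesum <- 0
  for (i in seq_len(nch)) {
    if (m[i, "p"] > 0) {
      xinf <- 1 / (1 + exp(-(v - m[i, "act_vh"]) / m[i, "act_k"]))
      act[i] <- act[i] + (xinf - act[i]) * (1 - exp(-dt / m[i, "act_tau"]))
    }
    if (m[i, "q"] > 0) {
      xinf <- 1 / (1 + exp(-(v - m[i, "inact_vh"]) / m[i, "inact_k"]))
      inact[i] <- inact[i] + (xinf - inact[i]) * (1 - exp(-dt / m[i, "inact_tau"]))
    }
    g <- m[i, "gbar"] * act[i]^m[i, "p"] * inact[i]^m[i, "q"]
    e <- m[i, "erev"] + if (m[i, "is_k"] > 0) delta_EK else 0
    gsum <- gsum + g
    gesum <- gesum + g * e
  }
  if (!is.null(syn_g)) {
    for (nm in names(syn_g)) {
      row <- which(kin$name == nm)
      g <- syn_g[[nm]]
      if (kin$is_nmda[row]) g <- g * mg_block(v)
      gsum <- gsum + g
      gesum <- gesum + g * kin$erev[row]
    }
  }
  v_inf <- unname(gesum / gsum)
  tau <- unname(cm / gsum)
  v_new <- v_inf + (v - v_inf) * exp(-dt / tau)
  if (!is.finite(v_new)) stop("integration failure: non-finite Vm")
  list(v = v_new, act = unname(act), inact = unname(inact),
       v_inf = v_inf, tau = tau)
}

init_gates <- function(m, v) {
  nch <- nrow(m)
  act <- rep(1, nch)
  inact <- rep(1, nch)
  for (i in seq_len(nch)) {
    if (m[i, "p"] > 0) act[i] <- 1 / (1 + exp(-(v - m[i, "act_vh"]) / m[i, "act_k"]))
    if (m[i, "q"] > 0) inact[i] <- 1 / (1 + exp(-(v - m[i, "inact_vh"]) / m[i, "inact_k"]))
  }
  list(act = act, inact = inact)
}

#' Simulate one point-dendrite trial
#'
#' Runs the single-compartment dendritic-segment model through the 3-event
#' stimulation protocol. Event 1 runs at the resting potassium reversal;
#' subsequent events run with the reversal shifted by `delta_EK` (a step
#' change between events). Each synapse's AMPA and NMDA conductances are
#' scaled by its orientation-tuned activity at the stimulus orientation.
#'
#' @param segment A [sample_segment()] result, or `NULL` to build a segment of
#'   `n_synapses` identical synapses with activity `w` (the controlled-drive
#'   mode used for the threshold surface).
#' @param theta Stimulus orientation, degrees (ignored in controlled-drive
#'   mode).
#' @param delta_EK Imposed reversal shift for events 2+, mV (0 to 18).
#' @param protocol A [stimulus_protocol()].
#' @param channels Channel table (default [point_dendrite_channels()]).
#' @param kin Receptor kinetics (default [synapse_kinetics()]).
#' @param n_synapses,w Controlled-drive mode: synapse count and common
#'   activity weight (used when `segment` is `NULL`).
#' @param gaba Optional non-specific inhibition, a list from
#'   [gaba_background()].
#' @param cm Specific capacitance, uF/cm^2 (default 2).
#' @param dt Time step, ms (default 0.025).
#' @param record_every Record the trace every this many steps (default 4,
#'   i.e. 0.1 ms).
#' @param seed Optional integer seed (sets the R RNG for the synaptic
#'   delays).
#' @param engine `"cpp"` (default) or `"r"` (slow reference implementation
#'   used for solver validation).
#' @param spike_threshold Dendritic-spike voltage criterion, mV (default
#'   -30).
#' @return Object of class `pd_trial`: list with `trace` (data.frame `t_ms`,
#'   `v_mV`), `events` (per-event [spike metrics][spike_metrics]: `event`,
#'   `onset_ms`, `delta_EK`, `spiked`, `duration_ms`, `peak_mV`), `gates`
#'   (recorded gate matrix, cpp engine only) and the call parameters.
#' @export
#' @examples
#' tr <- point_dendrite_trial(theta = 0, delta_EK = 12, seed = 1)
#' tr$events
point_dendrite_trial <- function(segment = NULL, theta = 0, delta_EK = 0,
                                 protocol = stimulus_protocol(),
                                 channels = point_dendrite_channels(),
                                 kin = synapse_kinetics(),
                                 n_synapses = 10, w = NULL,
                                 gaba = NULL,
                                 cm = 2, dt = 0.025, record_every = 4,
                                 seed = NULL,
                                 engine = c("cpp", "r"),
                                 spike_threshold = -30) {
  engine <- match.arg(engine)
  if (delta_EK < 0) stop("`delta_EK` must be >= 0 (depolarizing shift)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(segment) && is.null(w)) {
    segment <- sample_segment("similar")
  }
  weights <- if (!is.null(segment)) {
    synapse_activity(orientation_distance(theta, segment$preferred),
                     segment$tuning_width)
  } else {
    rep(w, n_synapses)
  }
  area <- cylinder_area_cm2(10, 1)
  gaba_times <- NULL
  gaba_g <- NULL
  if (!is.null(gaba)) {
    gaba_times <- gaba$times
    gaba_g <- rep(gaba$g_nS, length(gaba_times))
  }
  ev <- synaptic_events(weights, protocol, kin, gaba_times, gaba_g)
  # nS -> mS/cm^2 conductance density
  ev$amp <- ev$amp_nS * 1e-6 / area
  v0 <- resting_potential(channels, 0)
  ek_time <- c(0, protocol$onsets[-1][1])
  ek_value <- c(0, delta_EK)
  if (protocol$n_events < 2) {
    ek_time <- 0
    ek_value <- 0
  }
  if (engine == "cpp") {
    res <- cpp_point_dendrite(channel_matrix(channels), cm, v0,
                              ev$time, as.integer(ev$type0), ev$amp,
                              syn_matrix(kin), ek_time, ek_value,
                              dt, protocol$t_total, as.integer(record_every),
                              1.0)
    trace <- data.frame(t_ms = res$t_ms, v_mV = res$v_mV)
    gates <- res$gates
  } else {
    trace <- r_point_dendrite(channels, kin, cm, v0, ev, ek_time, ek_value,
                              dt, protocol$t_total, record_every)
    gates <- NULL
  }
  events <- spike_metrics(trace, protocol, delta_EK,
                          threshold = spike_threshold)
  structure(list(trace = trace, events = events, gates = gates,
                 weights = weights, theta = theta, delta_EK = delta_EK,
                 protocol = protocol, channels = channels, kin = kin,
                 v0 = v0, dt = dt),
            class = "pd_trial")
}

# reference R implementation (synapse states aggregated per type, same
# numerics as the compiled path)
r_point_dendrite <- function(channels, kin, cm, v0, ev, ek_time, ek_value,
                             dt, t_total, record_every) {
  m <- channel_matrix(channels)
  sm <- syn_matrix(kin)
  nt <- ceiling(t_total / dt)
  g0 <- init_gates(m, v0)
  act <- g0$act
  inact <- g0$inact
  synA <- numeric(nrow(sm))
  synB <- numeric(nrow(sm))
  decA <- exp(-dt / sm[, 1])
  decB <- exp(-dt / sm[, 2])
  fact <- ifelse(m[, "p"] > 0, 1 - exp(-dt / m[, "act_tau"]), 0)
  finact <- ifelse(m[, "q"] > 0, 1 - exp(-dt / m[, "inact_tau"]), 0)
  v <- v0
  iev <- 1L
  iek <- 1L
  dek <- 0
  rec_t <- numeric()
  rec_v <- numeric()
  for (i in seq_len(nt)) {
    t_now <- (i - 1) * dt
    while (iek <= length(ek_time) && ek_time[iek] <= t_now) {
      dek <- ek_value[iek]
      iek <- iek + 1L
    }
    while (iev <= nrow(ev) && ev$time[iev] <= t_now) {
      s <- ev$type0[iev] + 1L
      synA[s] <- synA[s] + ev$amp[iev]
      synB[s] <- synB[s] + ev$amp[iev]
      iev <- iev + 1L
    }
    xinf <- 1 / (1 + exp(-(v - m[, "act_vh"]) / m[, "act_k"]))
    act <- act + (xinf - act) * fact
    yinf <- 1 / (1 + exp(-(v - m[, "inact_vh"]) / m[, "inact_k"]))
    yinf[m[, "q"] == 0] <- 1
    inact <- inact + (yinf - inact) * finact
    g <- m[, "gbar"] * act^m[, "p"] * inact^m[, "q"]
    e <- m[, "erev"] + m[, "is_k"] * dek
    gs <- pmax(synB - synA, 0)
    gs[sm[, 4] > 0] <- gs[sm[, 4] > 0] * mg_block(v)
    synA <- synA * decA
    synB <- synB * decB
    gsum <- sum(g) + sum(gs)
    vinf <- (sum(g * e) + sum(gs * sm[, 3])) / gsum
    v <- vinf + (v - vinf) * exp(-dt / (cm / gsum))
    if (!is.finite(v)) stop("integration failure: non-finite Vm")
    if ((i - 1) %% record_every == 0) {
      rec_t <- c(rec_t, t_now)
      rec_v <- c(rec_v, v)
    }
  }
  data.frame(t_ms = rec_t, v_mV = rec_v)
}

#' Per-event dendritic spike metrics
#'
#' Splits a trace into consecutive event windows (one inter-event interval
#' each) and reports, per event, the time spent above the spike threshold
#' (-30 mV), whether a dendritic spike occurred, and the peak potential.
#'
#' @param trace data.frame with `t_ms`, `v_mV`.
#' @param protocol The [stimulus_protocol()] used.
#' @param delta_EK Shift applied from event 2 on (stored in the output).
#' @param threshold Spike criterion, mV (default -30).
#' @return data.frame, one row per event.
#' @export
spike_metrics <- function(trace, protocol, delta_EK = 0, threshold = -30) {
  dt_rec <- median(diff(trace$t_ms))
  out <- lapply(seq_len(protocol$n_events), function(k) {
    t0 <- protocol$onsets[k]
    t1 <- t0 + protocol$inter_event_ms
    win <- trace$v_mV[trace$t_ms >= t0 & trace$t_ms < t1]
    dur <- sum(win > threshold) * dt_rec
    data.frame(event = k, onset_ms = t0,
               delta_EK = if (k == 1) 0 else delta_EK,
               spiked = dur > 0, duration_ms = dur, peak_mV = max(win))
  })
  do.call(rbind, out)
}

#' @export
print.pd_trial <- function(x, ...) {
  cat(sprintf("<pd_trial> theta = %g deg, delta_EK = %g mV, rest = %.1f mV\n",
              x$theta, x$delta_EK, x$v0))
  print(x$events, row.names = FALSE)
  invisible(x)
}

#' Background GABA_A activation
#'
#' Poisson-timed inhibitory synapse activations superimposed on a trial:
#' `density` synapses per um over the 10-um segment, each firing as an
#' independent Poisson process at `rate_hz`.
#'
#' @param density GABA_A synapses per um (default 0.2, i.e. 2 synapses on a
#'   10-um segment).
#' @param rate_hz Mean activation rate per synapse, Hz (default 10).
#' @param conductance_scale Multiplier on the GABA_A peak conductance
#'   (default 1).
#' @param t_total Duration over which to draw activations, ms.
#' @param segment_length Segment length, um (default 10).
#' @param kin Receptor kinetics (source of the base GABA_A conductance).
#' @return List with `times` (ms) and `g_nS`, suitable for the `gaba`
#'   argument of [point_dendrite_trial()].
#' @export
gaba_background <- function(density = 0.2, rate_hz = 10,
                            conductance_scale = 1, t_total = 1000,
                            segment_length = 10,
                            kin = synapse_kinetics()) {
  if (rate_hz < 0) stop("`rate_hz` must be >= 0")
  n_syn <- round(density * segment_length)
  n_act <- stats::rpois(1, n_syn * rate_hz * t_total / 1000)
  times <- sort(stats::runif(n_act, 0, t_total))
  list(times = times,
       g_nS = conductance_scale * kin$g_nS[kin$name == "GABA_A"])
}

#' Minimal reversal shift for dendritic spiking over a parameter grid
#'
#' For each combination of synapse count `N` and common synaptic weight `w`,
#' scans the reversal-shift grid upward and reports the smallest shift for
#' which the majority of trials produce a dendritic spike in the shifted
#' events. Cells that spike without any shift report 0 ("no shift needed");
#' cells that never spike within the scanned range report `NA` ("never
#' spikes").
#'
#' @param N_grid Synapse counts (default `7:13`).
#' @param w_grid Common weights in `[0, 1]`.
#' @param EK_grid Candidate shifts, mV, ascending (default `seq(0, 18, 2)`).
#' @param trials_per_cell Trials per grid cell (default 3; the outcome is the
#'   majority vote).
#' @param seed Integer seed.
#' @param ... Passed to [point_dendrite_trial()].
#' @return data.frame with `N`, `w`, `min_shift_mV` (NA when never spiking)
#'   and `category` in `{"no shift needed", "shift", "never spikes"}`.
#' @export
threshold_surface <- function(N_grid = 7:13,
                              w_grid = seq(0.1, 0.9, by = 0.1),
                              EK_grid = seq(0, 18, by = 2),
                              trials_per_cell = 3,
                              seed = NULL, ...) {
  if (!length(N_grid) || !length(w_grid) || !length(EK_grid)) {
    stop("grids must be non-empty")
  }
  if (is.unsorted(EK_grid)) stop("`EK_grid` must be ascending")
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(N = N_grid, w = w_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    N <- grid$N[i]
    w <- grid$w[i]
    min_shift <- NA_real_
    for (ek in EK_grid) {
      spikes <- vapply(seq_len(trials_per_cell), function(j) {
        tr <- point_dendrite_trial(segment = NULL, delta_EK = ek,
                                   n_synapses = N, w = w, ...)
        any(tr$events$spiked[tr$events$event > 1])
      }, logical(1))
      if (mean(spikes) >= 0.5) {
        min_shift <- ek
        break
      }
    }
    category <- if (is.na(min_shift)) "never spikes" else
      if (min_shift == 0) "no shift needed" else "shift"
    data.frame(N = N, w = w, min_shift_mV = min_shift, category = category)
  })
  do.call(rbind, res)
}

#' Spike-duration broadening under a reversal shift
#'
#' Runs `n_trials` point-dendrite trials at the target orientation with the
#' 3-event protocol and reports the percent increase of the mean dendritic
#' spike duration (time above -30 mV, averaged over spiking events) in the
#' shifted events relative to the control event.
#'
#' @param delta_EK Reversal shift for events 2+, mV (default 12).
#' @param n_trials Number of trials (default 10).
#' @param theta Stimulus orientation, degrees (default 0).
#' @param seed Integer seed.
#' @param ... Passed to [point_dendrite_trial()].
#' @return List with `percent_increase`, `mean_control_ms`,
#'   `mean_shifted_ms`, `p_control`, `p_shifted` (spike probabilities) and
#'   the per-trial event table.
#' @export
spike_duration_broadening <- function(delta_EK = 12, n_trials = 10,
                                      theta = 0, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ev <- do.call(rbind, lapply(seq_len(n_trials), function(i) {
    tr <- point_dendrite_trial(theta = theta, delta_EK = delta_EK, ...)
    cbind(trial = i, tr$events)
  }))
  ctrl <- ev$duration_ms[ev$event == 1]
  shift <- ev$duration_ms[ev$event > 1]
  mc <- mean(ctrl[ctrl > 0])
  ms <- mean(shift[shift > 0])
  list(percent_increase = 100 * (ms / mc - 1),
       mean_control_ms = mc, mean_shifted_ms = ms,
       p_control = mean(ctrl > 0), p_shifted = mean(shift > 0),
       events = ev)
}
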
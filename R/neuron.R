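#' Build the abstract fractal neuron morphology
#'
#' The apical tree is a self-similar fractal: every section branches into 3
#' children of half its length, and the most distal sections are
#' `distal_length` long, giving fractal dimension `ln 3 / ln 2 = 1.58`. The
#' tree root attaches to a 500-um trunk, which attaches to a 30 x 10 um soma.
#' Section diameters taper linearly from `root_diam` at the first tree
#' generation to `distal_diam` at the last.
#'
#' @param generations Number of tree generations (default 4, i.e. 120 tree
#'   sections of which 81 are distal).
#' @param distal_length Length of the most distal sections, um (default 20).
#' @param trunk_length Trunk length, um (default 500).
#' @param trunk_diam,root_diam,distal_diam Diameters, um.
#' @param soma_length,soma_diam Soma cylinder, um (defaults 30 and 10).
#' @param Ra Axial resistivity, ohm cm (default 150).
#' @param max_comp_length Target compartment length, um (default 20; each
#'   section is split into `ceiling(length / max_comp_length)` compartments).
#' @param scale Overall length scale factor: multiplies every section length
#'   (diameters unchanged); used by [distance_scaling()].
#' @return Object of class `fractal_neuron`: list with `sections`
#'   (data.frame: `section`, `parent`, `generation`, `type`, `length_um`,
#'   `diam_um`), `compartments` (data.frame: `comp`, `section`, `parent`,
#'   `type`, `length_um`, `diam_um`, `area_cm2`, `g_axial_mS`), counts and
#'   parameters.
#' @export
#' @examples
#' m <- build_fractal_neuron(generations = 2)
#' m$n_distal  # 9 distal sections
build_fractal_neuron <- function(generations = 4, distal_length = 20,
                                 trunk_length = 500, trunk_diam = 4,
                                 root_diam = 3, distal_diam = 1,
                                 soma_length = 30, soma_diam = 10,
                                 Ra = 150, max_comp_length = 20,
                                 scale = 1) {
  if (generations < 1) stop("need at least one tree generation")
  sec <- data.frame(section = 1L, parent = NA_integer_, generation = NA_integer_,
                    type = "soma", length_um = soma_length * scale,
                    diam_um = soma_diam, stringsAsFactors = FALSE)
  sec <- rbind(sec, data.frame(section = 2L, parent = 1L, generation = NA,
                               type = "trunk", length_um = trunk_length * scale,
                               diam_um = trunk_diam))
  diam_for_gen <- function(g) {
    if (generations == 1) return(distal_diam)
    root_diam + (distal_diam - root_diam) * (g - 1) / (generations - 1)
  }
  parents <- 2L  # trunk
  next_id <- 3L
  for (g in seq_len(generations)) {
    len <- distal_length * 2^(generations - g) * scale
    kids <- integer(0)
    for (p in parents) {
      ids <- next_id + 0:2
      sec <- rbind(sec, data.frame(
        section = ids, parent = p, generation = g,
        type = if (g == generations) "distal" else "tree",
        length_um = len, diam_um = diam_for_gen(g)))
      kids <- c(kids, ids)
      next_id <- next_id + 3L
    }
    parents <- kids
  }
  rownames(sec) <- NULL

  # discretize into compartments; parent comp index always smaller
  comp <- list()
  sec_last_comp <- integer(nrow(sec))  # most distal compartment per section
  cid <- 0L
  for (i in seq_len(nrow(sec))) {
    n <- max(1L, ceiling(sec$length_um[i] / max_comp_length))
    l <- sec$length_um[i] / n
    for (j in seq_len(n)) {
      cid <- cid + 1L
      parent_comp <- if (j > 1) cid - 1L else
        if (is.na(sec$parent[i])) NA_integer_ else sec_last_comp[sec$parent[i]]
      comp[[cid]] <- data.frame(
        comp = cid, section = sec$section[i], parent = parent_comp,
        type = sec$type[i], length_um = l, diam_um = sec$diam_um[i])
    }
    sec_last_comp[i] <- cid
  }
  comp <- do.call(rbind, comp)
  comp$area_cm2 <- pi * comp$diam_um * comp$length_um * 1e-8
  # axial conductance to parent: series of half-cylinder resistances
  half_res <- function(i) {  # ohm
    4 * Ra * (comp$length_um[i] / 2) / (pi * comp$diam_um[i]^2) * 1e4
  }
  comp$g_axial_mS <- NA_real_
  for (i in seq_len(nrow(comp))) {
    p <- comp$parent[i]
    if (!is.na(p)) comp$g_axial_mS[i] <- 1e3 / (half_res(i) + half_res(p))
  }
  structure(list(
    sections = sec, compartments = comp,
    sec_last_comp = sec_last_comp,
    n_tree = sum(!sec$type %in% c("soma", "trunk")),
    n_distal = sum(sec$type == "distal"),
    generations = generations, Ra = Ra, scale = scale,
    fractal_dimension = log(3) / log(2)
  ), class = "fractal_neuron")
}

#' @export
print.fractal_neuron <- function(x, ...) {
  cat(sprintf(
    "<fractal_neuron> %d generations, %d tree sections (%d distal), %d compartments, scale = %g\n",
    x$generations, x$n_tree, x$n_distal, nrow(x$compartments), x$scale))
  invisible(x)
}

# default per-region channel density multipliers (on neuron_channels() gbar)
neuron_region_gbar <- function() {
  list(
    soma  = c(K_leak = 1, Na_P = 1, Na_T = 1, K_P = 1, K_T = 1, K_DR = 1,
              K_Ca = 1, K_M = 1, Ca_LVA = 1, Ca_HVA = 1, HCN = 1),
    trunk = c(K_leak = 1, Na_P = 0.5, Na_T = 0.1, K_P = 1, K_T = 1,
              K_DR = 0.1, K_Ca = 1, K_M = 1, Ca_LVA = 1, Ca_HVA = 1,
              HCN = 1),
    tree  = c(K_leak = 1, Na_P = 0.3, Na_T = 0.01, K_P = 1, K_T = 1,
              K_DR = 0.02, K_Ca = 1, K_M = 1, Ca_LVA = 1, Ca_HVA = 1,
              HCN = 1)
  )
}

# absolute conductance matrix (mS): compartments x channels
neuron_gdens <- function(morph, channels, region_gbar = neuron_region_gbar(),
                         na_block = FALSE) {
  comp <- morph$compartments
  region <- ifelse(comp$type %in% c("tree", "distal"), "tree", comp$type)
  gd <- matrix(0, nrow(comp), nrow(channels),
               dimnames = list(NULL, channels$name))
  for (r in unique(region)) {
    mult <- region_gbar[[r]][channels$name]
    rows <- region == r
    gd[rows, ] <- outer(comp$area_cm2[rows], channels$gbar * mult)
  }
  if (na_block) {
    blocked <- comp$type %in% c("soma", "trunk")
    gd[blocked, channels$name %in% c("Na_T", "Na_P")] <- 0
  }
  gd
}

#' Simulate the fractal neuron under orientation-tuned distal input
#'
#' Selects a Poisson-distributed number of distal sections (mean
#' `lambda_segments`) to host similarly tuned dendritic segments, activates
#' their synapses over `n_events` stimulation events (per-synapse
#' exponential delays, mean `lambda_activation_ms`), imposes the local
#' reversal shift `delta_EK` on the stimulated distal compartments, and
#' integrates the coupled cable equations (backward Euler / Hines solver).
#'
#' @param morph A [build_fractal_neuron()] morphology.
#' @param theta Stimulus orientation, degrees.
#' @param delta_EK Local reversal shift in stimulated distal compartments,
#'   mV (conditions 0 / 6 / 18 in the main analysis).
#' @param seed Integer seed; with the same seed the synapse layout and
#'   activation times are identical across `delta_EK` conditions (paired
#'   design).
#' @param channels Channel table ([neuron_channels()]).
#' @param kin Receptor kinetics.
#' @param region_gbar Per-region density multipliers.
#' @param na_block If `TRUE`, voltage-gated Na channels in soma and trunk are
#'   silenced (used for the trunk AUC measurements; abolishes somatic
#'   firing).
#' @param lambda_segments Mean number of stimulated distal sections
#'   (default 32).
#' @param lambda_activation_ms Mean synapse activation delay within an
#'   event, ms (default 30).
#' @param n_events,inter_event_ms Stimulation train (defaults 3 and 300).
#' @param t_total Simulated time, ms (default 1000).
#' @param dt Time step, ms (default 0.025).
#' @param record_every Trace recording stride (default 4).
#' @param syn_gain Multiplier on AMPA/NMDA conductances (calibration knob).
#' @param cm_dend,cm_soma Specific capacitance, uF/cm^2.
#' @return Object of class `neuron_sim`: list with `soma` and `trunk_base`
#'   traces (data.frame `t_ms`, `v_mV`), `spikes` (somatic spike times),
#'   `rate_hz`, `stimulated_sections`, and the call parameters.
#' @export
simulate_neuron <- function(morph, theta = 0, delta_EK = 0, seed = NULL,
                            channels = neuron_channels(),
                            kin = synapse_kinetics(),
                            region_gbar = neuron_region_gbar(),
                            na_block = FALSE,
                            lambda_segments = 32,
                            lambda_activation_ms = 30,
                            n_events = 3, inter_event_ms = 300,
                            t_total = 1000, dt = 0.025, record_every = 4,
                            syn_gain = 10.5,
                            cm_dend = 2, cm_soma = 1) {
  if (!is.null(seed)) set.seed(seed)
  comp <- morph$compartments
  distal_secs <- morph$sections$section[morph$sections$type == "distal"]
  n_stim <- min(length(distal_secs), max(1L, stats::rpois(1, lambda_segments)))
  stim_secs <- sample(distal_secs, n_stim)

  ev <- list()
  for (s in stim_secs) {
    seg <- sample_segment("similar")
    act <- synapse_activity(orientation_distance(theta, seg$preferred),
                            seg$tuning_width)
    target_comp <- morph$sec_last_comp[s]
    for (onset in (seq_len(n_events) - 1) * inter_event_ms) {
      delays <- stats::rexp(length(act), rate = 1 / lambda_activation_ms)
      for (k in c("AMPA", "NMDA")) {
        row <- which(kin$name == k)
        g_abs <- syn_gain * act * kin$g_nS[row] * 1e-6 /
          dexp_peak(kin$tau_rise[row], kin$tau_decay[row])  # mS
        ev[[length(ev) + 1L]] <- data.frame(
          time = onset + delays, comp = target_comp, type0 = row - 1L,
          amp = g_abs)
      }
    }
  }
  ev <- do.call(rbind, ev)
  ev <- ev[order(ev$time), , drop = FALSE]

  gd <- neuron_gdens(morph, channels, region_gbar, na_block)
  dek <- numeric(nrow(comp))
  stim_comps <- comp$comp[comp$section %in% stim_secs]
  dek[stim_comps] <- delta_EK
  cm_abs <- ifelse(comp$type == "soma", cm_soma, cm_dend) * comp$area_cm2  # uF
  g_ax <- comp$g_axial_mS
  g_ax[is.na(g_ax)] <- 0
  soma_comp <- comp$comp[comp$type == "soma"][1]
  trunk_base_comp <- comp$comp[comp$type == "trunk"][1]
  extra_comps <- integer(0)
  if (length(stim_secs)) extra_comps <- morph$sec_last_comp[stim_secs[1]]
  v0 <- -78
  parent0 <- ifelse(is.na(comp$parent), -1L, comp$parent - 1L)
  res <- cpp_cable_sim(as.integer(parent0),
                       cm_abs, g_ax, channel_matrix(channels), gd, dek,
                       ev$time, as.integer(ev$comp) - 1L,
                       as.integer(ev$type0), ev$amp,
                       syn_matrix(kin), dt, t_total,
                       as.integer(c(soma_comp, trunk_base_comp,
                                    extra_comps)) - 1L,
                       as.integer(record_every), 1.0, v0)
  soma <- data.frame(t_ms = res$t_ms, v_mV = res$v_mV[, 1])
  trunk <- data.frame(t_ms = res$t_ms, v_mV = res$v_mV[, 2])
  distal <- if (length(extra_comps)) {
    data.frame(t_ms = res$t_ms, v_mV = res$v_mV[, 3])
  } else NULL
  spikes <- detect_spikes(soma$t_ms, soma$v_mV)
  structure(list(
    soma = soma, trunk_base = trunk, distal_example = distal, spikes = spikes,
    rate_hz = length(spikes) / (t_total / 1000),
    stimulated_sections = stim_secs, theta = theta, delta_EK = delta_EK,
    na_block = na_block, t_total = t_total
  ), class = "neuron_sim")
}

#' Detect somatic spikes
#'
#' Upward crossings of `threshold` (default 0 mV) separated by at least
#' `refractory_ms`.
#'
#' @param t_ms,v_mV Trace vectors.
#' @param threshold Detection threshold, mV.
#' @param refractory_ms Deduplication window, ms (default 2).
#' @return Spike times, ms.
#' @export
detect_spikes <- function(t_ms, v_mV, threshold = 0, refractory_ms = 2) {
  up <- which(v_mV[-1] >= threshold & v_mV[-length(v_mV)] < threshold) + 1L
  if (!length(up)) return(numeric(0))
  times <- t_ms[up]
  keep <- c(TRUE, diff(times) > refractory_ms)
  times[keep]
}

#' @export
print.neuron_sim <- function(x, ...) {
  cat(sprintf(
    "<neuron_sim> theta = %g deg, delta_EK = %g mV: %d somatic spikes (%.1f Hz)%s\n",
    x$theta, x$delta_EK, length(x$spikes), x$rate_hz,
    if (x$na_block) " [Na blocked in soma/trunk]" else ""))
  invisible(x)
}

#' Somatic firing-rate tuning under paired reversal-shift conditions
#'
#' Runs `n_trials` independent neuron setups; each setup (synapse layout and
#' activation times, fixed by the per-trial seed) is simulated once per
#' reversal-shift condition, giving a paired design.
#'
#' @param morph A [build_fractal_neuron()].
#' @param theta_grid Orientations, degrees.
#' @param conditions Reversal-shift conditions, mV (default `c(0, 6, 18)`).
#' @param n_trials Paired simulations per orientation (default 15).
#' @param seed Integer seed.
#' @param ... Passed to [simulate_neuron()].
#' @return data.frame with `theta_deg`, `delta_EK`, `trial`, `rate_hz`.
#' @export
neuron_tuning <- function(morph, theta_grid = seq(0, 90, by = 15),
                          conditions = c(0, 6, 18), n_trials = 15,
                          seed = 1, ...) {
  out <- list()
  for (th in theta_grid) {
    for (tr in seq_len(n_trials)) {
      trial_seed <- seed + 1000 * tr + round(th)
      for (ek in conditions) {
        sim <- simulate_neuron(morph, theta = th, delta_EK = ek,
                               seed = trial_seed, ...)
        out[[length(out) + 1L]] <- data.frame(
          theta_deg = th, delta_EK = ek, trial = tr, rate_hz = sim$rate_hz)
      }
    }
  }
  do.call(rbind, out)
}

#' Multiplicative and additive gain fits of a tuning transformation
#'
#' Chi-square fits of `FR_after = xi_mul * FR_before` (multiplicative) and
#' `FR_after = FR_before + xi_add` (additive) to orientation-resolved firing
#' rates with Gaussian errors. Orientations with zero standard deviation are
#' excluded.
#'
#' @param fr_before,fr_after Mean firing rates per orientation.
#' @param sd_after Standard deviations of `fr_after` (used as the chi-square
#'   weights).
#' @return Object of class `gain_fit`: list with `xi_mul`, `xi_add`, their
#'   standard errors, `chisq_mul`, `chisq_add`, `n`.
#' @export
#' @examples
#' fit_gain(c(1, 2, 4), c(2, 4, 8), c(0.1, 0.1, 0.1))  # xi_mul = 2, chisq 0
fit_gain <- function(fr_before, fr_after, sd_after) {
  ok <- is.finite(sd_after) & sd_after > 0
  if (sum(ok) < 3) stop("need >= 3 orientations with nonzero error bars")
  b <- fr_before[ok]
  a <- fr_after[ok]
  s <- sd_after[ok]
  xi_mul <- sum(a * b / s^2) / sum(b^2 / s^2)
  se_mul <- sqrt(1 / sum(b^2 / s^2))
  chisq_mul <- sum(((a - xi_mul * b) / s)^2)
  xi_add <- sum((a - b) / s^2) / sum(1 / s^2)
  se_add <- sqrt(1 / sum(1 / s^2))
  chisq_add <- sum(((a - b - xi_add) / s)^2)
  structure(list(xi_mul = xi_mul, se_mul = se_mul, chisq_mul = chisq_mul,
                 xi_add = xi_add, se_add = se_add, chisq_add = chisq_add,
                 n = sum(ok)),
            class = "gain_fit")
}

#' @export
print.gain_fit <- function(x, ...) {
  cat(sprintf(
    "<gain_fit> xi_mul = %.3f +/- %.3f (chisq %.2f) | xi_add = %.3f +/- %.3f (chisq %.2f), n = %d\n",
    x$xi_mul, x$se_mul, x$chisq_mul, x$xi_add, x$se_add, x$chisq_add, x$n))
  invisible(x)
}

#' Baseline-subtracted trunk-base voltage integral
#'
#' Trapezoidal integral of the trunk-base membrane potential over a 500-ms
#' stimulation window after subtracting the control baseline (the
#' pre-stimulus potential of the no-shift condition). Used with
#' `na_block = TRUE` simulations so back-propagating action potentials do
#' not contaminate the integral.
#'
#' @param sim A [simulate_neuron()] result (trunk-base trace).
#' @param baseline_mV Control baseline to subtract; default: the mean of
#'   this trace before the first event (suitable when comparing conditions,
#'   pass the no-shift baseline explicitly).
#' @param window_ms Integration window `c(start, end)`, ms (default
#'   `c(0, 500)`).
#' @return AUC in mV ms.
#' @export
trunk_auc <- function(sim, baseline_mV = NULL, window_ms = c(0, 500)) {
  tr <- sim$trunk_base
  if (is.null(baseline_mV)) {
    pre <- tr$v_mV[tr$t_ms < 1]
    baseline_mV <- if (length(pre)) mean(pre) else tr$v_mV[1]
  }
  sel <- tr$t_ms >= window_ms[1] & tr$t_ms <= window_ms[2]
  t <- tr$t_ms[sel]
  v <- tr$v_mV[sel] - baseline_mV
  sum(diff(t) * (v[-length(v)] + v[-1]) / 2)
}

#' Signal attenuation with synaptic input distance
#'
#' Scales the whole neuron by each factor in `scale_factors` (section
#' lengths only; diameters unchanged), measures the trunk AUC at the target
#' orientation for each reversal-shift condition, and fits the power law
#' `AUC(x) = x^a + c` per condition by least squares on the
#' condition-normalized AUC, where `x` is the relative input distance.
#'
#' @param scale_factors Length scale factors (>= 4 values).
#' @param conditions Reversal-shift conditions, mV.
#' @param n_trials Trials per scale and condition (default 3).
#' @param seed Integer seed.
#' @param generations,... Morphology and simulation arguments passed through.
#' @return List with `auc` (data.frame `scale`, `delta_EK`, `trial`,
#'   `auc_mVms`) and `fits` (data.frame `delta_EK`, `exponent`, `offset`,
#'   `converged`).
#' @export
distance_scaling <- function(scale_factors = c(1, 1.25, 1.5, 1.75, 2),
                             conditions = c(0, 18), n_trials = 3, seed = 1,
                             generations = 4, ...) {
  if (length(scale_factors) < 4) stop("need >= 4 scale factors")
  rows <- list()
  for (sc in scale_factors) {
    morph <- build_fractal_neuron(generations = generations, scale = sc)
    for (tr in seq_len(n_trials)) {
      for (ek in conditions) {
        sim <- simulate_neuron(morph, theta = 0, delta_EK = ek,
                               seed = seed + 97 * tr, na_block = TRUE, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          scale = sc, delta_EK = ek, trial = tr, auc_mVms = trunk_auc(sim))
      }
    }
  }
  auc <- do.call(rbind, rows)
  fits <- do.call(rbind, lapply(conditions, function(ek) {
    d <- auc[auc$delta_EK == ek, ]
    m <- stats::aggregate(auc_mVms ~ scale, d, mean)
    y <- m$auc_mVms / m$auc_mVms[m$scale == min(m$scale)]
    x <- m$scale
    obj <- function(p) sum((y - (x^p[1] + p[2]))^2)
    fit <- try(stats::optim(c(-1, 0), obj), silent = TRUE)
    if (inherits(fit, "try-error")) {
      data.frame(delta_EK = ek, exponent = NA, offset = NA, converged = FALSE)
    } else {
      data.frame(delta_EK = ek, exponent = fit$par[1], offset = fit$par[2],
                 converged = fit$convergence == 0)
    }
  }))
  list(auc = auc, fits = fits)
}
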
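#' Effective (tortuosity-corrected) diffusion coefficient
#'
#' `D* = D_free / lambda^2`. With the free K+ coefficient 1.96 um^2/ms and
#' tortuosity 1.6 this gives 0.765625, conventionally printed as 0.76.
#'
#' @param D_free Free-medium diffusion coefficient, um^2/ms (default 1.96).
#' @param tortuosity_lambda Dimensionless tortuosity (default 1.6).
#' @return Effective coefficient, um^2/ms (full precision; see
#'   [truncate2()] for the printed two-decimal convention).
#' @export
effective_diffusion <- function(D_free = 1.96, tortuosity_lambda = 1.6) {
  if (!(D_free > 0) || !(tortuosity_lambda > 0)) stop("inputs must be positive")
  D_free / tortuosity_lambda^2
}

#' Truncate to two decimals
#'
#' Reporting convention for diffusion coefficients: truncation (not rounding)
#' to two decimals, so 0.765625 prints as 0.76.
#'
#' @param x Numeric vector.
#' @return `x` truncated toward zero at the second decimal.
#' @export
truncate2 <- function(x) trunc(x * 100) / 100

#' Characteristic diffusion time over a distance
#'
#' Inverts the Brownian root-mean-square displacement `L = sqrt(2 D t)`:
#' `tau = L^2 / (2 D)`. For a 10 um segment and the printed effective
#' coefficient 0.76 um^2/ms this is about 66 ms, after which the segment's
#' extracellular space is treated as well mixed.
#'
#' @param L Distance, um.
#' @param D_eff Effective diffusion coefficient, um^2/ms.
#' @return Time in ms.
#' @export
characteristic_time <- function(L, D_eff) {
  if (!(L > 0) || !(D_eff > 0)) stop("inputs must be positive")
  L^2 / (2 * D_eff)
}

#' Expected diffusive displacement after a time
#'
#' `sqrt(2 D t)`; about 30 um in 600 ms at the default effective coefficient,
#' which bounds how far released K+ can spread between stimulation events.
#'
#' @param D_eff Effective diffusion coefficient, um^2/ms.
#' @param t Elapsed time, ms (>= 0).
#' @return Displacement in um.
#' @export
expected_displacement <- function(D_eff, t) {
  if (!(D_eff > 0)) stop("`D_eff` must be positive")
  if (any(t < 0)) stop("`t` must be non-negative")
  sqrt(2 * D_eff * t)
}

#' Diffusion and pump parameters
#'
#' @param D_free Free diffusion coefficient, um^2/ms (default 1.96).
#' @param tortuosity_lambda Tortuosity (default 1.6).
#' @param K_dec Membrane pump clearance constant, m/s (default 2.9e-8). It is
#'   converted internally to a first-order volumetric sink
#'   `2 K_dec / (R2 - R1)` acting on the concentration excess.
#' @return Object of class `diffusion_params` with the derived `D_eff`.
#' @export
diffusion_params <- function(D_free = 1.96, tortuosity_lambda = 1.6,
                             K_dec = 2.9e-8) {
  if (K_dec < 0) stop("`K_dec` must be >= 0")
  structure(list(D_free = D_free, tortuosity_lambda = tortuosity_lambda,
                 D_eff = effective_diffusion(D_free, tortuosity_lambda),
                 K_dec = K_dec),
            class = "diffusion_params")
}

# alpha-function efflux waveform, peak 1 at t = t_peak, 0 for t < 0
alpha_waveform <- function(t, t_peak = 20) {
  w <- (t / t_peak) * exp(1 - t / t_peak)
  w[t < 0] <- 0
  w
}

#' Simulate extracellular K+ diffusion along a concatenated dendrite
#'
#' Eleven 10-um dendritic segments are concatenated into a 110-um dendrite;
#' the central segment carries similarly tuned synapses and the flanks carry
#' diversely tuned synapses (an all-diverse reference dendrite is simulated
#' alongside). Each synapse injects K+ into the annular extracellular shell
#' with an alpha-function time course whose amplitude scales with the
#' synapse's orientation-dependent activity; injections start at a per-synapse
#' exponential delay after each stimulation event. The concentration excess
#' obeys 1-D axial diffusion with reflecting (closed) ends and a first-order
#' pump sink, and each segment's reversal shift follows from its
#' segment-averaged concentration via the Nernst relation.
#'
#' @param theta Stimulus orientation, degrees.
#' @param params A [diffusion_params()].
#' @param geom A [k_geometry()] for one segment (the dendrite concatenates
#'   `n_segments` of them).
#' @param baseline An [ion_baseline()].
#' @param n_segments Number of concatenated segments (default 11; the similar
#'   segment sits at the centre).
#' @param n_events,interstimulus_ms Stimulation protocol: number of events
#'   (default 3) and inter-event interval in ms (default 300).
#' @param delay_mean_ms Mean of the exponential per-synapse onset delay after
#'   each event (default 80).
#' @param t_peak_ms Alpha-function time to peak of the per-synapse efflux
#'   (default 20).
#' @param source_scale Total K+ released by one fully active synapse per
#'   event, in mM um^3 of concentration-volume (calibrated so the all-diverse
#'   reference dendrite peaks near 0.5 mM, the middle of the in vivo range,
#'   at the target orientation with the default geometry).
#' @param pump_width_um Effective width of the perimembrane cleft over which
#'   the pump flux constant acts when converted to a volumetric rate
#'   `2 K_dec / width`. The default 0.015 um is a calibrated effective value
#'   (clearance time constant ~0.26 s) chosen so a single stimulation event
#'   peaks 140-170 ms after onset and relaxes to baseline within ~1.5 s; it
#'   sits below the anatomical cleft-width range because it also absorbs
#'   unmodelled uptake pathways (see the methods vignette).
#' @param dx Axial grid spacing, um (default 0.5; must be <= 1).
#' @param dt Time step, ms; default `0.4 * dx^2 / D_eff`, safely inside the
#'   explicit-scheme stability bound `dx^2 / (2 D_eff)`.
#' @param t_total Simulated time, ms (default 1000).
#' @param record_every Record the field every this many steps (default 10).
#' @param sigma_pref,sigma_tuning,n_range Sampling parameters for the synapse
#'   populations (see [sample_segment()]).
#' @param seed Integer seed.
#' @return Object of class `k_field`: list with `t_ms` (recorded times),
#'   `x_um` (grid centres), `field` (time x space matrix of Delta K+ in mM),
#'   `reference_field` (same for the all-diverse dendrite), `segments`
#'   (data.frame: per-recorded-time, per-segment mean Delta K+ and Delta E_K
#'   for both dendrites), `summary` (per-segment peak and time-to-peak), and
#'   the run parameters.
#' @export
simulate_k_field <- function(theta = 0,
                             params = diffusion_params(),
                             geom = k_geometry(),
                             baseline = ion_baseline(),
                             n_segments = 11,
                             n_events = 3,
                             interstimulus_ms = 300,
                             delay_mean_ms = 80,
                             t_peak_ms = 20,
                             source_scale = 25,
                             pump_width_um = 0.015,
                             dx = 0.5,
                             dt = NULL,
                             t_total = 1000,
                             record_every = 10,
                             sigma_pref = 15,
                             sigma_tuning = 11,
                             n_range = 7:13,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (dx > 1) stop("grid spacing `dx` must be <= 1 um")
  D <- params$D_eff
  if (is.null(dt)) dt <- 0.4 * dx^2 / D
  if (dt > dx^2 / (2 * D)) {
    stop(sprintf("explicit scheme unstable: need dt <= dx^2/(2 D) = %.4g ms",
                 dx^2 / (2 * D)))
  }
  seg_len <- geom$L
  L_total <- n_segments * seg_len
  nx <- round(L_total / dx)
  x <- (seq_len(nx) - 0.5) * dx
  centre <- ceiling(n_segments / 2)
  a_ext <- pi * (geom$R2^2 - geom$R1^2)      # annulus cross-section, um^2
  sink_rate <- 2 * (params$K_dec * 1e3) / pump_width_um  # 1/ms

  # synapse populations: centre similar, flanks diverse; reference all diverse
  draw_sources <- function(regimes) {
    out <- list()
    for (s in seq_len(n_segments)) {
      seg <- sample_segment(regimes[s], sigma_pref = sigma_pref,
                            sigma_tuning = sigma_tuning, n_range = n_range,
                            length = seg_len, radius = geom$R1)
      act <- synapse_activity(orientation_distance(theta, seg$preferred),
                              sigma_tuning)
      pos <- (s - 1) * seg_len + stats::runif(length(act), 0, seg_len)
      onset <- rep((seq_len(n_events) - 1) * interstimulus_ms,
                   each = length(act)) +
        stats::rexp(length(act) * n_events, rate = 1 / delay_mean_ms)
      out[[s]] <- data.frame(
        segment = s,
        cell = pmin(nx, pmax(1L, ceiling(rep(pos, n_events) / dx))),
        onset = onset,
        amplitude = rep(act, n_events) * source_scale
      )
    }
    do.call(rbind, out)
  }
  regimes <- rep("diverse", n_segments)
  regimes[centre] <- "similar"
  src_main <- draw_sources(regimes)
  src_ref <- draw_sources(rep("diverse", n_segments))

  run_grid <- function(src) {
    # int_0^inf (t/tp) e^(1 - t/tp) dt = e * tp, so dividing by this makes
    # each source release exactly `amplitude` (mM um^3) per event
    waveform_integral <- exp(1) * t_peak_ms
    nt <- ceiling(t_total / dt)
    rec_idx <- seq(1, nt, by = record_every)
    field <- matrix(0, nrow = length(rec_idx), ncol = nx)
    C <- numeric(nx)
    r <- D * dt / dx^2
    k <- 0L
    cell_amp <- split(seq_len(nrow(src)), src$cell)
    for (i in seq_len(nt)) {
      t_now <- (i - 1) * dt
      # diffusion (reflecting ends)
      lap <- c(C[2] - C[1], diff(C, differences = 2), C[nx - 1] - C[nx])
      C <- C + r * lap
      # sources
      w <- alpha_waveform(t_now - src$onset, t_peak_ms) / waveform_integral
      inj <- src$amplitude * w * dt / (a_ext * dx)
      if (any(inj > 0)) {
        add <- vapply(cell_amp, function(ii) sum(inj[ii]), numeric(1))
        C[as.integer(names(cell_amp))] <- C[as.integer(names(cell_amp))] + add
      }
      # pump sink
      if (sink_rate > 0) C <- C * exp(-sink_rate * dt)
      C[C < 0] <- 0
      if (i %in% rec_idx) {
        k <- k + 1L
        field[k, ] <- C
      }
    }
    list(t_ms = (rec_idx - 1) * dt, field = field)
  }

  main <- run_grid(src_main)
  ref <- run_grid(src_ref)

  seg_index <- rep(seq_len(n_segments), each = nx / n_segments)
  seg_mean <- function(field) {
    t(apply(field, 1, function(row) tapply(row, seg_index, mean)))
  }
  sm <- seg_mean(main$field)
  sr <- seg_mean(ref$field)
  dek <- function(m) apply(m, 2, function(col)
    vapply(col, function(d) nernst_shift(baseline, 0, d), numeric(1)))
  dek_m <- dek(sm)
  dek_r <- dek(sr)

  segments <- do.call(rbind, lapply(seq_len(n_segments), function(s) {
    data.frame(t_ms = main$t_ms, segment = s,
               distance_um = abs(s - centre) * seg_len,
               regime = regimes[s],
               dKo_mM = sm[, s], dEK_mV = dek_m[, s],
               dKo_ref_mM = sr[, s], dEK_ref_mV = dek_r[, s])
  }))
  summary <- do.call(rbind, lapply(seq_len(n_segments), function(s) {
    i <- which.max(dek_m[, s])
    data.frame(segment = s, regime = regimes[s],
               distance_um = abs(s - centre) * seg_len,
               peak_dKo_mM = sm[i, s], peak_dEK_mV = dek_m[i, s],
               t_peak_ms = main$t_ms[i],
               peak_dEK_ref_mV = max(dek_r[, s]))
  }))

  structure(list(
    t_ms = main$t_ms, x_um = x,
    field = main$field, reference_field = ref$field,
    segments = segments, summary = summary,
    theta = theta, params = params, geom = geom,
    n_segments = n_segments, centre = centre,
    dt = dt, dx = dx, source_scale = source_scale,
    sink_rate_per_ms = sink_rate
  ), class = "k_field")
}

#' Total K+ mass on a simulated field
#'
#' Axial integral of the concentration excess times the extracellular
#' cross-section, per recorded time point. With the pump off and closed
#' boundaries this is conserved once all sources have finished injecting.
#'
#' @param kf A `k_field` from [simulate_k_field()].
#' @param reference If `TRUE`, use the all-diverse reference dendrite.
#' @return Numeric vector (mM um^3), one value per recorded time.
#' @export
k_field_mass <- function(kf, reference = FALSE) {
  stopifnot(inherits(kf, "k_field"))
  f <- if (reference) kf$reference_field else kf$field
  a_ext <- pi * (kf$geom$R2^2 - kf$geom$R1^2)
  rowSums(f) * kf$dx * a_ext
}

#' @export
print.k_field <- function(x, ...) {
  cat(sprintf(
    "<k_field> %d segments x %g um, theta = %g deg, %d recorded times\n",
    x$n_segments, x$geom$L, x$theta, length(x$t_ms)))
  c_summ <- x$summary[x$summary$segment == x$centre, ]
  cat(sprintf("  centre (similar) peak dEK = %.2f mV at t = %.0f ms\n",
              c_summ$peak_dEK_mV, c_summ$t_peak_ms))
  invisible(x)
}
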
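#' Default experiment configuration
#'
#' Central configuration for [run_experiment()]: sampling parameters,
#' geometry, baselines and per-stage problem sizes. Two profiles are
#' provided: `"ci"` (reduced scale, minutes) and `"full"` (analysis scale).
#' Configurations round-trip through JSON via [read_experiment_config()] /
#' [write_experiment_config()].
#'
#' @param scale `"ci"` or `"full"`.
#' @return Named list of parameters.
#' @export
default_experiment_config <- function(scale = c("ci", "full")) {
  scale <- match.arg(scale)
  full <- scale == "full"
  list(
    scale = scale,
    sigma_pref = 15,
    sigma_tuning = 11,
    n_range = c(7, 13),
    theta_grid = seq(0, 90, by = if (full) 5 else 15),
    n_segments = if (full) 1e4 else 1e3,
    K_out = 3, K_in = 140,
    R1 = 1, R2 = 2, L = 10,
    delta_k_in_grid = seq(0.2, 2, by = if (full) 0.1 else 0.3),
    R2_grid = seq(1.2, 3, by = if (full) 0.1 else 0.3),
    ek_conditions = c(0, 6, 18),
    pd_trials = if (full) 10 else 5,
    neuron_trials = if (full) 15 else 3,
    neuron_generations = if (full) 4 else 2,
    diffusion_t_total = if (full) 1000 else 400
  )
}

#' @rdname default_experiment_config
#' @param path JSON file path.
#' @export
read_experiment_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_experiment_config(cfg$scale %||% "ci")
  utils::modifyList(base, cfg)
}

#' @rdname default_experiment_config
#' @param config Configuration list.
#' @export
write_experiment_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a named experiment stage and write its outputs
#'
#' Reproducible experiment runner tying the analysis stages together. Each
#' stage regenerates the data behind one line of the analysis and writes CSV
#' tables plus a JSON manifest (stage name, seed, configuration snapshot,
#' output files, summary statistics). Per-stage seeds are derived
#' deterministically from the root seed, so rerunning with the same seed and
#' configuration reproduces identical outputs.
#'
#' Stages: `"activity"` (activity factor and reversal-shift heat maps),
#' `"spikes"` (point-dendrite trials and spike-probability tuning),
#' `"landscape"` (I-V fixed-point tracks), `"neuron"` (somatic tuning, gain
#' fits, trunk AUC), `"diffusion"` (axial K+ field), `"all"`.
#'
#' @param name Stage name (see Details).
#' @param config Configuration list (default
#'   [default_experiment_config()]).
#' @param seed Root integer seed (default 1).
#' @param outdir Output directory (created if missing).
#' @return The manifest, invisibly (list; also written as
#'   `manifest_<name>.json`).
#' @export
run_experiment <- function(name = c("activity", "spikes", "landscape",
                                    "neuron", "diffusion", "all"),
                           config = default_experiment_config(),
                           seed = 1, outdir = tempfile("dendroK_run_")) {
  name <- match.arg(name)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (name == "all") {
    stages <- c("activity", "spikes", "landscape", "neuron", "diffusion")
    return(invisible(lapply(stages, run_experiment, config = config,
                            seed = seed, outdir = outdir)))
  }
  stage_seed <- (seed * 1009 + match(name, c("activity", "spikes",
                                             "landscape", "neuron",
                                             "diffusion")) * 7919) %% 2147483647
  files <- character(0)
  summary <- list()
  emit <- function(df, fname) {
    path <- file.path(outdir, fname)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  if (name == "activity") {
    af <- activity_factor(theta_grid = config$theta_grid,
                          n_segments = config$n_segments, seed = stage_seed,
                          sigma_pref = config$sigma_pref,
                          sigma_tuning = config$sigma_tuning,
                          n_range = config$n_range[1]:config$n_range[2])
    emit(af, "activity_factor.csv")
    hm <- shift_heatmap(config$delta_k_in_grid, config$R2_grid,
                        ion_baseline(config$K_out, config$K_in),
                        factor_at_target = af$factor[1],
                        R1 = config$R1, L = config$L)
    emit(hm, "shift_heatmap.csv")
    summary$factor_at_target <- af$factor[1]
    summary$dEK_similar_range <- range(hm$dEK_similar_mV[hm$in_vivo])
  }
  if (name == "spikes") {
    set.seed(stage_seed)
    trials <- do.call(rbind, lapply(seq_len(config$pd_trials), function(i) {
      tr <- point_dendrite_trial(theta = 0, delta_EK = 12)
      cbind(trial = i, tr$events)
    }))
    emit(trials, "point_dendrite_events.csv")
    af <- activity_factor(theta_grid = config$theta_grid,
                          n_segments = config$n_segments, seed = stage_seed)
    tun <- lapply(config$ek_conditions, function(ek) {
      tr <- spike_probability(reference_spike_plane(), ek,
                              theta_grid = config$theta_grid,
                              n_segments = config$n_segments,
                              factor_fun = normalized_activity_factor(af),
                              seed = stage_seed + ek)
      cbind(delta_EK = ek, as.data.frame(tr), osi = attr(tr, "osi"))
    })
    tun <- do.call(rbind, tun)
    emit(tun, "spike_probability.csv")
    summary$osi <- unique(tun[, c("delta_EK", "osi")])
  }
  if (name == "landscape") {
    for (ek in range(config$ek_conditions)) {
      ls <- iv_landscape(delta_EK = ek)
      emit(cbind(delta_EK = ek, ls$fixed_points),
           sprintf("fixed_points_dEK%02d.csv", ek))
      summary[[sprintf("excitable_ms_dEK%02d", ek)]] <- excitable_epoch(ls)
    }
  }
  if (name == "neuron") {
    morph <- build_fractal_neuron(generations = config$neuron_generations)
    tun <- neuron_tuning(morph, theta_grid = config$theta_grid,
                         conditions = config$ek_conditions,
                         n_trials = config$neuron_trials, seed = stage_seed)
    emit(tun, "neuron_tuning.csv")
    agg <- stats::aggregate(rate_hz ~ theta_deg + delta_EK, tun, mean)
    sdv <- stats::aggregate(rate_hz ~ theta_deg + delta_EK, tun, stats::sd)
    base <- agg$rate_hz[agg$delta_EK == 0]
    for (ek in setdiff(config$ek_conditions, 0)) {
      aft <- agg$rate_hz[agg$delta_EK == ek]
      s <- sdv$rate_hz[sdv$delta_EK == ek]
      fit <- try(fit_gain(base, aft, s), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        summary[[sprintf("gain_dEK%02d", ek)]] <-
          list(xi_mul = fit$xi_mul, xi_add = fit$xi_add,
               chisq_mul = fit$chisq_mul, chisq_add = fit$chisq_add)
      }
    }
  }
  if (name == "diffusion") {
    kf <- simulate_k_field(theta = 0, seed = stage_seed,
                           t_total = config$diffusion_t_total)
    emit(kf$segments, "k_field_segments.csv")
    emit(kf$summary, "k_field_summary.csv")
    centre <- kf$summary[kf$summary$segment == kf$centre, ]
    summary$peak_dEK_mV <- centre$peak_dEK_mV
    summary$t_peak_ms <- centre$t_peak_ms
  }
  manifest <- list(experiment = name, seed = seed, stage_seed = stage_seed,
                   config = config, files = basename(files),
                   summary = summary,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest,
                       file.path(outdir, sprintf("manifest_%s.json", name)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
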
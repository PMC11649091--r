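# reduced-scale morphology so simulations stay fast; the structural tests
# use the full default tree
small_neuron <- function() build_fractal_neuron(generations = 2)

test_that("fractal tree construction follows the halving rule", {
  m <- build_fractal_neuron(generations = 4)
  sec <- m$sections
  expect_equal(m$n_tree, 3 + 9 + 27 + 81)
  expect_equal(m$n_distal, 81)
  # generation k holds 3^k sections of length 20 * 2^(4-k)
  for (k in 1:4) {
    g <- sec[!is.na(sec$generation) & sec$generation == k, ]
    expect_equal(nrow(g), 3^k)
    expect_equal(unique(g$length_um), 20 * 2^(4 - k))
  }
  expect_equal(m$fractal_dimension, log(3) / log(2))
  expect_equal(round(m$fractal_dimension, 2), 1.58)
  # soma and trunk attached at the root
  expect_equal(sec$type[1:2], c("soma", "trunk"))
  expect_equal(sec$length_um[sec$type == "trunk"], 500)
  expect_equal(sec$length_um[sec$type == "soma"], 30)
  expect_equal(sec$diam_um[sec$type == "soma"], 10)
  # every non-terminal tree section has exactly 3 children
  tree_ids <- sec$section[!is.na(sec$generation)]
  kids <- table(factor(sec$parent[sec$parent %in% tree_ids],
                       levels = tree_ids))
  non_terminal <- sec$section[!is.na(sec$generation) & sec$generation < 4]
  expect_true(all(kids[as.character(non_terminal)] == 3))
  # compartments: parent index always smaller (solver requirement)
  comp <- m$compartments
  expect_true(all(is.na(comp$parent) | comp$parent < comp$comp))
  # scaling multiplies lengths, not diameters
  m2 <- build_fractal_neuron(generations = 2, scale = 2)
  m1 <- build_fractal_neuron(generations = 2, scale = 1)
  expect_equal(m2$sections$length_um, 2 * m1$sections$length_um)
  expect_equal(m2$sections$diam_um, m1$sections$diam_um)
  expect_error(build_fractal_neuron(generations = 0), "generation")
})

test_that("passive soma input conductance matches the analytic ladder", {
  # passive membrane: only the leak row retained, so the whole-tree input
  # conductance seen from the soma folds exactly through the axial ladder
  m <- small_neuron()
  ch <- neuron_channels()[neuron_channels()$name == "K_leak", ]
  erev <- ch$erev[1]
  comp <- m$compartments
  gm <- ch$gbar[1] * comp$area_cm2            # mS per compartment
  g_ax <- ifelse(is.na(comp$g_axial_mS), 0, comp$g_axial_mS)
  gin <- gm
  for (i in rev(seq_len(nrow(comp))[-1])) {   # children before parents
    p <- comp$parent[i]
    gin[p] <- gin[p] + 1 / (1 / gin[i] + 1 / g_ax[i])
  }
  g_in <- gin[1]
  # numeric steady state under a constant somatic conductance g_inj toward
  # 0 mV: V* = g_in * erev / (g_in + g_inj) (conductance divider)
  g_inj <- g_in
  kin <- synapse_kinetics()
  kin$tau_decay[1] <- 1e7      # effectively a step conductance
  kin$tau_rise[1] <- 1e-3
  parent0 <- ifelse(is.na(comp$parent), -1L, comp$parent - 1L)
  res <- dendroK:::cpp_cable_sim(
    as.integer(parent0), 2 * comp$area_cm2, g_ax,
    dendroK:::channel_matrix(ch),
    matrix(gm, ncol = 1), numeric(nrow(comp)),
    0.1, 0L, 0L, g_inj,
    dendroK:::syn_matrix(kin),
    0.05, 600, 0L, 100L, 1.0, erev)
  v_star <- res$v_mV[nrow(res$v_mV), 1]
  expect_equal(v_star, g_in * erev / (g_in + g_inj), tolerance = 0.02)
})

test_that("symmetric sibling branches respond identically", {
  m <- small_neuron()
  comp <- m$compartments
  # stimulate two sibling distal sections with identical events
  sibs <- m$sections$section[m$sections$type == "distal"][1:2]
  target <- m$sec_last_comp[sibs]
  kin <- synapse_kinetics()
  ev <- data.frame(
    time = rep(c(10, 10), each = 1),
    comp = target,
    type0 = which(kin$name == "NMDA") - 1L,
    amp = 5e-6
  )
  gd <- dendroK:::neuron_gdens(m, neuron_channels())
  parent0 <- ifelse(is.na(comp$parent), -1L, comp$parent - 1L)
  g_ax <- ifelse(is.na(comp$g_axial_mS), 0, comp$g_axial_mS)
  res <- dendroK:::cpp_cable_sim(
    as.integer(parent0), 2 * comp$area_cm2, g_ax,
    dendroK:::channel_matrix(neuron_channels()), gd,
    numeric(nrow(comp)),
    ev$time, as.integer(ev$comp) - 1L, as.integer(ev$type0), ev$amp,
    dendroK:::syn_matrix(kin), 0.025, 120, as.integer(target) - 1L, 4L,
    1.0, -78)
  expect_equal(res$v_mV[, 1], res$v_mV[, 2], tolerance = 1e-10)
})

test_that("neuron simulation is deterministic and condition-paired", {
  m <- small_neuron()
  a <- simulate_neuron(m, theta = 0, delta_EK = 0, seed = 42, t_total = 300)
  b <- simulate_neuron(m, theta = 0, delta_EK = 0, seed = 42, t_total = 300)
  expect_identical(a$soma, b$soma)
  expect_identical(a$stimulated_sections, b$stimulated_sections)
  # same seed, different condition: identical synapse layout
  c18 <- simulate_neuron(m, theta = 0, delta_EK = 18, seed = 42,
                         t_total = 300)
  expect_identical(a$stimulated_sections, c18$stimulated_sections)
})

test_that("distal drive attenuates into a delayed trunk depolarization", {
  m <- build_fractal_neuron(generations = 3)
  s <- simulate_neuron(m, theta = 0, delta_EK = 0, seed = 7, t_total = 400,
                       na_block = TRUE)
  d_peak <- max(s$distal_example$v_mV)
  t_peak_d <- s$distal_example$t_ms[which.max(s$distal_example$v_mV)]
  tr_peak <- max(s$trunk_base$v_mV)
  t_peak_tr <- s$trunk_base$t_ms[which.max(s$trunk_base$v_mV)]
  v0 <- s$trunk_base$v_mV[1]
  expect_gt(d_peak, tr_peak)          # attenuation
  expect_gt(tr_peak, v0 + 0.5)        # but a visible depolarization arrives
})

test_that("chi-square gain fits recover exact transformations", {
  b <- c(1, 2, 4, 6)
  s <- rep(0.2, 4)
  f_mul <- fit_gain(b, 2 * b, s)
  expect_equal(f_mul$xi_mul, 2)
  expect_equal(f_mul$chisq_mul, 0)
  f_add <- fit_gain(b, b + 3, s)
  expect_equal(f_add$xi_add, 3)
  expect_equal(f_add$chisq_add, 0)
  # for truly multiplicative data the multiplicative chi-square wins
  expect_lt(f_mul$chisq_mul, f_mul$chisq_add)
  # zero-sd orientations are excluded; all-excluded errors
  f <- fit_gain(c(b, 9), c(2 * b, 5), c(s, 0))
  expect_equal(f$n, 4)
  expect_error(fit_gain(b, 2 * b, rep(0, 4)), "nonzero")
})

test_that("trunk AUC is the baseline-subtracted trapezoidal integral", {
  sim <- list(trunk_base = data.frame(t_ms = seq(0, 500, by = 1),
                                      v_mV = rep(-70, 501)))
  expect_equal(trunk_auc(sim, baseline_mV = -70), 0)
  # rectangular 10 mV depolarization for 100 ms -> 1000 mV ms
  sim$trunk_base$v_mV[sim$trunk_base$t_ms > 100 &
                        sim$trunk_base$t_ms <= 200] <- -60
  expect_equal(trunk_auc(sim, baseline_mV = -70), 1000, tolerance = 20)
})

test_that("somatic rate and trunk AUC increase with the local shift", {
  m <- build_fractal_neuron(generations = 3)
  rates <- sapply(c(0, 18), function(ek) {
    mean(sapply(1:3, function(s) {
      simulate_neuron(m, theta = 0, delta_EK = ek, seed = s,
                      t_total = 700)$rate_hz
    }))
  })
  expect_gte(rates[2], rates[1])
  aucs <- sapply(c(0, 18), function(ek) {
    mean(sapply(1:3, function(s) {
      trunk_auc(simulate_neuron(m, theta = 0, delta_EK = ek, seed = s,
                                t_total = 600, na_block = TRUE))
    }))
  })
  expect_gt(aucs[2], aucs[1])
})

test_that("neuron tuning table has the paired-design layout", {
  m <- small_neuron()
  tun <- neuron_tuning(m, theta_grid = c(0, 90), conditions = c(0, 18),
                       n_trials = 2, seed = 5, t_total = 300)
  expect_equal(nrow(tun), 2 * 2 * 2)
  expect_setequal(names(tun), c("theta_deg", "delta_EK", "trial", "rate_hz"))
  expect_true(all(tun$rate_hz >= 0))
})

test_that("distance scaling returns per-condition power-law fits", {
  ds <- distance_scaling(scale_factors = c(0.8, 1, 1.2, 1.4),
                         conditions = c(0, 18), n_trials = 1, seed = 3,
                         generations = 2, t_total = 500)
  expect_equal(nrow(ds$fits), 2)
  expect_true(all(c("exponent", "offset") %in% names(ds$fits)))
  expect_equal(sort(unique(ds$auc$scale)), c(0.8, 1, 1.2, 1.4))
  expect_error(distance_scaling(scale_factors = c(1, 2)), ">= 4")
})
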
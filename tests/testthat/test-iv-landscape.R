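leak_only_iv <- function(gbar = 0.1, erev = -70) {
  data.frame(name = "leak", gbar = gbar, erev = erev, is_k = FALSE,
             p = 0, act_vh = NA, act_k = NA, act_tau = NA,
             q = 0, inact_vh = NA, inact_k = NA, inact_tau = NA)
}

test_that("linear leak curve has a single stable root at the reversal", {
  curve <- iv_curve(leak_only_iv(erev = -70))
  fp <- find_fixed_points(curve)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$V_star_mV, -70, tolerance = 1e-3)
  expect_equal(fp$stability, "stable")
  expect_error(iv_curve(leak_only_iv(), V_grid = numeric(0)), "empty")
})

test_that("intrinsic channels alone give one hyperpolarized stable point", {
  curve <- iv_curve(point_dendrite_channels())
  fp <- find_fixed_points(curve)
  expect_equal(nrow(fp), 1)
  expect_equal(fp$stability, "stable")
  expect_lt(fp$V_star_mV, -70)
  # root residual is tiny relative to the curve's scale
  expect_lt(abs(fp$I_residual), 1e-6 * max(abs(curve$I)))
})

test_that("NMDA conductance ramp produces the 1 -> 3 -> 1 root transition", {
  ch <- point_dendrite_channels()
  n_roots <- vapply(seq(0, 8, by = 0.1), function(g) {
    nrow(find_fixed_points(iv_curve(ch, syn_g = c(NMDA = g))))
  }, numeric(1))
  expect_equal(sort(unique(n_roots)), c(1, 3))
  expect_equal(n_roots[1], 1)                     # rest only
  expect_equal(n_roots[length(n_roots)], 1)       # up-state only
  expect_true(any(n_roots == 3))                  # bistable in between
  # runs of counts: down -> bistable -> up (single contiguous transition)
  r <- rle(n_roots)$values
  expect_equal(r, c(1, 3, 1))
  # in the bistable regime the pattern is stable/unstable/stable by V order
  g_bi <- seq(0, 8, by = 0.1)[which(n_roots == 3)[1]]
  fp <- find_fixed_points(iv_curve(ch, syn_g = c(NMDA = g_bi)))
  expect_equal(fp$stability, c("stable", "unstable", "stable"))
})

test_that("a reversal shift depolarizes rest and reduces outward current", {
  ch <- point_dendrite_channels()
  c0 <- iv_curve(ch, delta_EK = 0)
  c18 <- iv_curve(ch, delta_EK = 18)
  f0 <- find_fixed_points(c0)
  f18 <- find_fixed_points(c18)
  expect_gt(f18$V_star_mV[1], f0$V_star_mV[1])
  # net outward current (negative I) shrinks at every voltage
  expect_true(all(c18$I >= c0$I))
})

test_that("stability classification agrees with forward simulation", {
  ch <- point_dendrite_channels()
  curve <- iv_curve(ch, syn_g = c(NMDA = 2.0))
  fp <- find_fixed_points(curve)
  expect_equal(nrow(fp), 3)  # drive chosen inside the bistable window
  flow_toward <- function(v_start, v_star) {
    state <- list(v = v_start)
    for (i in 1:4000) {
      state <- exp_euler_step(state, ch, syn_g = c(NMDA = 2.0), dt = 0.05)
    }
    abs(state$v - v_star) < 2
  }
  for (i in seq_len(nrow(fp))) {
    v <- fp$V_star_mV[i]
    if (fp$stability[i] == "stable") {
      expect_true(flow_toward(v + 1, v))
      expect_true(flow_toward(v - 1, v))
    } else {
      expect_false(flow_toward(v + 1, v))
      expect_false(flow_toward(v - 1, v))
    }
  }
})

test_that("landscape: shift lowers the barrier and extends excitable epochs", {
  ls0 <- iv_landscape(delta_EK = 0, w = 0.5, t_max = 100, dt_curve = 2)
  ls18 <- iv_landscape(delta_EK = 18, w = 0.5, t_max = 100, dt_curve = 2)
  # no synaptic input at the end of the window: fixed points settle back
  expect_gt(excitable_epoch(ls18), excitable_epoch(ls0))
  # voltage barrier (unstable minus down-stable fixed point) on the static
  # bistable curve at peak NMDA conductance, no AMPA: monotone decreasing in
  # the imposed shift
  ch <- point_dendrite_channels()
  barrier <- vapply(c(0, 6, 12), function(dek) {
    fp <- find_fixed_points(iv_curve(ch, syn_g = c(NMDA = 1.4),
                                     delta_EK = dek))
    fp$V_star_mV[fp$stability == "unstable"][1] - min(fp$V_star_mV)
  }, numeric(1))
  expect_true(all(diff(barrier) < 0))
  # the shift also lowers the NMDA conductance needed to become bistable
  onset_g <- function(dek) {
    gs <- seq(0.8, 2, by = 0.1)
    gs[which(vapply(gs, function(g) {
      nrow(find_fixed_points(iv_curve(ch, syn_g = c(NMDA = g),
                                      delta_EK = dek))) == 3
    }, logical(1)))[1]]
  }
  expect_lt(onset_g(12), onset_g(0))
})

test_that("zero synaptic input leaves the fixed-point set constant", {
  ls <- iv_landscape(delta_EK = 0, w = 0, t_max = 20, dt_curve = 5)
  fps <- split(ls$fixed_points$V_star_mV, ls$fixed_points$t_ms)
  expect_true(all(vapply(fps, length, numeric(1)) == 1))
  vs <- unlist(fps)
  expect_lt(diff(range(vs)), 0.05)
})
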
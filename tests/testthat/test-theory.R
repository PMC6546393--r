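test_that("weight decay and survival have their closed-form anchors", {
  p <- model_params()
  expect_equal(weight_decay(0, p), p$w_max)
  expect_equal(weight_decay(2 * 86400, p), p$w_max * exp(-1))
  tt <- seq(0, 5 * 86400, length.out = 50)
  expect_true(all(diff(weight_decay(tt, p)) < 0) && all(weight_decay(tt, p) > 0))
  expect_equal(survival_probability(0, p), 1)
  # flat-sigmoid limit: constant hazard (d0 + d1) / 2
  pf <- model_params(beta = 1e-9)
  expect_equal(survival_probability(86400, pf),
               exp(-(24 + 0.03) / 2), tolerance = 1e-6)
})

test_that("survival quadrature agrees with a dense trapezoid oracle", {
  p <- model_params()
  # frozen value from a 10^6-point trapezoid evaluation of the survival
  # integral at t = 20 h
  expect_equal(survival_probability(20 * 3600, p), 0.9171581,
               tolerance = 1e-6)
  tg <- seq(0, 20 * 3600, length.out = 200001)
  dg <- deletion_rate(weight_decay(tg, p), p) / 86400
  s_trap <- exp(-sum((dg[-1] + dg[-length(dg)]) / 2) * diff(tg)[1])
  expect_equal(survival_probability(20 * 3600, p), s_trap, tolerance = 1e-7)
})

test_that("small-synapse equilibrium and decay time-course anchors hold", {
  p <- model_params()
  expect_equal(small_synapse_count(3600, 0, p), 0.64, tolerance = 1e-9)
  expect_equal(small_synapse_count(0, p$s_max, p), 0)
  expect_equal(decay_time_course(0, 8, p), 8 * 1 + (1 / 25) * (16 - 8))
})

test_that("latest-reactivation time agrees with a grid-scan oracle", {
  p <- model_params()
  expect_true(is.na(t_max_reactivation(3, p)))
  expect_true(is.na(t_max_reactivation(3.5, p)))
  # grid-scan oracle: cumulative trapezoid of the hazard, last passing time
  tg <- seq(0, 45 * 3600, by = 1)
  dg <- deletion_rate(weight_decay(tg, p), p) / 86400
  sg <- exp(-cumsum(c(0, (dg[-1] + dg[-length(dg)]) / 2)))
  lhs <- exp(-p$delta_decay * tg) * sg
  for (S0 in c(8, 12, 16)) {
    oracle <- tg[max(which(lhs >= p$w_inh / (p$w_max * S0)))]
    expect_lt(abs(t_max_reactivation(S0, p) - oracle), 1)
  }
  expect_true(t_max_reactivation(8, p) < t_max_reactivation(12, p) &&
              t_max_reactivation(12, p) < t_max_reactivation(16, p))
})

test_that("per-cycle change has the analytic limits and fixed point", {
  p <- model_params()
  inf_t <- 60 * 86400
  expect_equal(delta_S_cycle(8, inf_t, 4 * 3600, p), 16 - 8, tolerance = 1e-6)
  g <- p$d0 / (p$d0 + p$b) * exp(-p$b / 86400 * 7200)
  expect_equal(delta_S_cycle(8, 7200, inf_t, p), 16 * (1 - g) - 8,
               tolerance = 1e-4)
  # delta_S vanishes exactly at the stationary point
  for (ts in c(2, 6, 12) * 3600) for (tr in c(0.5, 2) * 3600) {
    Sstar <- stationary_S(tr, ts, p)
    expect_equal(delta_S_cycle(Sstar, tr, ts, p), 0, tolerance = 1e-10)
  }
})

test_that("stationary synapse number is monotone in both phase durations", {
  p <- model_params()
  ts <- c(1, 4, 10, 20, 30) * 3600
  tr <- c(0.1, 0.5, 1, 2, 4) * 3600
  for (t1 in ts) expect_true(all(diff(vapply(tr, function(x)
    stationary_S(x, t1, p), numeric(1))) > 0))
  for (t2 in tr) expect_true(all(diff(vapply(ts, function(x)
    stationary_S(t2, x, p), numeric(1))) < 0))
  expect_equal(stationary_S(60 * 86400, 4 * 3600, p), 16, tolerance = 1e-6)
})

test_that("iterating the per-cycle map converges to S* from both sides", {
  p <- model_params()
  for (S0 in c(2, 15.9)) {
    S <- S0
    for (k in 1:500) S <- S + delta_S_cycle(S, 3600, 4 * 3600, p)
    expect_equal(S, stationary_S(3600, 4 * 3600, p), tolerance = 1e-6)
  }
})

test_that("phase diagram flags unsustainable regions and is a pure function", {
  p <- model_params()
  pd <- phase_diagram(c(1, 10, 25) * 3600, c(0.05, 1, 3) * 3600, S0 = 8,
                      params = p)
  expect_equal(pd, phase_diagram(c(1, 10, 25) * 3600, c(0.05, 1, 3) * 3600,
                                 S0 = 8, params = p))
  expect_true(all(pd$delta_S_total[pd$t_sens == 3600] > 0))
  bad <- pd$S_star <= p$w_inh / p$w_max
  expect_true(all(!pd$sustainable[bad]))
  # short sensory phases grow towards s_max
  row <- pd[pd$t_sens == 3600 & pd$t_rest == 3 * 3600, ]
  expect_gt(row$S_star, 15)
})

test_that("sustainability and growth boundaries both lie near twenty hours", {
  p <- model_params()
  # 3-minute rest phases sustain assemblies for up to ~20 h of sensory input
  expect_equal(max_sustainable_sensory(180, p) / 3600, 20, tolerance = 0.15)
  # assemblies at 8 synapses with 2 h rests shrink beyond ~20 h sensory phases
  b <- growth_boundary_sensory(8, 2 * 3600, p) / 3600
  expect_gte(b, 20)
  expect_lt(b, 30)
})
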
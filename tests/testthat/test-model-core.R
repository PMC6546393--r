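test_that("firing rate is the logistic gain with its closed-form values", {
  expect_equal(firing_rate(0), 0.5)
  expect_equal(firing_rate(log(3)), 0.75)
  u <- seq(-8, 8, by = 0.37)
  expect_equal(firing_rate(u) + firing_rate(-u), rep(1, length(u)))
  expect_error(firing_rate(Inf), "finite")
  expect_error(firing_rate(NA_real_), "finite")
})

test_that("membrane update is one forward-Euler step of the rate equation", {
  p <- tiny_params(2)
  st <- network_state(p)
  # fixed point at the origin
  st0 <- update_membrane(st, p, recurrent = 0)
  expect_equal(st0$u, c(0, 0))
  # one-step arithmetic from u = 1 with zero input
  st$u <- c(1, 1)
  st1 <- update_membrane(st, p, recurrent = 0)
  expect_equal(st1$u, rep(1 - 0.1 / 0.155, 2), tolerance = 1e-12)
  # convergence to a constant total input
  st <- network_state(p); st$i_inh <- 0
  for (k in 1:2000) st <- update_membrane(st, p, recurrent = 3.2)
  expect_equal(st$u, c(3.2, 3.2), tolerance = 1e-9)
  expect_error(update_membrane(st, p, recurrent = c(1, 2, 3)), "length")
})

test_that("global inhibition follows the summed rates", {
  p <- tiny_params(2)
  st <- network_state(p)
  st$v <- c(0, 0); st$i_inh <- -1
  st1 <- update_inhibition(st, p)
  expect_equal(st1$i_inh, -1 + 0.1 / 0.155, tolerance = 1e-12)
  # steady state with sum(v) held at 1: -w_inh = -3.5 * 0.7
  st$v <- c(1, 0); st$i_inh <- 0
  for (k in 1:2000) st <- update_inhibition(st, p)
  expect_equal(st$i_inh, -2.45, tolerance = 1e-9)
  # zero rates from zero inhibition stay at zero
  st$v <- c(0, 0); st$i_inh <- 0
  expect_equal(update_inhibition(st, p)$i_inh, 0)
})

test_that("short-term depression relaxes to 1 and depletes to 1/(1+tau*F*v)", {
  p <- tiny_params(1)
  st <- network_state(p)
  st$v <- 0; st$f <- 0.2
  for (k in 1:5000) st <- update_short_term_depression(st, p)
  expect_equal(st$f, 1, tolerance = 1e-8)
  st$v <- 1
  for (k in 1:5000) st <- update_short_term_depression(st, p)
  expect_equal(st$f, 1 / 6, tolerance = 1e-8)
  st$f <- 1; st$v <- 0
  expect_equal(update_short_term_depression(st, p)$f, 1)
  st$f <- 1.5
  expect_error(update_short_term_depression(st, p), "\\(0, 1\\]")
})

test_that("adaptation current integrates towards -alpha * v", {
  p <- tiny_params(1, adaptation_mode = "spike_frequency_adaptation")
  st <- network_state(p)
  st$v <- 1
  st1 <- update_adaptation(st, p)
  expect_equal(st1$i_ad, -0.66)  # dt/tau_adapt * (-33)
  for (k in 1:10000) st <- update_adaptation(st, p)
  expect_equal(st$i_ad, -33, tolerance = 1e-6)
  st$v <- 0
  for (k in 1:10000) st <- update_adaptation(st, p)
  expect_equal(st$i_ad, 0, tolerance = 1e-6)
})

test_that("rates and utilization stay in their open intervals along noisy trajectories", {
  p <- tiny_params(5, noise = 1.5)
  tab <- tiny_assembly(5, 3, p)
  st <- network_state(p)
  set.seed(7)
  for (k in 1:300) {
    out <- step_network(st, tab, p, noise = rnorm(5, 0, p$noise_sd))
    st <- out$state; tab <- out$table
    expect_true(all(st$v > 0 & st$v < 1))
    expect_true(all(st$f > 0 & st$f <= 1))
  }
})

test_that("without noise, input or synapses the potentials decay to rest", {
  p <- tiny_params(4)
  tab <- synapse_table(4, p$s_max)
  st <- network_state(p)
  st$u <- c(2, -3, 0.5, 0)
  prev <- abs(st$u)
  for (k in 1:100) {
    st <- update_membrane(st, p, recurrent = 0)
    expect_true(all(abs(st$u) <= prev + 1e-12))
    prev <- abs(st$u)
  }
  expect_equal(st$u, rep(0, 4), tolerance = 1e-8)
})

test_that("global inhibition makes the dynamics equivariant under neuron permutation", {
  p <- tiny_params(6, noise = 0)
  tab <- tiny_assembly(6, 4, p)
  st <- network_state(p)
  istim <- c(5, 0, 2, 0, 0, 1)
  ref <- run_ref_steps(st, tab, p, 40, i_stim = istim)
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)  # new index of each neuron
  ptab <- synapse_table(6, p$s_max, post = perm[tab$post], pre = perm[tab$pre],
                        slot = tab$slot, w = tab$w, t_create = tab$t_create)
  pstim <- numeric(6); pstim[perm] <- istim
  out <- run_ref_steps(network_state(p), ptab, p, 40, i_stim = pstim)
  expect_equal(out$state$u[perm], ref$state$u, tolerance = 1e-12)
  expect_equal(out$state$i_inh, ref$state$i_inh, tolerance = 1e-12)
})

test_that("spike-frequency adaptation keeps utilization pinned at 1", {
  p <- tiny_params(4, noise = 1.5,
                   adaptation_mode = "spike_frequency_adaptation")
  tab <- tiny_assembly(4, 4, p)
  st <- network_state(p)
  set.seed(11)
  for (k in 1:200) {
    out <- step_network(st, tab, p, i_stim = c(10, 10, 10, 0),
                        noise = rnorm(4, 0, p$noise_sd))
    st <- out$state; tab <- out$table
  }
  expect_equal(st$f, rep(1, 4))
  expect_lt(min(st$i_ad), 0)
})
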
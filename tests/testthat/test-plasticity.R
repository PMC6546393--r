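test_that("deletion rate interpolates the printed sigmoid and is monotone", {
  p <- model_params()
  expect_equal(deletion_rate(p$w_off, p), (24 + 0.03) / 2)
  expect_equal(deletion_rate(0, p),
               0.03 + 23.97 / (1 + exp(-p$beta * p$w_off)), tolerance = 1e-12)
  expect_equal(deletion_rate(p$w_max, p),
               0.03 + 23.97 / (1 + exp(p$beta * (p$w_max - p$w_off))),
               tolerance = 1e-12)
  w <- seq(0, p$w_max, length.out = 200)
  expect_true(all(diff(deletion_rate(w, p)) < 0))
  expect_error(deletion_rate(-0.1, p), "outside")
  expect_error(deletion_rate(0.8, p), "outside")
})

test_that("the three Hebbian regimes partition the rate plane and bound weights", {
  p <- tiny_params(2)
  tab <- synapse_table(2, p$s_max, post = 1L, pre = 2L, slot = 1L, w = 0.5)
  upd <- function(w, vpre, vpost) {
    tab$w <- w
    hebbian_step(tab, c(vpost, vpre), p)$w  # neuron 1 post, neuron 2 pre
  }
  # soft-bound potentiation: no change at w_max
  expect_equal(upd(p$w_max, 0.9, 0.9), p$w_max)
  # depression example: dw = -delta_ltd * w * dt
  expect_equal(upd(0.7, 0.9, 0.1), 0.7 - 0.01 * 0.7 * 0.1)
  # decay regime
  expect_equal(upd(0.35, 0.1, 0.2), 0.35 * (1 - p$delta_decay * p$dt))
  # ties at exactly v = 0.5 fall into the depression branch
  expect_equal(upd(0.4, 0.5, 0.5), 0.4 * (1 - p$delta_ltd * p$dt))
  expect_equal(upd(0.4, 0.5, 0.9), 0.4 * (1 - p$delta_ltd * p$dt))
  # exactly one regime applies everywhere on a rate grid
  for (vpre in c(0.1, 0.5, 0.9)) for (vpost in c(0.1, 0.5, 0.9)) {
    w1 <- upd(0.3, vpre, vpost)
    regimes <- c(decay = 0.3 * (1 - p$delta_decay * p$dt),
                 ltp = 0.3 + p$delta_ltp * (p$w_max - 0.3) * p$dt,
                 ltd = 0.3 * (1 - p$delta_ltd * p$dt))
    expect_equal(sum(abs(w1 - regimes) < 1e-15), 1)
  }
  expect_error({tab$w <- 0.9; hebbian_step(tab, c(0.1, 0.1), p)}, "outside")
})

test_that("Euler weight decay matches the exponential closed form on frozen segments", {
  p <- tiny_params(2)
  tab <- synapse_table(2, p$s_max, post = c(1L, 2L), pre = c(2L, 1L),
                       slot = c(1L, 1L), w = c(0.35, 0.6))
  for (k in 1:1000) tab <- hebbian_step(tab, c(0.1, 0.1), p)
  expect_equal(tab$w, c(0.35, 0.6) * exp(-p$delta_decay * 100),
               tolerance = 1e-6)
})

test_that("weights never leave [0, w_max] under prolonged updates", {
  p <- tiny_params(3)
  tab <- synapse_table(3, p$s_max, post = c(1L, 2L, 3L), pre = c(2L, 3L, 1L),
                       slot = c(1L, 1L, 1L), w = c(0.01, 0.69, 0.3))
  set.seed(3)
  for (k in 1:500) {
    tab <- hebbian_step(tab, runif(3), p)
    expect_true(all(tab$w >= 0 & tab$w <= p$w_max))
  }
})

test_that("structural step conserves potential locations and respects dt = 0", {
  p <- tiny_params(3, s_max = 4)
  tab <- init_assemblies(assembly_spec(list(1:3), 4), p)  # fully occupied
  expect_identical(structural_step(tab, p, 0), tab)
  set.seed(5)
  tab2 <- structural_step(tab, p, 3600)
  counts <- table(paste(tab2$post, tab2$pre))
  expect_true(all(counts <= p$s_max))
  # fully occupied pairs cannot receive creations
  expect_lte(n_synapses(tab2), n_synapses(tab))
})

test_that("new synapses carry w0 and the creation time of their step", {
  p <- tiny_params(4)
  tab <- synapse_table(4, p$s_max, t = 100)
  set.seed(8)
  tab2 <- structural_step(tab, p, 7200)  # 2 h: expect some creations
  expect_gt(n_synapses(tab2), 0)
  expect_true(all(tab2$w == p$w0))
  expect_true(all(tab2$t_create == 100 + 7200))
  expect_equal(tab2$t, 100 + 7200)
})

test_that("frozen-weight occupancy converges to the detailed-balance value", {
  # 10 simulated days of pure structural dynamics, weights pinned at w0
  p <- tiny_params(4)
  tab <- synapse_table(4, p$s_max)
  set.seed(42)
  dt <- 600
  n_pairs <- 4 * 3
  occ <- numeric(0)
  for (k in seq_len(10 * 86400 / dt)) {
    tab <- structural_step(tab, p, dt)
    tab$w[] <- p$w0
    if (k * dt > 2 * 86400) occ <- c(occ, n_synapses(tab) / n_pairs)
  }
  # equilibrium of the per-location Bernoulli chain at the simulated
  # interval; tends to s_max * b / (b + d(w0)) as dt -> 0
  p_c <- -expm1(-p$b / 86400 * dt)
  p_d <- -expm1(-deletion_rate(p$w0, p) / 86400 * dt)
  target <- p$s_max * p_c / (p_c + p_d)
  # per-snapshot binomial sd, ~1 h autocorrelation time -> >100 effective
  # independent samples over 8 days
  phat <- target / p$s_max
  se <- sqrt(phat * (1 - phat) / (n_pairs * p$s_max)) * p$s_max / sqrt(100)
  expect_lt(abs(mean(occ) - target), 3 * se + 0.02 * target)
  expect_lt(abs(target - equilibrium_occupancy(p)), 0.06)
  expect_equal(equilibrium_occupancy(p), 0.64)
})

test_that("equilibrium occupancy has the correct limits", {
  p <- model_params()
  q <- unclass(p); q$b <- 0
  expect_equal(equilibrium_occupancy(q), 0)
  q <- unclass(p); q$d0 <- 1e-12
  expect_equal(equilibrium_occupancy(q), p$s_max, tolerance = 1e-9)
})

test_that("event-based and Bernoulli structural updates are distributionally equivalent", {
  # 4-neuron frozen-weight network, 500 runs each; compare occupancy counts
  p <- tiny_params(4)
  run_once <- function(method) {
    tab <- synapse_table(4, p$s_max)
    for (k in 1:6) {
      tab <- structural_step(tab, p, 14400, method = method)
      tab$w[] <- p$w0
    }
    n_synapses(tab)
  }
  set.seed(99)
  bern <- replicate(500, run_once("bernoulli"))
  evnt <- replicate(500, run_once("event"))
  expect_gt(stats::wilcox.test(bern, evnt)$p.value, 0.001)
  expect_lt(abs(mean(bern) - mean(evnt)),
            3 * sqrt(var(bern) / 500 + var(evnt) / 500) + 0.5)
})
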
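test_that("class-resolved connectivity matches a hand-built table", {
  p <- model_params(n_cells = 60)
  groups <- list(1:30)
  tab <- init_assemblies(assembly_spec(groups, 8), p)
  cc <- class_connectivity(tab, groups)
  intra <- cc$stats[cc$stats$class == "intra", ]
  expect_equal(intra$mean_S, 8)
  expect_equal(intra$mean_w, p$w_max)
  expect_equal(cc$stats[cc$stats$class == "inter", "mean_S"], 0)
  expect_equal(cc$stats[cc$stats$class == "control", "n_synapses"], 0L)
  # relabeling neurons together with groups leaves the statistics unchanged
  perm <- sample(60)
  tab2 <- synapse_table(60, p$s_max, post = perm[tab$post], pre = perm[tab$pre],
                        slot = tab$slot, w = tab$w)
  cc2 <- class_connectivity(tab2, list(perm[1:30]))
  expect_equal(cc2$stats, cc$stats)
})

test_that("overlap pairs are classed as intra-assembly", {
  p <- model_params(n_cells = 20)
  cc <- class_connectivity(init_assemblies(assembly_spec(list(1:8, 6:13), 2), p),
                           list(1:8, 6:13))
  expect_equal(unname(cc$class_matrix[6, 7]), "intra")
  expect_equal(unname(cc$class_matrix[1, 13]), "inter")
  expect_equal(unname(cc$class_matrix[15, 16]), "control")
})

test_that("turnover fractions count slot identities day over day", {
  mk <- function(slots, t) synapse_table(4, 16, post = rep(2L, length(slots)),
                                         pre = rep(1L, length(slots)),
                                         slot = as.integer(slots),
                                         w = rep(0.5, length(slots)),
                                         t_create = rep(0, length(slots)),
                                         t = t)
  rep1 <- turnover_stats(list(mk(c(1, 2, 3), 0), mk(c(2, 3, 4), 86400)))
  expect_equal(rep1$turnover$created, 1 / 3)
  expect_equal(rep1$turnover$removed, 1 / 3)
  rep2 <- turnover_stats(list(mk(1:3, 0), mk(1:3, 86400)))
  expect_equal(rep2$turnover$created, 0)
  expect_equal(rep2$turnover$removed, 0)
  expect_error(turnover_stats(list(mk(1:3, 0))), "two snapshots")
})

test_that("persistence is non-increasing and identity-based", {
  p <- tiny_params(6)
  sch <- phase_schedule(data.frame(kind = "rest", t_start = 0, t_end = 4 * 3600))
  tab <- tiny_assembly(6, 8, p)
  rec <- run_network(sch, p, table = tab,
                     cfg = run_config(seed = 11, snapshot_every = 3600))
  ts <- turnover_stats(rec$snapshots)
  expect_true(all(diff(ts$persistence$surviving) <= 1e-12))
  expect_equal(ts$persistence$surviving[1], 1)
  # a slot removed and recreated does not count as persistent
  t0 <- synapse_table(4, 16, post = 2L, pre = 1L, slot = 1L, w = 0.5,
                      t_create = 0, t = 0)
  t1 <- synapse_table(4, 16, post = 2L, pre = 1L, slot = 1L, w = 0.5,
                      t_create = 5000, t = 86400)
  expect_equal(turnover_stats(list(t0, t1))$persistence$surviving, c(1, 0))
})

test_that("reactivation detection finds maximal supra-threshold intervals", {
  t <- seq(1, 60)
  expect_equal(nrow(detect_reactivations(t, rep(0, 60))), 0L)
  pulse <- as.numeric(t > 20 & t <= 22)                 # 2 x min_duration
  ev <- detect_reactivations(t, pulse, min_duration = 1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration, 2)
  three <- as.numeric((t > 5 & t <= 7) | (t > 20 & t <= 22) | (t > 40 & t <= 42))
  expect_equal(nrow(detect_reactivations(t, three, 0.5, 1)), 3L)
  # events shorter than min_duration are discarded
  blip <- as.numeric(t == 30)
  expect_equal(nrow(detect_reactivations(t, blip, 0.5, 2)), 0L)
})

test_that("pattern corruption swaps equal numbers in and out", {
  set.seed(1)
  pat <- 1:30
  expect_equal(corrupt_pattern(pat, 0, 1:120), 1:30)
  for (k in 1:20) {
    cp <- corrupt_pattern(pat, 0.2, 1:120)
    expect_equal(length(cp), 30L)
    expect_equal(sum(!cp %in% pat), 6L)                 # 6 on, 6 off
    expect_equal(sum(!pat %in% cp), 6L)
  }
  expect_error(corrupt_pattern(pat, 1.2, 1:120), "fraction")
})

test_that("clamped-cue currents follow the inhibitory fixed point arithmetic", {
  p <- model_params(n_cells = 60)
  tab <- init_assemblies(assembly_spec(list(1:30), 12), p)
  cur <- completion_currents(tab, cue = 1:30, params = p)
  expect_equal(cur[1], 29 * 12 * p$w_max - p$w_inh * 30)  # 243.6 - 73.5
  expect_equal(cur[31], -p$w_inh * 30)
  res <- evaluate_completion(tab, list(1:30), levels = 0, n_trials = 1,
                             params = p)
  expect_equal(res$quality$correct, 1)
  # empty table: every neuron sees only inhibition
  empty <- synapse_table(60, p$s_max)
  res0 <- evaluate_completion(empty, list(1:30), levels = 0, n_trials = 1,
                              params = p)
  expect_equal(res0$quality$false_negative, 30 / 60)
  expect_equal(res0$quality$correct, 1 - 30 / 60)
})

test_that("completion quality declines with cue corruption on average", {
  p <- model_params(n_cells = 60)
  tab <- init_assemblies(assembly_spec(list(1:30), 5), p)  # moderately wired
  set.seed(21)
  res <- evaluate_completion(tab, list(1:30), levels = seq(0, 0.5, 0.1),
                             n_trials = 100, params = p)
  q <- res$quality$correct
  expect_gte(q[1], q[length(q)])
  fit <- stats::lm(q ~ res$quality$level)
  expect_lte(stats::coef(fit)[2], 0)
  expect_true(all(res$quality$correct + res$quality$false_negative +
                    res$quality$false_positive == 1))
})

test_that("retention widens the separation of cue-evoked current classes", {
  # a freshly wired assembly versus the same assembly after a day of
  # sensory/rest cycling with reactivation
  p <- model_params(n_cells = 60)
  groups <- list(1:30)
  tab0 <- init_assemblies(assembly_spec(groups, 8), p)
  set.seed(substream_seed(31, "phases"))
  cyc <- phase_durations(12, mode = "exponential")
  rec <- run_retention_experiment(assembly_spec(groups, 8), p,
           cycles = cyc, total_time = 86400,
           cfg = run_config(seed = substream_seed(31, "engine"),
                            snapshot_every = 86400))
  separation <- function(tab) {
    set.seed(77)
    res <- evaluate_completion(tab, groups, levels = 0.1, n_trials = 20,
                               params = p)
    cur <- res$currents
    mean(cur$current[cur$class == "pattern"]) -
      mean(cur$current[cur$class == "control"])
  }
  expect_gt(separation(rec$table), separation(tab0))
  # and the assembly itself strengthened rather than merely drifting
  cc0 <- class_connectivity(tab0, groups)$stats
  cc1 <- class_connectivity(rec$table, groups)$stats
  expect_gt(cc1$mean_S[cc1$class == "intra"], cc0$mean_S[cc0$class == "intra"])
})
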
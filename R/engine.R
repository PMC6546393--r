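#' Run configuration
#'
#' Controls recording cadence and reproducibility of a simulation run.
#'
#' @param seed Integer seed for all randomness of the run (noise, structural
#'   events). `NULL` leaves the RNG state untouched.
#' @param snapshot_every Seconds between connectivity snapshots (default 1 h;
#'   must be at least `dt`).
#' @param record_every Seconds between activity records (default 1 s; group
#'   mean rates).
#' @param hebbian,structural Toggles for the two plasticity processes
#'   (e.g. `structural = FALSE` freezes the wiring after learning).
#' @param log_events Keep a per-synapse creation/deletion event log.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = NULL, snapshot_every = 3600, record_every = 1,
                       hebbian = TRUE, structural = TRUE, log_events = FALSE) {
  stopifnot(snapshot_every > 0, record_every > 0)
  structure(list(seed = seed, snapshot_every = snapshot_every,
                 record_every = record_every, hebbian = hebbian,
                 structural = structural, log_events = log_events),
            class = "run_config")
}

compile_events <- function(schedule, params) {
  ev <- schedule$events
  if (!nrow(ev))
    return(list(t_start = numeric(0), t_end = numeric(0), amp = numeric(0),
                ids = integer(0), ptr = 0L))
  ord <- order(ev$t_start)
  ev <- ev[ord, , drop = FALSE]
  ids <- lapply(ev$ids, as.integer)
  if (any(unlist(ids) < 1L) || any(unlist(ids) > params$n_cells))
    stop("stimulation event references neuron outside the network")
  list(t_start = ev$t_start, t_end = ev$t_end, amp = ev$amplitude,
       ids = unlist(ids), ptr = c(0L, cumsum(lengths(ids))))
}

#' Run the full network model
#'
#' Advances the complete model (rate dynamics, global inhibition, short-term
#' depression or spike-frequency adaptation, Hebbian weight updates,
#' structural plasticity) through a stimulation schedule with the compiled
#' forward-Euler engine. Per step, in order: recurrent current from the
#' step-start rates; membrane update; inhibition update; depression or
#' adaptation update; rate recomputation; Hebbian update (step-start rates);
#' structural update. The run is deterministic given `cfg$seed` and aborts
#' with a diagnostic if the state becomes non-finite.
#'
#' @param schedule A [phase_schedule()].
#' @param params A [model_params()] object.
#' @param state Initial [network_state()] (default: resting state).
#' @param table Initial [synapse_table()] (default: empty lattice).
#' @param cfg A [run_config()].
#' @param groups Optional list of neuron-id groups; group mean rates are
#'   recorded per group (remaining neurons form the control group).
#' @return An object of class `sim_recorder`: list with `activity` (data
#'   frame of group mean rates over time), `snapshots` (list of
#'   [synapse_table()]s), `snapshot_times`, `events` (structural event log,
#'   if requested), `phases`, `state` and `table` (final), `params`,
#'   `groups`.
#' @export
run_network <- function(schedule, params, state = NULL, table = NULL,
                        cfg = run_config(), groups = list()) {
  stopifnot(inherits(schedule, "phase_schedule"), inherits(cfg, "run_config"))
  validate_params(params)
  if (is.null(state)) state <- network_state(params)
  if (is.null(table)) table <- synapse_table(params$n_cells, params$s_max)
  check_state(state, params)
  if (length(state$u) != params$n_cells || table$n_cells != params$n_cells)
    stop("state/table dimensions do not match params$n_cells")
  if (cfg$snapshot_every < params$dt) stop("snapshot_every must be >= dt")
  total <- schedule_duration(schedule)
  gidx <- integer(params$n_cells)
  for (g in seq_along(groups)) gidx[groups[[g]]] <- g
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ev <- compile_events(schedule, params)
  res <- engine_run(unclass(params),
                    state$u, state$i_inh, state$f, state$i_ad, state$t,
                    table$post, table$pre, table$slot, table$w,
                    table$t_create,
                    ev$t_start + state$t, ev$t_end + state$t, ev$amp,
                    ev$ids, as.integer(ev$ptr), gidx,
                    total, cfg$snapshot_every, cfg$record_every,
                    cfg$hebbian, cfg$structural, cfg$log_events)
  fs <- res$state
  out_state <- structure(list(u = fs$u, v = fs$v, i_inh = fs$i_inh, f = fs$f,
                              i_ad = fs$i_ad, t = fs$t),
                         class = "network_state")
  sy <- res$synapses
  out_table <- synapse_table(params$n_cells, params$s_max, post = sy$post,
                             pre = sy$pre, slot = sy$slot, w = sy$w,
                             t_create = sy$t_create, t = fs$t)
  sn <- res$snapshots
  nsnap <- length(sn$t)
  snaps <- vector("list", nsnap)
  for (k in seq_len(nsnap)) {
    i0 <- sn$ptr[k] + 1L; i1 <- sn$ptr[k + 1L]
    sel <- if (i1 >= i0) i0:i1 else integer(0)
    snaps[[k]] <- synapse_table(params$n_cells, params$s_max,
                                post = sn$post[sel], pre = sn$pre[sel],
                                slot = sn$slot[sel], w = sn$w[sel],
                                t_create = sn$t_create[sel], t = sn$t[k])
  }
  act <- data.frame(t = res$rec_t)
  rates <- res$rec_rate
  colnames(rates) <- c("control", if (length(groups))
    paste0("group", seq_along(groups)))
  act <- cbind(act, as.data.frame(rates))
  phases <- schedule$phases
  if (nrow(phases)) {
    phases$t_start <- phases$t_start + state$t
    phases$t_end <- phases$t_end + state$t
  }
  evl <- NULL
  if (cfg$log_events)
    evl <- data.frame(t = res$events$t, kind = res$events$kind,
                      post = res$events$post, pre = res$events$pre,
                      slot = res$events$slot)
  structure(list(activity = act, snapshots = snaps, snapshot_times = sn$t,
                 events = evl, phases = phases, state = out_state,
                 table = out_table, params = params, groups = groups),
            class = "sim_recorder")
}

#' @export
print.sim_recorder <- function(x, ...) {
  cat(sprintf("<sim_recorder> %d activity records, %d snapshots, final t = %g s\n",
              nrow(x$activity), length(x$snapshots), x$state$t))
  print(x$table)
  invisible(x)
}

#' Retention experiment driver
#'
#' Convenience wrapper for the memory-retention protocol: assemblies are
#' pre-wired via [init_assemblies()] (skipping the learning phase), then the
#' network alternates between sensory phases (random patterns over the
#' non-assembly neurons) and rest phases. Per-cycle phase durations are
#' either supplied explicitly or drawn from the truncated-normal protocol.
#'
#' @param spec An [assembly_spec()].
#' @param params A [model_params()] object.
#' @param cycles Data frame with columns `sens`, `rest` in seconds (e.g. from
#'   [phase_durations()]); if `NULL`, durations are drawn to cover
#'   `total_time`.
#' @param total_time Total simulated time in seconds (schedule truncated
#'   here).
#' @param mean_sens,mean_rest Phase-duration means used when drawing.
#' @param mode Distribution of drawn durations (see [phase_durations()]).
#' @param cfg A [run_config()].
#' @return A `sim_recorder` (see [run_network()]); with zero cycles, the
#'   recorder holds only the initialization snapshot.
#' @export
run_retention_experiment <- function(spec, params, cycles = NULL,
                                     total_time = NULL,
                                     mean_sens = 4 * 3600,
                                     mean_rest = 2 * 3600,
                                     mode = "truncated_normal",
                                     cfg = run_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(cycles)) {
    if (is.null(total_time))
      stop("either cycles or total_time must be given")
    n_guess <- ceiling(total_time / (mean_sens + mean_rest)) + 10L
    cycles <- phase_durations(n_guess, mode = mode, mean_sens = mean_sens,
                              mean_rest = mean_rest)
  }
  table <- init_assemblies(spec, params)
  eligible <- setdiff(seq_len(params$n_cells), unlist(spec$groups))
  schedule <- retention_schedule(cycles, eligible, total_time = total_time)
  cfg$seed <- NULL  # already applied; schedule consumed its share
  run_network(schedule, params, table = table, cfg = cfg,
              groups = spec$groups)
}
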
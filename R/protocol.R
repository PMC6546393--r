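#' Stimulation events and phase schedules
#'
#' A schedule is an ordered, contiguous list of phases (warmup, learning,
#' sensory, rest), each carrying its rectangular stimulation events. Events
#' are stored as a data frame with columns `t_start`, `t_end` (seconds,
#' absolute), `amplitude` (current units) and a list-column `ids` of
#' stimulated neuron indices. Rest phases carry no events.
#'
#' @param phases Data frame with columns `kind`, `t_start`, `t_end`.
#' @param events Event data frame as described above.
#' @return An object of class `phase_schedule`.
#' @export
phase_schedule <- function(phases, events = empty_events()) {
  stopifnot(all(c("kind", "t_start", "t_end") %in% names(phases)))
  if (nrow(phases)) {
    stopifnot(all(phases$t_end > phases$t_start))
    if (nrow(phases) > 1L &&
        any(abs(phases$t_start[-1L] - phases$t_end[-nrow(phases)]) > 1e-9))
      stop("phases must be contiguous in time")
    rest <- phases[phases$kind == "rest", , drop = FALSE]
    if (nrow(rest) && nrow(events)) {
      in_rest <- vapply(seq_len(nrow(events)), function(i)
        any(events$t_start[i] < rest$t_end - 1e-9 &
            events$t_end[i] > rest$t_start + 1e-9), logical(1))
      if (any(in_rest)) stop("rest phases must not contain stimulation events")
    }
  }
  if (nrow(events) && any(events$t_end <= events$t_start))
    stop("events must have t_end > t_start")
  structure(list(phases = phases, events = events), class = "phase_schedule")
}

empty_events <- function() {
  data.frame(t_start = numeric(0), t_end = numeric(0), amplitude = numeric(0),
             ids = I(list()))
}

make_events <- function(t_start, t_end, amplitude, ids) {
  data.frame(t_start = t_start, t_end = t_end, amplitude = amplitude,
             ids = I(ids))
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat(sprintf("<phase_schedule> %d phase(s), %.1f s total, %d stimulation event(s)\n",
              nrow(x$phases), schedule_duration(x), nrow(x$events)))
  if (nrow(x$phases)) {
    tab <- table(x$phases$kind)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname phase_schedule
#' @param schedule A `phase_schedule`.
#' @export
schedule_duration <- function(schedule) {
  if (!nrow(schedule$phases)) return(0)
  max(schedule$phases$t_end) - min(schedule$phases$t_start)
}

#' Concatenate schedules in time
#'
#' Appends `later` after `earlier`, shifting `later`'s times so that it
#' starts where `earlier` ends.
#'
#' @param earlier,later `phase_schedule` objects.
#' @return A combined `phase_schedule`.
#' @export
concat_schedules <- function(earlier, later) {
  off <- if (nrow(earlier$phases)) max(earlier$phases$t_end) else 0
  ph <- later$phases
  ph$t_start <- ph$t_start + off; ph$t_end <- ph$t_end + off
  ev <- later$events
  if (nrow(ev)) { ev$t_start <- ev$t_start + off; ev$t_end <- ev$t_end + off }
  phase_schedule(rbind(earlier$phases, ph), rbind(earlier$events, ev))
}

#' Learning-phase schedule
#'
#' Builds the round-robin learning protocol: group 1 is stimulated with
#' amplitude `amplitude` for `stim_len` seconds, followed by `gap_len`
#' seconds without stimulation, then group 2, and so on, cycling through the
#' groups for the whole phase duration (default cycle: 18 s on / 36 s off at
#' amplitude 200). Events are truncated at the phase end.
#'
#' @param groups List of disjoint integer vectors of neuron ids.
#' @param duration Phase duration in seconds (default 9 h).
#' @param params A [model_params()] object (id range check).
#' @param amplitude Stimulation current (default 200).
#' @param stim_len,gap_len Stimulus and gap lengths in seconds.
#' @return A `phase_schedule` with a single `learning` phase.
#' @export
learning_schedule <- function(groups, duration = 9 * 3600, params,
                              amplitude = 200, stim_len = 18, gap_len = 36) {
  ids <- unlist(groups)
  if (anyDuplicated(ids)) stop("learning groups must be disjoint")
  if (any(ids < 1L | ids > params$n_cells)) stop("neuron id out of range")
  if (duration <= 0)
    return(phase_schedule(data.frame(kind = character(0), t_start = numeric(0),
                                     t_end = numeric(0))))
  cyc <- stim_len + gap_len
  starts <- seq(0, duration, by = cyc)
  starts <- starts[starts < duration - 1e-9]
  if (length(starts)) {
    g <- ((seq_along(starts) - 1L) %% length(groups)) + 1L
    ends <- pmin(starts + stim_len, duration)
    ok <- ends > starts
    ev <- make_events(starts[ok], ends[ok], amplitude,
                      lapply(g[ok], function(i) as.integer(groups[[i]])))
  } else ev <- empty_events()
  phase_schedule(data.frame(kind = "learning", t_start = 0, t_end = duration),
                 ev)
}

#' Random sensory stimulation events
#'
#' Back-to-back 1 s events, each stimulating `n_stim` neurons drawn uniformly
#' without replacement from the eligible set, at amplitude 50. During
#' retention, neurons belonging to learned or pre-wired groups are excluded
#' from the eligible set so that random input cannot accidentally reactivate
#' a stored assembly. The final event is truncated at the phase end.
#'
#' @param eligible Integer vector of selectable neuron ids (length >=
#'   `n_stim`).
#' @param duration Phase duration in seconds.
#' @param n_stim Neurons per pattern (default 15).
#' @param amplitude Stimulation current (default 50).
#' @param pattern_len Pattern duration in seconds (default 1).
#' @param t0 Absolute start time of the phase.
#' @return An event data frame (see [phase_schedule()]).
#' @export
sensory_events <- function(eligible, duration, n_stim = 15L, amplitude = 50,
                           pattern_len = 1, t0 = 0) {
  eligible <- as.integer(eligible)
  if (length(eligible) < n_stim)
    stop("need at least ", n_stim, " eligible neurons for sensory stimulation")
  if (duration <= 0) return(empty_events())
  starts <- seq(0, duration, by = pattern_len)
  starts <- starts[starts < duration - 1e-9]
  ids <- lapply(seq_along(starts), function(i)
    sort(sample(eligible, n_stim)))
  make_events(t0 + starts, t0 + pmin(starts + pattern_len, duration),
              amplitude, ids)
}

#' A single sensory phase
#'
#' @inheritParams sensory_events
#' @return A `phase_schedule` with one `sensory` phase.
#' @export
sensory_schedule <- function(eligible, duration, n_stim = 15L,
                             amplitude = 50) {
  phase_schedule(data.frame(kind = "sensory", t_start = 0, t_end = duration),
                 sensory_events(eligible, duration, n_stim, amplitude))
}

#' Warm-up phase
#'
#' A plain sensory phase (default 6 h) run before any learning, during which
#' structural plasticity relaxes to its creation/removal equilibrium of
#' `s_max b / (b + d0)` synapses per pair. Before learning no groups exist,
#' so all neurons are eligible for stimulation.
#'
#' @param params A [model_params()] object.
#' @param duration Seconds (default 21600, i.e. 6 h).
#' @param eligible Eligible neurons (default: all).
#' @return A `phase_schedule` with one `warmup` phase.
#' @export
warmup_schedule <- function(params, duration = 6 * 3600,
                            eligible = seq_len(params$n_cells)) {
  sch <- sensory_schedule(eligible, duration)
  sch$phases$kind <- "warmup"
  sch
}

#' Sample alternating sensory/rest phase durations
#'
#' Draws `n_cycles` pairs of (sensory, rest) durations. In `"exponential"`
#' mode the durations are i.i.d. exponential with the stated means (the
#' default retention protocol). In `"truncated_normal"` mode they are normal
#' with sd = 0.25 * mean, truncated at zero by resampling (used for the
#' pre-wired assembly experiments).
#'
#' @param n_cycles Number of sensory+rest cycles.
#' @param mode `"exponential"` or `"truncated_normal"`.
#' @param mean_sens Mean sensory-phase duration, seconds (default 4 h).
#' @param mean_rest Mean rest-phase duration, seconds (default 2 h).
#' @return Data frame with columns `sens` and `rest` (seconds).
#' @export
phase_durations <- function(n_cycles, mode = c("exponential",
                                               "truncated_normal"),
                            mean_sens = 4 * 3600, mean_rest = 2 * 3600) {
  mode <- match.arg(mode)
  stopifnot(n_cycles >= 0, mean_sens > 0, mean_rest > 0)
  draw <- function(n, m) {
    if (mode == "exponential") return(stats::rexp(n, 1 / m))
    x <- stats::rnorm(n, m, 0.25 * m)
    while (any(bad <- x <= 0)) x[bad] <- stats::rnorm(sum(bad), m, 0.25 * m)
    x
  }
  data.frame(sens = draw(n_cycles, mean_sens), rest = draw(n_cycles, mean_rest))
}

#' Alternating sensory/rest retention schedule
#'
#' Builds the retention protocol: sensory and rest phases alternate (sensory
#' first) with the given durations; sensory phases receive random patterns
#' over the eligible neurons. If `total_time` is given the schedule is
#' truncated there.
#'
#' @param cycles Data frame with columns `sens`, `rest` (seconds), e.g. from
#'   [phase_durations()].
#' @param eligible Neurons eligible for sensory stimulation (non-assembly).
#' @param total_time Optional hard cut in seconds.
#' @return A `phase_schedule`.
#' @export
retention_schedule <- function(cycles, eligible, total_time = NULL) {
  phases <- list(); events <- list(); t <- 0
  add <- function(kind, len) {
    if (!is.null(total_time)) len <- min(len, total_time - t)
    if (len <= 1e-9) return(FALSE)
    phases[[length(phases) + 1L]] <<- data.frame(kind = kind, t_start = t,
                                                 t_end = t + len)
    if (kind == "sensory")
      events[[length(events) + 1L]] <<- sensory_events(eligible, len, t0 = t)
    t <<- t + len
    TRUE
  }
  for (i in seq_len(nrow(cycles))) {
    if (!add("sensory", cycles$sens[i])) break
    if (!add("rest", cycles$rest[i])) break
  }
  if (!length(phases))
    return(phase_schedule(data.frame(kind = character(0),
                                     t_start = numeric(0),
                                     t_end = numeric(0))))
  phase_schedule(do.call(rbind, c(phases, list(make.row.names = FALSE))),
                 do.call(rbind, c(events, list(make.row.names = FALSE),
                                  list(empty_events()))))
}

#' Assembly specification and pre-wired initialization
#'
#' `assembly_spec` describes groups of neurons to be wired as assemblies:
#' every ordered intra-group pair receives `s_init` functional synapses at
#' weight `w_init` (default `w_max`). Groups may overlap; pairs inside an
#' overlap are wired once (no duplication beyond `s_max`).
#'
#' @param groups List of integer vectors of neuron ids.
#' @param s_init Synapses per intra-group connection (<= `s_max`).
#' @param w_init Initial weight (default: maximal weight).
#' @return `assembly_spec`: an object of class `assembly_spec`;
#'   `init_assemblies`: a [synapse_table()].
#' @export
assembly_spec <- function(groups, s_init, w_init = NULL) {
  stopifnot(length(groups) >= 1L, all(lengths(groups) >= 1L), s_init >= 0)
  structure(list(groups = lapply(groups, as.integer),
                 s_init = as.integer(s_init), w_init = w_init),
            class = "assembly_spec")
}

#' @rdname assembly_spec
#' @param spec An `assembly_spec`.
#' @param params A [model_params()] object.
#' @export
init_assemblies <- function(spec, params) {
  stopifnot(inherits(spec, "assembly_spec"))
  if (spec$s_init > params$s_max) stop("s_init exceeds s_max")
  w_init <- if (is.null(spec$w_init)) params$w_max else spec$w_init
  ids <- unlist(spec$groups)
  if (any(ids < 1L | ids > params$n_cells)) stop("neuron id out of range")
  pairs <- unique(do.call(rbind, lapply(spec$groups, function(g) {
    if (length(g) < 2L) return(NULL)
    e <- expand.grid(post = g, pre = g)
    e[e$post != e$pre, ]
  })))
  if (is.null(pairs) || spec$s_init == 0L)
    return(synapse_table(params$n_cells, params$s_max))
  k <- spec$s_init
  synapse_table(params$n_cells, params$s_max,
                post = rep(pairs$post, each = k),
                pre = rep(pairs$pre, each = k),
                slot = rep(seq_len(k), nrow(pairs)),
                w = rep(w_init, nrow(pairs) * k),
                t_create = rep(0, nrow(pairs) * k))
}

#' Export a schedule's events as a flat table
#'
#' @param schedule A [phase_schedule()].
#' @return Data frame with one row per (event, neuron) with columns
#'   `t_start`, `t_end`, `amplitude`, `neuron`.
#' @export
schedule_event_table <- function(schedule) {
  ev <- schedule$events
  if (!nrow(ev))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      amplitude = numeric(0), neuron = integer(0)))
  n <- lengths(ev$ids)
  data.frame(t_start = rep(ev$t_start, n), t_end = rep(ev$t_end, n),
             amplitude = rep(ev$amplitude, n), neuron = unlist(ev$ids))
}
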
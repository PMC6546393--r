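pair_class_matrix <- function(n, groups) {
  # class per ordered pair: "intra" (both in one group, incl. overlaps),
  # "inter" (different groups, or group vs control), "control" (neither)
  member <- matrix(FALSE, n, length(groups))
  for (g in seq_along(groups)) member[groups[[g]], g] <- TRUE
  any_g <- rowSums(member) > 0
  cls <- matrix("control", n, n)
  both_g <- outer(any_g, any_g, `&`)
  either_g <- outer(any_g, any_g, `|`)
  cls[either_g | both_g] <- "inter"
  for (g in seq_along(groups)) {
    m <- member[, g]
    cls[outer(m, m, `&`)] <- "intra"
  }
  diag(cls) <- NA_character_
  cls
}

#' Class-resolved connectivity statistics
#'
#' Splits all ordered neuron pairs into three classes - intra-assembly
#' (both neurons in the same group; overlap pairs count as intra),
#' inter (pairs spanning different groups or a group and the control
#' population) and control-control - and reports, per class, the mean and
#' standard deviation of the weight per synapse and of the number of
#' synapses per connection. Dense pair matrices are attached for plotting.
#'
#' @param table A [synapse_table()].
#' @param groups List of neuron-id vectors defining the assemblies.
#' @return An object of class `class_connectivity`: data frame `stats` with
#'   one row per non-empty class (`class`, `mean_w`, `sd_w`, `mean_S`,
#'   `sd_S`, `n_pairs`, `n_synapses`) plus attributes `S` and `W` (pair
#'   matrices) and `class_matrix`. Classes with no pairs are absent.
#' @export
class_connectivity <- function(table, groups = list()) {
  n <- table$n_cells
  cls <- pair_class_matrix(n, groups)
  ps <- pair_summaries(table)
  syn_cls <- cls[cbind(table$post, table$pre)]
  out <- lapply(c("intra", "inter", "control"), function(cl) {
    sel <- !is.na(cls) & cls == cl
    if (!sum(sel)) return(NULL)
    wsel <- table$w[syn_cls == cl]
    data.frame(class = cl,
               mean_w = if (length(wsel)) mean(wsel) else NA_real_,
               sd_w = if (length(wsel) > 1) stats::sd(wsel) else NA_real_,
               mean_S = mean(ps$S[sel]), sd_S = stats::sd(ps$S[sel]),
               n_pairs = sum(sel), n_synapses = length(wsel))
  })
  stats <- do.call(rbind, out)
  structure(list(stats = stats, S = ps$S, W = ps$W, class_matrix = cls,
                 t = table$t),
            class = "class_connectivity")
}

#' @export
print.class_connectivity <- function(x, ...) {
  cat(sprintf("<class_connectivity> at t = %g s\n", x$t))
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Synaptic turnover and persistence from snapshots
#'
#' Compares the occupied potential locations between consecutive snapshots
#' (typically daily). The created fraction on day d is
#' `|occupied_d \ occupied_{d-1}| / |occupied_{d-1}|`; the removed fraction
#' is defined analogously. The persistence curve is slot-identity based: the
#' fraction of locations occupied at the first snapshot that are still
#' occupied by the *same* synapse (equal creation time - a removed and
#' recreated location does not count) at each later snapshot; it is
#' non-increasing.
#'
#' @param snapshots List of [synapse_table()]s at increasing times (at least
#'   two).
#' @param pairs Optional restriction: a 2-column matrix / data frame of
#'   (post, pre) pairs, or a list of neuron groups whose intra-group pairs
#'   are used (e.g. the assembly).
#' @return An object of class `turnover_report`: data frames `turnover`
#'   (`t`, `created`, `removed`) and `persistence` (`t`, `surviving`).
#' @export
turnover_stats <- function(snapshots, pairs = NULL) {
  if (length(snapshots) < 2L) stop("need at least two snapshots")
  keep_fun <- make_pair_filter(pairs, snapshots[[1L]]$n_cells)
  keys <- lapply(snapshots, function(tab) {
    sel <- keep_fun(tab$post, tab$pre)
    list(slot = paste(tab$post[sel], tab$pre[sel], tab$slot[sel]),
         created = tab$t_create[sel], t = tab$t)
  })
  to <- lapply(seq_along(keys)[-1L], function(k) {
    prev <- keys[[k - 1L]]$slot; cur <- keys[[k]]$slot
    data.frame(t = keys[[k]]$t,
               created = length(setdiff(cur, prev)) / length(prev),
               removed = length(setdiff(prev, cur)) / length(prev))
  })
  ref <- keys[[1L]]
  ref_id <- paste(ref$slot, ref$created)
  pers <- vapply(keys, function(kk)
    length(intersect(paste(kk$slot, kk$created), ref_id)) / length(ref_id),
    numeric(1))
  structure(list(turnover = do.call(rbind, to),
                 persistence = data.frame(t = vapply(keys, `[[`, numeric(1), "t"),
                                          surviving = pers)),
            class = "turnover_report")
}

make_pair_filter <- function(pairs, n) {
  if (is.null(pairs)) return(function(post, pre) rep(TRUE, length(post)))
  if (is.list(pairs) && !is.data.frame(pairs)) {
    cls <- pair_class_matrix(n, pairs)
    return(function(post, pre) {
      v <- cls[cbind(post, pre)]
      !is.na(v) & v == "intra"
    })
  }
  pairs <- as.matrix(pairs)
  key <- paste(pairs[, 1L], pairs[, 2L])
  function(post, pre) paste(post, pre) %in% key
}

#' @export
print.turnover_report <- function(x, ...) {
  cat("<turnover_report>\n")
  print(x$turnover, row.names = FALSE)
  invisible(x)
}

#' Detect reactivation events in a rate trace
#'
#' A reactivation (Up) event is a maximal interval during which the trace
#' exceeds `threshold` for at least `min_duration` seconds. The trace must be
#' regularly sampled; each sample represents one cadence interval, so an
#' isolated supra-threshold sample at 1 s cadence counts as a 1 s event. The
#' defaults (threshold 0.5 - the plasticity/gain midpoint - and 1 s) match
#' the assembly-level Up states terminated by depression/adaptation.
#'
#' @param t Sample times, seconds (regular cadence).
#' @param rate Trace values (e.g. assembly mean rate), same length as `t`.
#' @param threshold Rate threshold (default 0.5).
#' @param min_duration Minimal event duration in seconds (default 1).
#' @return Data frame with one row per event: `t_start`, `t_end`,
#'   `duration`, `peak`.
#' @export
detect_reactivations <- function(t, rate, threshold = 0.5, min_duration = 1) {
  stopifnot(length(t) == length(rate))
  if (!length(t))
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), peak = numeric(0)))
  cadence <- if (length(t) > 1L) stats::median(diff(t)) else min_duration
  above <- rate > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths * cadence >= min_duration - 1e-9)
  data.frame(t_start = t[starts[sel]] - cadence,
             t_end = t[ends[sel]],
             duration = r$lengths[sel] * cadence,
             peak = vapply(sel, function(i)
               max(rate[starts[i]:ends[i]]), numeric(1)))
}

#' Reactivation flags per rest phase
#'
#' @param recorder A `sim_recorder` from [run_network()].
#' @param threshold,min_duration See [detect_reactivations()].
#' @return Data frame with one row per (rest phase, group): columns
#'   `phase_start`, `phase_end`, `group`, `n_events`, `reactivated`.
#' @export
rest_phase_reactivations <- function(recorder, threshold = 0.5,
                                     min_duration = 1) {
  rest <- recorder$phases[recorder$phases$kind == "rest", , drop = FALSE]
  gcols <- grep("^group", names(recorder$activity), value = TRUE)
  out <- list()
  for (i in seq_len(nrow(rest))) {
    sel <- recorder$activity$t > rest$t_start[i] &
      recorder$activity$t <= rest$t_end[i]
    for (g in seq_along(gcols)) {
      evs <- detect_reactivations(recorder$activity$t[sel],
                                  recorder$activity[[gcols[g]]][sel],
                                  threshold, min_duration)
      out[[length(out) + 1L]] <- data.frame(
        phase_start = rest$t_start[i], phase_end = rest$t_end[i],
        group = g, n_events = nrow(evs), reactivated = nrow(evs) > 0L)
    }
  }
  if (!length(out))
    return(data.frame(phase_start = numeric(0), phase_end = numeric(0),
                      group = integer(0), n_events = integer(0),
                      reactivated = logical(0)))
  do.call(rbind, out)
}

#' Corrupt an activity pattern
#'
#' Switches off `round(fraction * |pattern|)` active neurons (ties to even)
#' and switches on the same number of inactive neurons from the universe, so
#' the corrupted pattern has the same size as the original.
#'
#' @param pattern Integer vector of active neuron ids.
#' @param fraction Corruption level in `[0, 1]`.
#' @param universe All neuron ids (active + inactive candidates).
#' @return Integer vector: the corrupted active set.
#' @export
corrupt_pattern <- function(pattern, fraction, universe) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  k <- round(fraction * length(pattern))
  inactive <- setdiff(universe, pattern)
  if (k > length(inactive))
    stop("not enough inactive neurons to switch on")
  if (k == 0L) return(sort(as.integer(pattern)))
  off <- sample(pattern, k)
  on <- sample(inactive, k)
  sort(as.integer(c(setdiff(pattern, off), on)))
}

#' Clamped-cue input currents
#'
#' Deterministic current evaluation used by the pattern-completion measure:
#' cue neurons are clamped to rate 1, all others to 0, utilization is at rest
#' (`f = 1`), and the global inhibition takes its fixed-point value under the
#' clamped rates, `I_inh* = -w_inh * |cue|`. Neuron i then receives
#' `sum_j sum_k w_ijk v_j + I_inh*`. Noise is excluded.
#'
#' @param table A [synapse_table()].
#' @param cue Integer vector of clamped-active neuron ids.
#' @param params A [model_params()] object.
#' @return Numeric vector of per-neuron input currents.
#' @export
completion_currents <- function(table, cue, params) {
  n <- table$n_cells
  input <- numeric(n)
  sel <- table$pre %in% cue
  if (any(sel)) {
    agg <- rowsum(table$w[sel], table$post[sel])
    input[as.integer(rownames(agg))] <- agg[, 1L]
  }
  input - params$w_inh * length(cue)
}

#' Associative pattern-completion quality
#'
#' Evaluates recall of stored patterns from corrupted cues using the
#' binary-unit abstraction: for each corrupted cue the clamped input currents
#' (see [completion_currents()]) are computed and each neuron is classified
#' active iff its input exceeds zero. The classification is compared against
#' the uncorrupted pattern over all neurons and averaged over `n_trials`
#' corrupted versions per pattern and over patterns.
#'
#' @param table A [synapse_table()] (after learning or initialization).
#' @param patterns List of integer vectors (the stored patterns).
#' @param levels Corruption levels in `[0, 1]` (default 0 to 0.5 in 5% steps).
#' @param n_trials Corrupted versions per pattern and level (default 100).
#' @param params A [model_params()] object.
#' @return An object of class `completion_result`: data frame `quality` with
#'   columns `level`, `correct`, `false_negative`, `false_positive`
#'   (fractions of all neurons; `correct + false_negative + false_positive
#'   = 1`), and `currents`, a data frame of per-class current samples
#'   (`level`, `class` in pattern/other/control, `current`) for histograms.
#' @export
evaluate_completion <- function(table, patterns, levels = seq(0, 0.5, 0.05),
                                n_trials = 100L, params) {
  n <- table$n_cells
  universe <- seq_len(n)
  in_any <- universe %in% unlist(patterns)
  rows <- list(); cur <- list()
  for (lv in levels) {
    corr <- fn <- fp <- 0
    for (p in seq_along(patterns)) {
      pat <- patterns[[p]]
      should <- universe %in% pat
      other <- in_any & !should
      for (trial in seq_len(n_trials)) {
        cue <- corrupt_pattern(pat, lv, universe)
        inp <- completion_currents(table, cue, params)
        act <- inp > 0
        fn <- fn + sum(should & !act)
        fp <- fp + sum(!should & act)
        corr <- corr + sum(act == should)
        if (trial == 1L)
          cur[[length(cur) + 1L]] <- data.frame(
            level = lv,
            class = ifelse(should, "pattern",
                           ifelse(other, "other", "control")),
            current = inp)
      }
    }
    denom <- length(patterns) * n_trials * n
    rows[[length(rows) + 1L]] <- data.frame(
      level = lv, correct = corr / denom, false_negative = fn / denom,
      false_positive = fp / denom)
  }
  structure(list(quality = do.call(rbind, rows),
                 currents = do.call(rbind, cur)),
            class = "completion_result")
}

#' @export
print.completion_result <- function(x, ...) {
  cat("<completion_result>\n")
  print(x$quality, row.names = FALSE, digits = 4)
  invisible(x)
}
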
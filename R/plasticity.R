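#' Weight-dependent synapse deletion rate
#'
#' Deletion rate of a functional synapse as a function of its weight,
#' `d(w) = d1 + (d0 - d1) / (1 + exp(-beta * (w_off - w)))`, a decreasing
#' sigmoid interpolating between `d0` (small synapses, unstable) and `d1`
#' (large synapses, stable). Rates are per day, as parameterised.
#'
#' @param w Synaptic weight(s) in `[0, w_max]`.
#' @param params A [model_params()] object.
#' @return Deletion rate(s), per day.
#' @examples
#' p <- model_params()
#' deletion_rate(p$w_off, p)  # sigmoid midpoint: (d0 + d1) / 2
#' @export
deletion_rate <- function(w, params) {
  if (any(w < 0) || any(w > params$w_max + 1e-12))
    stop("weight outside [0, w_max]")
  params$d1 + (params$d0 - params$d1) /
    (1 + exp(-params$beta * (params$w_off - w)))
}

#' Threshold-based Hebbian weight update
#'
#' One Euler step of the three-regime Hebbian rule applied to every occupied
#' synapse, using the supplied rates:
#' * both `v_pre < 0.5` and `v_post < 0.5`: slow decay
#'   `dw = -delta_decay * w`;
#' * both `> 0.5`: soft-bounded potentiation `dw = +delta_ltp * (w_max - w)`;
#' * otherwise (including ties at exactly 0.5): depression
#'   `dw = -delta_ltd * w`.
#'
#' @param table A [synapse_table()].
#' @param v Per-neuron firing rates at the start of the step.
#' @param params A `model_params`.
#' @param dt Step size in seconds (default `params$dt`).
#' @return The table with updated weights; weights remain in `[0, w_max]`.
#' @export
hebbian_step <- function(table, v, params, dt = params$dt) {
  if (length(v) != table$n_cells) stop("rate vector length mismatch")
  if (any(table$w < 0) || any(table$w > params$w_max + 1e-12))
    stop("weight outside [0, w_max] on input")
  if (!n_synapses(table)) return(table)
  vpre <- v[table$pre]; vpost <- v[table$post]
  w <- table$w
  dw <- -params$delta_ltd * w                     # mixed regime (and ties)
  low <- vpre < 0.5 & vpost < 0.5
  high <- vpre > 0.5 & vpost > 0.5
  dw[low] <- -params$delta_decay * w[low]
  dw[high] <- params$delta_ltp * (params$w_max - w[high])
  table$w <- pmin(pmax(w + dt * dw, 0), params$w_max)
  table
}

#' One interval of structural plasticity
#'
#' Stochastic creation and removal of synapses over an interval `dt`. Each
#' vacant potential location becomes functional with probability
#' `1 - exp(-b dt)` (new weight `w0`); each occupied location is removed
#' with probability `1 - exp(-d(w) dt)`, with the weight held constant over
#' the interval. Removals are applied before creations, so a synapse created
#' in this call is first eligible for deletion in the next one.
#'
#' Two algorithms with identical per-interval statistics are provided:
#' `"bernoulli"` draws one Bernoulli variable per potential location (the
#' reference semantics); `"event"` simulates exponential waiting times,
#' thinning deletion events against the upper bound `d0`. The event-based
#' form is the faster choice when `dt` spans many creation/deletion
#' half-lives and is the algorithm used inside the compiled engine.
#'
#' @param table A [synapse_table()].
#' @param params A `model_params`.
#' @param dt Interval length in seconds.
#' @param method `"bernoulli"` or `"event"`.
#' @return The updated table, with `t` advanced by `dt`.
#' @export
structural_step <- function(table, params, dt,
                            method = c("bernoulli", "event")) {
  method <- match.arg(method)
  stopifnot(dt >= 0)
  if (dt == 0) return(table)
  b_sec <- params$b / 86400
  d_sec <- deletion_rate(table$w, params) / 86400
  keep <- if (method == "bernoulli") {
    stats::runif(n_synapses(table)) >= -expm1(-d_sec * dt)
  } else {
    vapply(d_sec, function(dz) {
      tt <- 0
      repeat {
        tt <- tt + stats::rexp(1, rate = params$d0 / 86400)
        if (tt > dt) return(TRUE)
        if (stats::runif(1) < dz / (params$d0 / 86400)) return(FALSE)
      }
    }, logical(1))
  }
  vac <- vacant_slots(table)
  nv <- nrow(vac)
  create <- if (method == "bernoulli") {
    stats::runif(nv) < -expm1(-b_sec * dt)
  } else {
    stats::rexp(nv, rate = b_sec) <= dt
  }
  t_new <- table$t + dt
  synapse_table(table$n_cells, table$s_max,
                post = c(table$post[keep], vac$post[create]),
                pre = c(table$pre[keep], vac$pre[create]),
                slot = c(table$slot[keep], vac$slot[create]),
                w = c(table$w[keep], rep(params$w0, sum(create))),
                t_create = c(table$t_create[keep], rep(t_new, sum(create))),
                t = t_new)
}

# All vacant (post, pre, slot) locations of the lattice. O(n^2 s_max); meant
# for small networks (tests, fixtures) - the engine tracks vacancies
# incrementally.
vacant_slots <- function(table) {
  n <- table$n_cells
  grid <- expand.grid(post = seq_len(n), pre = seq_len(n),
                      slot = seq_len(table$s_max))
  grid <- grid[grid$post != grid$pre, ]
  if (n_synapses(table)) {
    key <- function(p, q, k) (p - 1) * n * table$s_max + (q - 1) * table$s_max + k
    occ <- key(table$post, table$pre, table$slot)
    grid <- grid[!key(grid$post, grid$pre, grid$slot) %in% occ, ]
  }
  grid
}

#' Equilibrium occupancy of weak synapses
#'
#' Expected number of functional synapses per directed pair when weights stay
#' near zero, so that the deletion rate is `d0`: detailed balance of creation
#' and removal gives `s_max * b / (b + d0)` (0.64 under defaults).
#'
#' @param params A [model_params()] object.
#' @return Expected synapses per directed neuron pair.
#' @export
equilibrium_occupancy <- function(params) {
  params$s_max * params$b / (params$b + params$d0)
}
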
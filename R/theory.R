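#' Mean-field theory of intra-assembly connectivity
#'
#' Analytic companion of the simulation for homogeneously connected
#' assemblies. During a sensory phase (no reactivation) all intra-assembly
#' weights start from `w_max` - reactivation during the preceding rest phase
#' is assumed to have re-potentiated them - and decay exponentially,
#' `w(t) = w_max exp(-delta_decay t)`. Feeding this decay through the
#' weight-dependent deletion rate yields the synapse survival probability
#' `s(t)`; adding the equilibrium population of small newly created synapses
#' gives the full decay time-course `S(t) = S0 s(t) + S_small(t)`. Balancing
#' removal during a sensory phase of length `t_sens` against creation and
#' stabilization during a rest phase of length `t_rest` yields the expected
#' per-cycle change `delta_S` and the stationary synapse number `S*`.
#' All functions are deterministic pure functions of their arguments; times
#' are in seconds, rates as in [model_params()].
#'
#' @name theory
NULL

#' Weight decay during a sensory phase
#'
#' `w(t) = w_max * exp(-delta_decay * t)`.
#'
#' @param t Time since the weights were last fully potentiated, seconds.
#' @param params A [model_params()] object.
#' @return Weight(s) at `t`.
#' @export
weight_decay <- function(t, params) {
  params$w_max * exp(-params$delta_decay * t)
}

#' Synapse survival probability without reactivation
#'
#' `s(t) = exp(-integral_0^t d(w(tau)) dtau)` with `w(tau)` from
#' [weight_decay()] and `d(.)` from [deletion_rate()]. The integral is
#' evaluated by adaptive quadrature (relative tolerance 1e-9); the
#' integrand is smooth and monotone.
#'
#' @param t Time(s) in seconds, `>= 0`.
#' @param params A [model_params()] object.
#' @return Survival probability/probabilities in (0, 1].
#' @export
survival_probability <- function(t, params) {
  stopifnot(all(t >= 0))
  integrand <- function(tau)
    deletion_rate(weight_decay(tau, params), params) / 86400
  vapply(t, function(tt) {
    if (tt == 0) return(1)
    q <- tryCatch(
      stats::integrate(integrand, 0, tt, rel.tol = 1e-9,
                       subdivisions = 500L),
      error = function(e) stop("survival quadrature failed at t = ", tt,
                               " s: ", conditionMessage(e)))
    exp(-q$value)
  }, numeric(1))
}

#' Equilibrium count of small synapses during decay
#'
#' Newly created synapses keep near-zero weights during a sensory phase and
#' are removed at rate ~ `d0`; their number equilibrates at
#' `S_small(t) = b/(d0+b) * (s_max - S0 s(t))`. The full decay time-course
#' is `S(t) = S0 s(t) + S_small(t)`.
#'
#' @param t Time(s) in seconds.
#' @param S0 Synapses per connection at the start of the sensory phase.
#' @param params A [model_params()] object.
#' @return Expected number of small synapses per connection.
#' @export
small_synapse_count <- function(t, S0, params) {
  params$b / (params$d0 + params$b) *
    (params$s_max - S0 * survival_probability(t, params))
}

#' @rdname small_synapse_count
#' @return `decay_time_course`: expected total synapses per connection,
#'   `S0 s(t) + S_small(t)`.
#' @export
decay_time_course <- function(t, S0, params) {
  S0 * survival_probability(t, params) + small_synapse_count(t, S0, params)
}

#' Latest possible reactivation time
#'
#' An assembly can still reactivate while its recurrent excitation per pair,
#' `S0 s(t) w(t)`, exceeds the inhibitory coupling `w_inh`. The largest such
#' time solves `exp(-delta_decay t) s(t) = w_inh / (w_max S0)` and is found
#' by bracketed root search (1 ms resolution). If `S0 w_max <= w_inh` the
#' condition already fails at t = 0 and `NA` is returned.
#'
#' @param S0 Initial synapses per connection (> 0).
#' @param params A [model_params()] object.
#' @return Time in seconds, or `NA` if reactivation is impossible.
#' @export
t_max_reactivation <- function(S0, params) {
  stopifnot(S0 > 0)
  target <- params$w_inh / (params$w_max * S0)
  g <- function(t) exp(-params$delta_decay * t) *
    survival_probability(t, params) - target
  if (g(0) <= 0) return(NA_real_)
  upper <- 3600
  while (g(upper) > 0) {
    upper <- upper * 2
    if (upper > 86400 * 1000) stop("no bracket for t_max")
  }
  stats::uniroot(g, c(0, upper), tol = 1e-3)$root
}

gamma_rest <- function(t_rest, params) {
  params$d0 / (params$d0 + params$b) * exp(-params$b / 86400 * t_rest)
}

#' Expected connectivity change over one sensory+rest cycle
#'
#' `delta_S = s_max (1 - gamma) - S0 (1 - gamma s(t_sens))` with
#' `gamma(t_rest) = d0/(d0+b) exp(-b t_rest)`: synapses surviving the
#' sensory phase plus those created during it and during the rest phase are
#' re-potentiated and stabilized by reactivation, while the remainder is
#' lost.
#'
#' @param S0 Synapses per connection at the cycle start.
#' @param t_rest,t_sens Phase durations, seconds.
#' @param params A [model_params()] object.
#' @return Expected change in synapses per connection over the cycle.
#' @export
delta_S_cycle <- function(S0, t_rest, t_sens, params) {
  g <- gamma_rest(t_rest, params)
  s <- survival_probability(t_sens, params)
  params$s_max * (1 - g) - S0 * (1 - g * s)
}

#' Stationary number of synapses per connection
#'
#' The fixed point of the per-cycle map, `delta_S(S*, t_rest, t_sens) = 0`:
#' `S* = s_max (1 - gamma) / (1 - gamma s(t_sens))`. Increasing in `t_rest`,
#' decreasing in `t_sens`.
#'
#' @inheritParams delta_S_cycle
#' @return The stationary synapse number `S*`.
#' @export
stationary_S <- function(t_rest, t_sens, params) {
  g <- gamma_rest(t_rest, params)
  s <- survival_probability(t_sens, params)
  params$s_max * (1 - g) / (1 - g * s)
}

#' Sustainability of the stationary assembly
#'
#' At the stationary synapse number, reactivation at the end of a sensory
#' phase requires the end-of-phase excitation to beat inhibition:
#' `S* s(t_sens) w(t_sens) >= w_inh`.
#'
#' @inheritParams delta_S_cycle
#' @return Logical.
#' @export
is_sustainable <- function(t_rest, t_sens, params) {
  s <- survival_probability(t_sens, params)
  stationary_S(t_rest, t_sens, params) * s * weight_decay(t_sens, params) >=
    params$w_inh
}

#' Longest sustainable sensory phase
#'
#' The largest sensory-phase duration for which the stationary assembly
#' still meets the end-of-phase reactivation condition (see
#' [is_sustainable()]) at a given rest-phase duration. Found by bracketed
#' root search on `S*(t) s(t) w(t) - w_inh`.
#'
#' @param t_rest Rest-phase duration, seconds.
#' @param params A [model_params()] object.
#' @param t_upper Upper search bound in seconds (default 10 days).
#' @return Duration in seconds (`Inf` if sustainable up to `t_upper`).
#' @export
max_sustainable_sensory <- function(t_rest, params, t_upper = 10 * 86400) {
  h <- function(t) {
    s <- survival_probability(t, params)
    stationary_S(t_rest, t, params) * s * weight_decay(t, params) -
      params$w_inh
  }
  if (h(1) <= 0) return(0)
  if (h(t_upper) > 0) return(Inf)
  stats::uniroot(h, c(1, t_upper), tol = 1e-3)$root
}

#' Boundary sensory duration for assembly growth
#'
#' The sensory-phase duration at which the expected per-cycle change
#' [delta_S_cycle()] crosses from positive (assembly gains synapses) to
#' negative (assembly shrinks), for a given starting connectivity and
#' rest-phase duration.
#'
#' @inheritParams delta_S_cycle
#' @param t_upper Upper search bound in seconds (default 10 days).
#' @return Duration in seconds (`Inf` if the change stays positive, 0 if it
#'   is already negative for arbitrarily short sensory phases).
#' @export
growth_boundary_sensory <- function(S0, t_rest, params,
                                    t_upper = 10 * 86400) {
  g <- function(t) delta_S_cycle(S0, t_rest, t, params)
  if (g(1) <= 0) return(0)
  if (g(t_upper) > 0) return(Inf)
  stats::uniroot(g, c(1, t_upper), tol = 1e-3)$root
}

#' Theory phase diagram over phase durations
#'
#' Evaluates, on a grid of sensory x rest durations: the per-cycle change
#' [delta_S_cycle()] at `S0`; the cumulative change after iterating the
#' per-cycle map for the number of cycles fitting into `total_time`
#' (`floor(total_time / (t_sens + t_rest))`); the stationary number
#' [stationary_S()]; and the sustainability flag [is_sustainable()].
#'
#' @param t_sens,t_rest Numeric vectors of phase durations, seconds.
#' @param S0 Initial synapses per connection.
#' @param params A [model_params()] object.
#' @param total_time Simulated-time horizon for the cumulative change,
#'   seconds (default 5 days).
#' @return A tidy data frame with columns `t_sens`, `t_rest`, `delta_S`,
#'   `delta_S_total`, `S_star`, `sustainable`.
#' @export
phase_diagram <- function(t_sens, t_rest, S0, params,
                          total_time = 5 * 86400) {
  s_tab <- survival_probability(t_sens, params)
  grid <- expand.grid(i = seq_along(t_sens), j = seq_along(t_rest))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    i <- grid$i[r]; j <- grid$j[r]
    ts <- t_sens[i]; tr <- t_rest[j]
    g <- gamma_rest(tr, params)
    s <- s_tab[i]
    dS1 <- params$s_max * (1 - g) - S0 * (1 - g * s)
    ncyc <- floor(total_time / (ts + tr))
    S <- S0
    for (k in seq_len(ncyc)) S <- S + params$s_max * (1 - g) - S * (1 - g * s)
    Sstar <- params$s_max * (1 - g) / (1 - g * s)
    data.frame(t_sens = ts, t_rest = tr, delta_S = dS1,
               delta_S_total = S - S0, S_star = Sstar,
               sustainable = Sstar * s * weight_decay(ts, params) >=
                 params$w_inh)
  })
  do.call(rbind, rows)
}
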
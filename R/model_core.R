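#' Logistic firing-rate function
#'
#' Maps membrane potential to firing rate, `v = 1 / (1 + exp(-u))`. Rates are
#' confined to the open interval (0, 1); the plasticity thresholds sit at the
#' midpoint v = 0.5 (u = 0).
#'
#' @param u Membrane potential(s); any numeric vector, must be finite.
#' @return Firing rate(s) in (0, 1), same shape as `u`.
#' @examples
#' firing_rate(0)        # 0.5
#' firing_rate(log(3))   # 0.75
#' @export
firing_rate <- function(u) {
  if (!is.numeric(u) || any(!is.finite(u)))
    stop("membrane potential must be finite numeric")
  1 / (1 + exp(-u))
}

#' Network state at one instant
#'
#' Bundles the dynamical variables of the rate network: membrane potentials
#' `u`, firing rates `v`, the single global inhibitory current `i_inh`
#' (delivered identically to every neuron), the per-presynaptic-neuron
#' short-term-depression utilization `f`, the spike-frequency adaptation
#' current `i_ad`, and the simulation time `t` in seconds.
#'
#' The initial condition is `u = 0` (hence `v = 0.5`), `i_inh = 0`, `f = 1`,
#' `i_ad = 0` at `t = 0`.
#'
#' @param params A [model_params()] object (supplies `n_cells`).
#' @param n_cells Optional override of the number of neurons.
#' @return An object of class `network_state`.
#' @export
network_state <- function(params, n_cells = params$n_cells) {
  n <- as.integer(n_cells)
  s <- list(u = numeric(n), v = rep(0.5, n), i_inh = 0,
            f = rep(1, n), i_ad = numeric(n), t = 0)
  class(s) <- "network_state"
  s
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state> %d neurons at t = %g s; mean rate %.3f, I_inh = %.3f\n",
              length(x$u), x$t, mean(x$v), x$i_inh))
  invisible(x)
}

check_state <- function(state, params) {
  n <- length(state$u)
  if (length(state$v) != n || length(state$f) != n || length(state$i_ad) != n)
    stop("inconsistent state vector lengths")
  invisible(n)
}

#' Forward-Euler update of the membrane potentials
#'
#' One Euler step of `tau du/dt = -u + I_rec + I_inh + I_stim + I_noise`
#' (plus the adaptation current `i_ad` when the model runs with
#' spike-frequency adaptation). The recurrent current must already include
#' the presynaptic utilization factors and all synaptic weights,
#' `I_rec_i = sum_j sum_k f_j w_ijk v_j`. Rates are not recomputed here; they
#' are refreshed once per step, after all current updates (see
#' [step_network()]).
#'
#' @param state A `network_state`.
#' @param params A `model_params`.
#' @param recurrent Per-neuron recurrent current.
#' @param i_stim Per-neuron external stimulation current (scalar or vector).
#' @param noise Per-neuron noise current, drawn externally (scalar or vector).
#' @return The updated `network_state`.
#' @export
update_membrane <- function(state, params, recurrent, i_stim = 0, noise = 0) {
  n <- check_state(state, params)
  for (arg in list(recurrent, i_stim, noise))
    if (!length(arg) %in% c(1L, n)) stop("input length does not match state")
  total <- recurrent + state$i_inh + i_stim + noise
  if (params$adaptation_mode == "spike_frequency_adaptation")
    total <- total + state$i_ad
  state$u <- state$u + (params$dt / params$tau) * (-state$u + total)
  state
}

#' Forward-Euler update of the global inhibitory current
#'
#' One Euler step of `tau dI_inh/dt = -I_inh - w_inh * sum_i v_i`, using the
#' current rates in `state`. The resulting current is global: one value,
#' delivered to every neuron including those contributing to the sum.
#'
#' @inheritParams update_membrane
#' @return The updated `network_state`.
#' @export
update_inhibition <- function(state, params) {
  check_state(state, params)
  state$i_inh <- state$i_inh + (params$dt / params$tau) *
    (-state$i_inh - params$w_inh * sum(state$v))
  state
}

#' Forward-Euler update of short-term depression
#'
#' One Euler step of `df_i/dt = (1 - f_i)/tau_relax - F f_i v_i`. There is one
#' utilization factor per presynaptic neuron; it multiplies all of that
#' neuron's outgoing synapses in the recurrent current. Under
#' spike-frequency adaptation `f` is pinned at 1 and this update is a no-op.
#'
#' @inheritParams update_membrane
#' @return The updated `network_state`.
#' @export
update_short_term_depression <- function(state, params) {
  check_state(state, params)
  if (params$adaptation_mode != "short_term_depression") return(state)
  if (any(state$f <= 0) || any(state$f > 1))
    stop("utilization f must lie in (0, 1]")
  state$f <- state$f + params$dt *
    ((1 - state$f) / params$tau_relax - params$f_dep * state$f * state$v)
  state
}

#' Forward-Euler update of the spike-frequency adaptation current
#'
#' One Euler step of `tau_adapt dI_ad/dt = -I_ad - alpha v_i`. The adaptation
#' current (always non-positive in steady operation) enters the membrane
#' equation as an additional current, shifting the effective gain.
#'
#' @inheritParams update_membrane
#' @return The updated `network_state`.
#' @export
update_adaptation <- function(state, params) {
  check_state(state, params)
  if (params$adaptation_mode != "spike_frequency_adaptation") return(state)
  state$i_ad <- state$i_ad + (params$dt / params$tau_adapt) *
    (-state$i_ad - params$alpha_adapt * state$v)
  state
}

#' One full network step (pure-R reference)
#'
#' Reference semantics of a single integration step, identical to the
#' compiled engine: (1) recurrent current from the step-start rates, weights
#' and utilizations; (2) membrane update (using the step-start inhibitory
#' current); (3) rate recomputation; (4) inhibition update from the new
#' rates; (5) depression or adaptation update from the new rates; (6)
#' Hebbian weight update using the step-start rates. The sequential sweep
#' (rates refreshed before the inhibition update) keeps the fast
#' membrane-inhibition loop of the discretized system stable at the default
#' 100 ms step; a fully parallel update is unstable for quiet networks of a
#' few hundred neurons and produces spurious synchronized bursting.
#' Structural plasticity is applied separately (see [structural_step()]).
#' This function is intended for small networks and for validating the
#' compiled engine; long simulations should use [run_network()].
#'
#' @param state A `network_state`.
#' @param table A [synapse_table()].
#' @param params A `model_params`.
#' @param i_stim Per-neuron stimulation current (scalar or vector).
#' @param noise Per-neuron noise current (scalar or vector). Pass draws from
#'   `rnorm(n, 0, params$noise_sd)` for the stochastic model.
#' @param hebbian Apply the Hebbian weight update (default TRUE).
#' @return A list with elements `state` and `table`.
#' @export
step_network <- function(state, table, params, i_stim = 0, noise = 0,
                         hebbian = TRUE) {
  n <- check_state(state, params)
  v_old <- state$v
  contrib <- state$f[table$pre] * table$w * v_old[table$pre]
  recurrent <- numeric(n)
  if (length(contrib))
    recurrent <- vapply(seq_len(n), function(i)
      sum(contrib[table$post == i]), numeric(1))
  state <- update_membrane(state, params, recurrent, i_stim, noise)
  state$v <- firing_rate(state$u)
  state <- update_inhibition(state, params)
  state <- update_short_term_depression(state, params)
  state <- update_adaptation(state, params)
  state$t <- state$t + params$dt
  if (hebbian) table <- hebbian_step(table, v_old, params)
  table$t <- state$t
  list(state = state, table = table)
}
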
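# Small parameter sets and networks shared across tests.

tiny_params <- function(n = 6L, noise = 0, ...) {
  model_params(n_cells = n, noise_sd = noise, ...)
}

# a 3-neuron assembly inside an n-neuron net, s synapses per connection
tiny_assembly <- function(n = 6L, s = 4L, params = tiny_params(n)) {
  init_assemblies(assembly_spec(list(1:3), s), params)
}

# run k pure-R reference steps
run_ref_steps <- function(state, table, params, k, i_stim = 0, noise = 0) {
  for (i in seq_len(k)) {
    out <- step_network(state, table, params, i_stim = i_stim, noise = noise)
    state <- out$state; table <- out$table
  }
  list(state = state, table = table)
}
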
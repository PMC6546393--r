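# reassembly

Simulation and theory of how Hebbian cell assemblies — the putative synaptic
substrate of long-term memories — survive continuous synaptic turnover.
Cortical synapses are created and removed daily, exchanging a large part of
the synapse population within weeks, yet memories persist and can even
improve offline. `reassembly` implements a rate-based recurrent network in
which stored assemblies spontaneously reactivate during rest periods; these
self-generated reactivations re-potentiate the assemblies' synapses, bias
structural plasticity towards keeping them, and thereby maintain and
strengthen the memory while the rest of the network decays. The package is
aimed at computational neuroscientists studying memory consolidation,
synaptic turnover and Up–Down population dynamics.

## Model

Membrane potentials follow

τ u̇ᵢ = −uᵢ + Σⱼ Σₖ fⱼ wᵢⱼ,ₖ vⱼ + I_inh + I_stim,i + I_noise,i,
  vᵢ = 1/(1+e^(−uᵢ)),

with one global inhibitory current τ İ_inh = −I_inh − w_inh Σᵢ vᵢ
(winner-take-all competition) and short-term depression
ḟᵢ = (1−fᵢ)/τ_relax − F fᵢ vᵢ terminating high-activity episodes
(spike-frequency adaptation is available as an alternative). Each ordered
neuron pair owns S_max = 16 potential synaptic locations: vacant locations
become synapses at rate b = 1/day, existing ones are deleted at a
weight-dependent rate d(w) = d₁ + (d₀−d₁)/(1+e^(−β(w_off−w))), and weights
follow a three-regime Hebbian rule (decay / soft-bounded LTP / LTD around
the rate threshold 0.5). A mean-field theory predicts the synapse survival
probability s(t) during stimulation-rich (reactivation-free) phases, the
expected connectivity change per sensory+rest cycle and the stationary
number of synapses per connection.

The time-stepping engine (forward Euler, dt = 0.1 s) is compiled C++
(Rcpp); protocols, analysis and theory are plain R.

## Worked example

The mean-field theory with all default parameters:

```r
library(reassembly)
p <- model_params()

survival_probability(20 * 3600, p)     # synapse survival after 20 h without rest
#> [1] 0.9171581
stationary_S(2 * 3600, 4 * 3600, p)    # stationary synapses/connection, 4 h/2 h cycling
#> [1] 15.32624
max_sustainable_sensory(180, p) / 3600 # 3-min rests keep assemblies viable up to ~20 h
#> [1] 19.67502
growth_boundary_sensory(8, 2 * 3600, p) / 3600  # growth flips to decay near 23 h
#> [1] 22.97702
```

A synapse that has to live through 20 hours of sensory input without a
reactivation still survives with probability 0.92, and with 2-hour rest
phases every 4 hours an assembly converges towards ~15.3 of its 16 possible
synapses per connection — but once sensory phases exceed ~23 h per cycle the
assembly loses synapses, and beyond ~20 h (even with only 3-minute rests)
reactivation itself becomes impossible.

Associative recall is evaluated by cueing a stored pattern with part of its
neurons corrupted and classifying every neuron by the sign of its summed
input:

```r
p60 <- model_params(n_cells = 60)
tab <- init_assemblies(assembly_spec(list(1:30), 8), p60)  # strong assembly
set.seed(1)
evaluate_completion(tab, list(1:30), levels = c(0, 0.2, 0.4),
                    n_trials = 100, params = p60)$quality
#>   level correct false_negative false_positive
#> 1   0.0       1              0              0
#> 2   0.2       1              0              0
#> 3   0.4       1              0              0
```

An assembly wired at 8 synapses per connection completes patterns perfectly
even with 40% of the cue corrupted; rebuilt at 4 synapses per connection its
recurrent excitation barely clears inhibition and recall collapses beyond
10% corruption (`correct` drops to 0.55) — pattern completion is a threshold
phenomenon in S·w.

Full simulations are driven by `run_network()` /
`run_retention_experiment()`; see the vignette
(`vignettes/assembly-maintenance.Rmd`) for the three-phase protocol,
turnover and reactivation analyses, and all numerical choices. A thin
command-line front end is installed at `inst/cli/asim.R`
(`asim run|theory|fixture|analyze`).

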
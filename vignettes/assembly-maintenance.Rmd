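---
title: "Maintaining Hebbian cell assemblies under synaptic turnover: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maintaining Hebbian cell assemblies under synaptic turnover: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reassembly)
```

## The scientific problem

Cortical synapses turn over continuously: a sizeable fraction of the synapse
population is created and removed every day, yet memories survive for months.
`reassembly` implements a rate-based recurrent network in which Hebbian cell
assemblies — groups of neurons with strong mutual excitatory connectivity —
are maintained, and even strengthened, by their own spontaneous reactivation
during rest periods, despite ongoing synapse creation and deletion.

## Model

### Neuron and population dynamics

Each of the $N$ neurons carries a membrane potential $u_i$ obeying

$$\tau \dot u_i = -u_i + \sum_{j}\sum_{k=1}^{S_{ij}} f_j\, w_{ij,k}\, v_j
  + I_\mathrm{inh} + I_{\mathrm{stim},i} + I_{\mathrm{noise},i},$$

with rate $v_i = 1/(1+e^{-u_i})$ and $\tau = 155$ ms. A single global
inhibitory current, shared by all neurons, tracks the total activity,
$\tau \dot I_\mathrm{inh} = -I_\mathrm{inh} - w_\mathrm{inh}\sum_i v_i$ with
$w_\mathrm{inh} = 3.5\,w_\mathrm{max}$; it implements winner-take-all
competition between assemblies. $I_{\mathrm{noise},i}$ is one Gaussian draw
per neuron per integration step (sd 1.5), held constant across the step and
not rescaled by $\sqrt{dt}$ — results are therefore tied to the reference
step $dt = 0.1$ s, which is also the step used for all quantitative runs.

High-activity episodes are terminated by short-term depression: a
per-presynaptic-neuron utilization $f_i \in (0,1]$ with
$\dot f_i = (1-f_i)/\tau_\mathrm{relax} - F f_i v_i$
($\tau_\mathrm{relax} = 5$ s, $F = 1\,\mathrm{s}^{-1}$), multiplying all
outgoing weights. Alternatively the model can run with spike-frequency
adaptation, an extra current
$\tau_\mathrm{adapt}\dot I_{\mathrm{ad},i} = -I_{\mathrm{ad},i} - \alpha v_i$
($\alpha = 33$, $\tau_\mathrm{adapt} = 5$ s) added to the membrane equation,
with $f_i$ pinned at 1. See "Known limitations" for the reach of this
variant.

### Plasticity

Every ordered neuron pair owns $S_\mathrm{max} = 16$ potential synaptic
locations. Vacant locations become functional synapses at rate $b = 1$/day
(initial weight $w_0 = 10^{-3}$); occupied locations are deleted at the
weight-dependent rate

$$d(w) = d_1 + \frac{d_0 - d_1}{1 + e^{-\beta(w_\mathrm{off} - w)}},$$

which interpolates between $d_0 = 24$/day for weak synapses and
$d_1 = 0.03$/day for strong ones ($w_\mathrm{off} = 0.35\,w_\mathrm{max}$,
$\beta = 20$). Weights follow a three-regime Hebbian rule driven by the
step-start rates: decay at $(2\,\mathrm{days})^{-1}$ when both neurons are
below rate 0.5, soft-bounded potentiation at $0.1\,\mathrm{s}^{-1}$ towards
$w_\mathrm{max} = 0.7$ when both are above, depression at
$0.01\,\mathrm{s}^{-1}$ otherwise. Rates exactly at 0.5 fall into the
depression branch; this tie is measure-zero under noise but is pinned for
reproducibility.

Structural plasticity is Hebbian only indirectly: creation is uniform, but
potentiated synapses survive far longer, so connectivity follows the weights
on a timescale of days.

### Protocol

Experiments are composed of four phase kinds. A *warm-up* (6 h of random
sensory input) lets the structural dynamics reach its equilibrium of
$S_\mathrm{max}\,b/(b+d_0) = 0.64$ synapses per pair. During *learning*,
three disjoint 30-neuron groups are stimulated round-robin (amplitude 200
for 18 s, 36 s gap) for 9 h. *Sensory* phases deliver a fresh random
15-neuron pattern (amplitude 50) every second, drawn from the neurons that
belong to no assembly so that stored patterns are never cued externally.
*Rest* phases deliver nothing: all activity is intrinsically generated, and
assemblies reactivate spontaneously in brief Up states. Retention
experiments alternate sensory and rest phases with durations drawn either
from exponential distributions (means 4 h / 2 h; the default protocol) or
truncated normal distributions (sd = 0.25 mean; pre-wired experiments).

## Mean-field theory

During a sensory phase an assembly's weights start from $w_\mathrm{max}$
(reactivation in the preceding rest phase re-potentiates them) and decay as
$w(t) = w_\mathrm{max}e^{-\Delta_\mathrm{decay}t}$. The survival probability
of a synapse is $s(t) = \exp[-\int_0^t d(w(\tau))\,d\tau]$, evaluated by
adaptive quadrature (relative tolerance $10^{-9}$). Newly created synapses
stay weak and equilibrate at
$S_\mathrm{small}(t) = \tfrac{b}{d_0+b}(S_\mathrm{max} - S_0 s(t))$, giving
the decay time-course $S(t) = S_0 s(t) + S_\mathrm{small}(t)$. Reactivation
remains possible while $S_0 s(t) w(t) \ge w_\mathrm{inh}$; the expected
change over one sensory+rest cycle is
$\Delta S = S_\mathrm{max}(1-\gamma) - S_0(1-\gamma s(t_\mathrm{sens}))$
with $\gamma(t_\mathrm{rest}) = \tfrac{d_0}{d_0+b}e^{-b t_\mathrm{rest}}$,
and the stationary synapse number is
$S^* = S_\mathrm{max}(1-\gamma)/(1-\gamma s(t_\mathrm{sens}))$.
Root finding (sustainability bound, growth boundary) uses bracketing and
`uniroot` at $10^{-3}$ s resolution. The theory assumes every surviving and
newly created synapse is fully re-potentiated each rest phase; regimes with
rest phases too short for re-potentiation are outside its reach.

```{r theory}
p <- model_params()
survival_probability(20 * 3600, p)          # ~0.92 after 20 h without rest
max_sustainable_sensory(180, p) / 3600      # 3-min rests sustain ~20 h
growth_boundary_sensory(8, 2 * 3600, p) / 3600
```

## Numerical choices

* **Integration.** Forward Euler at $dt = 0.1$ s, the regime in which all
  printed parameters were calibrated. Within a step: recurrent current from
  the step-start rates, membrane update, rate recomputation, then
  inhibition and depression/adaptation updates from the *updated* rates,
  Hebbian update from the step-start rates, structural update last. The
  sequential (Gauss–Seidel) placement of the inhibition update is
  deliberate: updating $I_\mathrm{inh}$ from the step-start rates makes the
  discrete membrane–inhibition loop unstable for quiet networks beyond
  roughly a hundred neurons
  ($|z|^2 = (1-\tfrac{dt}{\tau})^2 + (\tfrac{dt}{\tau})^2
  w_\mathrm{inh}N g'(u^*) > 1$) and produces an artificial globally
  synchronized ~1 Hz bursting mode that potentiates every connection in the
  network. The sequential sweep has determinant $(1-\tfrac{dt}{\tau})^2$
  and is stable for all network sizes used here, while agreeing with the
  parallel order at $O(dt)$.
* **Structural sampling.** The reference semantics is one Bernoulli draw
  per potential location per interval with probabilities $1-e^{-b\,dt}$ and
  $1-e^{-d(w)\,dt}$ (exact for a constant hazard, so the interval length
  only enters through the piecewise-constant weight approximation). The
  compiled engine draws per-step candidate counts at the bounding hazards
  ($b$, $d_0$) and thins deletions by $d(w)/d_0$, which matches the
  Bernoulli semantics to $O((d_0\,dt)^2)$; an event-based variant with
  exponential waiting times is provided and required to be
  distributionally indistinguishable (tested).
* **Degenerate inputs.** Non-finite membrane potentials abort the run with
  a diagnostic rather than being clipped — clipping would silently mask
  parameter errors. Empty connection classes are reported as absent, not
  zero. New synapses become eligible for deletion one step after creation.
* **Determinism.** Each run consumes R's RNG stream; a master seed is split
  into named substreams (phase durations, sensory patterns, engine) so
  changing one stochastic component leaves the others' draws unchanged.

## What the scaled experiments emulate — and what they do not

The quantitative experiments are run at reduced size so the whole suite
executes in minutes on one core (the sizes are stated with each result):
turnover uses one 30-neuron assembly plus 30 controls over 3 days;
completion uses 120 neurons (3 groups + 30 controls) with a 9 h learning
phase; the decay-versus-theory comparison uses fifteen 6-neuron assemblies;
the overlap experiment uses two 15-neuron assemblies sharing 3 neurons over
5 days. Scaling changes two things a user should know about:

* **Sensory-pattern density.** The 15-neuron pattern size is a printed
  constant, so in a small network random patterns co-stimulate any given
  pair of eligible neurons far more often than at full scale. In a
  120-neuron network a literal 6 h warm-up therefore potentiates background
  weights past the deletion-sigmoid knee and wires a spurious assembly
  among the eligible neurons. Scaled learning runs consequently start
  directly from the warm-up's fixed point — background occupancy
  $b/(b+d_0)$ per location at $w_0$ — which is what the warm-up produces at
  full scale (verified: after hours of 240-neuron warm-up, mean weight
  stays ≈ 0.14 and occupancy ≈ 0.7 per pair, with essentially no weight
  above $w_\mathrm{off}$). For the same reason, control neurons in small
  retention runs develop stronger mutual connectivity than full-scale
  controls would; intra-assembly measurements are unaffected.
* **Overlap proportion.** The overlap between the two overlapping
  assemblies scales with the group (`ceiling(scale/6)`: 5 of 30, 3 of 15).
  A constant 5-neuron overlap on 15-neuron groups would double the relative
  through-overlap excitation while inhibition halves, fusing the two
  assemblies regardless of the adaptation mechanism.

* **Assembly survival.** Exponentially distributed sensory phases
  occasionally exceed the no-reactivation limit (~27 h for an assembly
  starting at 8 synapses per connection), after which the assembly decays
  to background occupancy. Daily-turnover measurements describe maintained
  assemblies, so collapsed runs (reactivation condition
  $S\,w_\mathrm{max} \ge w_\mathrm{inh}$ violated at the end of the run)
  are excluded and replaced by runs from fresh seeds.

Passing tests at these scales show that the implementation reproduces the
model's mechanisms (reactivation, winner-take-all, turnover balance, the
mean-field decay law) — they are not a quantitative statement about
full-size cortical networks, and none of the synthetic protocols capture
real sensory statistics, neuromodulation, or inhibitory plasticity.

## Worked example

A miniature retention run — one pre-wired assembly cycling through sensory
and rest phases — with the turnover measurement:

```{r retention, eval = FALSE}
fx <- make_fixture("single_assembly", scale = 30, seed = 1)
set.seed(substream_seed(1, "phases"))
cycles <- phase_durations(40, mode = "exponential")
rec <- run_retention_experiment(assembly_spec(fx$groups, 8), fx$params,
         cycles = cycles, total_time = 3 * 86400,
         cfg = run_config(seed = substream_seed(1, "engine"),
                          snapshot_every = 86400))
turnover_stats(rec$snapshots, pairs = fx$groups)$turnover
rest_phase_reactivations(rec)
```

## Known limitations

* **Spike-frequency adaptation cannot end strong Up states.** With the
  printed strength $\alpha = 33$, a fully potentiated 30-neuron assembly
  has Up-state drive $(m{-}1)S w_\mathrm{max} - w_\mathrm{inh}\Sigma v
  \approx +75$ or more, so $|I_\mathrm{ad}| \le \alpha$ can never pull the
  population back down: under the SFA variant, pre-wired assemblies ignite
  at rest onset and remain active for the entire phase (verified at full
  scale), and overlapping assemblies fuse instead of segregating. The
  package implements the variant exactly as specified and does not rescale
  $\alpha$; the corresponding overlap-segregation check is expected to fail
  and is kept as a documented open discrepancy. Short-term depression, the
  default mechanism, terminates Up states within ~1–2 s.
* The mean-field theory ignores re-potentiation time within rest phases
  and treats all intra-assembly synapses as exchangeable.
* Global (all-to-all) inhibition only; no structured inhibitory circuits,
  no distance-dependent potential connectivity, no synapse-intrinsic
  weight fluctuations.
* Results are $dt$-dependent by construction; $dt$ is exposed as a
  parameter but all validated behaviour refers to $dt = 0.1$ s.
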
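Package: reassembly
Title: Hebbian Cell Assemblies Under Synaptic and Structural Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rate-based recurrent network model of the formation, maintenance
    and self-organized reinforcement of Hebbian cell assemblies on a lattice of
    potential synapses. Combines a threshold-based Hebbian plasticity rule,
    weight-dependent structural plasticity (synapse creation and deletion),
    short-term depression or spike-frequency adaptation, and the three-phase
    stimulation protocol (learning, sensory, rest) under which assemblies
    spontaneously reactivate during rest and are strengthened against ongoing
    synaptic turnover. Includes analysis tools for synaptic turnover and
    persistence, reactivation detection and associative pattern completion, and
    a mean-field theory of synapse survival, per-cycle connectivity change and
    the stationary number of synapses per connection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
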
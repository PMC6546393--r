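#' Derive named sub-seeds from one master seed
#'
#' Splits a single seed into independent named substreams (e.g. "phases",
#' "sensory", "engine") so that changing one stochastic component of an
#' experiment leaves the draws of the others unchanged. Deterministic; the
#' derived seeds stay below 2^31.
#'
#' @param seed Integer master seed.
#' @param name Character substream name.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483647) + 1L
}

#' Deterministic miniature-network fixtures
#'
#' Builds the initial conditions of the standard experiment families:
#' \describe{
#'   \item{`background_equilibrium`}{`2 * scale` unconnected neurons with
#'     every potential location occupied independently with probability
#'     `b / (b + d0)` at weight `w0` - the structural equilibrium.}
#'   \item{`single_assembly`}{One assembly of `scale` neurons pre-wired with
#'     `s_init` synapses per connection at maximal weight, plus `scale`
#'     control neurons (at least 15, so sensory stimulation stays possible).}
#'   \item{`two_overlapping`}{Two assemblies of `scale` neurons sharing
#'     `overlap` neurons (default: proportional, `ceiling(scale / 6)`, i.e.
#'     5 shared neurons between 30-neuron groups), each connection wired
#'     with `s_init` synapses (default 12), plus controls. Keeping the
#'     overlap proportional preserves the balance between through-overlap
#'     excitation and global inhibition when the experiment is scaled down.}
#'   \item{`three_learned`}{Three disjoint groups of `scale` neurons wired
#'     with `s_init` synapses (a post-learning analogue), plus `5 * scale`
#'     controls; at `scale = 30` this is the full 240-neuron network.}
#' }
#'
#' @param kind Fixture family (see above).
#' @param scale Neurons per group (default 30).
#' @param seed Integer seed (fixtures are deterministic given the seed).
#' @param params Base [model_params()]; `n_cells` is overridden to fit the
#'   fixture.
#' @param s_init Synapses per intra-assembly connection.
#' @param overlap Shared neurons between the two overlapping groups.
#' @return A list with `params` (resized), `state`, `table`, `groups`,
#'   `controls`.
#' @export
make_fixture <- function(kind = c("background_equilibrium", "single_assembly",
                                  "two_overlapping", "three_learned"),
                         scale = 30L, seed = 1L, params = model_params(),
                         s_init = NULL, overlap = NULL) {
  kind <- match.arg(kind)
  scale <- as.integer(scale)
  if (is.null(overlap)) overlap <- ceiling(scale / 6)
  if (scale < 1L) stop("scale must be at least 1 neuron per group")
  set.seed(substream_seed(seed, paste0("fixture_", kind)))
  n_ctrl <- max(scale, 15L)
  layout <- switch(kind,
    background_equilibrium = list(n = 2L * scale, groups = list()),
    single_assembly = list(n = scale + n_ctrl,
                           groups = list(seq_len(scale))),
    two_overlapping = {
      if (overlap >= scale) stop("overlap must be smaller than the group size")
      g1 <- seq_len(scale)
      g2 <- seq.int(scale - overlap + 1L, 2L * scale - overlap)
      list(n = 2L * scale - overlap + n_ctrl, groups = list(g1, g2))
    },
    three_learned = list(n = 8L * scale,
                         groups = lapply(0:2, function(k)
                           seq_len(scale) + k * scale)))
  p <- params
  p$n_cells <- as.integer(layout$n)
  validate_params(p)
  if (is.null(s_init))
    s_init <- switch(kind, two_overlapping = 12L, background_equilibrium = 0L,
                     8L)
  table <- if (length(layout$groups) && s_init > 0L) {
    init_assemblies(assembly_spec(layout$groups, s_init), p)
  } else {
    synapse_table(p$n_cells, p$s_max)
  }
  if (kind == "background_equilibrium") {
    occ_p <- p$b / (p$b + p$d0)
    grid <- vacant_slots(table)
    take <- stats::runif(nrow(grid)) < occ_p
    table <- synapse_table(p$n_cells, p$s_max, post = grid$post[take],
                           pre = grid$pre[take], slot = grid$slot[take],
                           w = rep(p$w0, sum(take)))
  }
  controls <- setdiff(seq_len(p$n_cells), unlist(layout$groups))
  list(params = p, state = network_state(p), table = table,
       groups = layout$groups, controls = controls)
}
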
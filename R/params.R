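#' Model parameters
#'
#' Constructs the full parameter set of the network model: neuron dynamics,
#' global inhibition, Hebbian synaptic plasticity, weight-dependent structural
#' plasticity, and the adaptation mechanism that terminates high-activity
#' episodes (short-term depression or spike-frequency adaptation).
#'
#' Two parameters are derived from `w_max` by default: the inhibitory weight
#' `w_inh = 3.5 * w_max` and the deletion-sigmoid offset `w_off = 0.35 * w_max`.
#' If `w_max` is overridden these are rescaled accordingly unless they are
#' themselves given explicitly.
#'
#' @param tau Membrane (and inhibition) time constant, seconds.
#' @param n_cells Number of neurons.
#' @param s_max Number of potential synaptic locations per directed neuron pair.
#' @param w_max Maximal synaptic weight; global weight scale.
#' @param w_inh Inhibitory weight (default `3.5 * w_max`).
#' @param noise_sd Standard deviation of the per-neuron Gaussian noise current.
#' @param b Synapse creation rate per vacant potential location, per day.
#' @param d0 Deletion rate for weights near zero, per day.
#' @param d1 Deletion rate at the maximal weight, per day.
#' @param w_off Offset of the deletion sigmoid (default `0.35 * w_max`).
#' @param beta Steepness of the deletion sigmoid.
#' @param w0 Weight at which newly created synapses are initialised.
#' @param delta_decay Weight decay rate when both neurons are inactive, per
#'   second (default `1 / (2 * 86400)`, i.e. a two-day time constant).
#' @param delta_ltp Potentiation rate, per second.
#' @param delta_ltd Depression rate, per second.
#' @param tau_relax Recovery time constant of short-term depression, seconds.
#' @param f_dep Utilization rate of short-term depression, per second.
#' @param alpha_adapt Spike-frequency adaptation strength.
#' @param tau_adapt Adaptation time constant, seconds.
#' @param dt Forward-Euler integration step, seconds.
#' @param adaptation_mode Either `"short_term_depression"` (default) or
#'   `"spike_frequency_adaptation"`.
#'
#' @return An object of class `model_params` (a validated named list).
#' @examples
#' p <- model_params()
#' p$w_inh                  # 3.5 * 0.7
#' model_params(w_max = 1)$w_off  # rescaled to 0.35
#' @export
model_params <- function(tau = 0.155,
                         n_cells = 240L,
                         s_max = 16L,
                         w_max = 0.7,
                         w_inh = NULL,
                         noise_sd = 1.5,
                         b = 1,
                         d0 = 24,
                         d1 = 0.03,
                         w_off = NULL,
                         beta = 20,
                         w0 = 0.001,
                         delta_decay = 1 / (2 * 86400),
                         delta_ltp = 0.1,
                         delta_ltd = 0.01,
                         tau_relax = 5,
                         f_dep = 1,
                         alpha_adapt = 33,
                         tau_adapt = 5,
                         dt = 0.1,
                         adaptation_mode = c("short_term_depression",
                                             "spike_frequency_adaptation")) {
  adaptation_mode <- match.arg(adaptation_mode)
  if (is.null(w_inh)) w_inh <- 3.5 * w_max
  if (is.null(w_off)) w_off <- 0.35 * w_max
  p <- list(tau = tau, n_cells = as.integer(n_cells), s_max = as.integer(s_max),
            w_max = w_max, w_inh = w_inh, noise_sd = noise_sd,
            b = b, d0 = d0, d1 = d1, w_off = w_off, beta = beta, w0 = w0,
            delta_decay = delta_decay, delta_ltp = delta_ltp,
            delta_ltd = delta_ltd, tau_relax = tau_relax, f_dep = f_dep,
            alpha_adapt = alpha_adapt, tau_adapt = tau_adapt, dt = dt,
            adaptation_mode = adaptation_mode)
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' Validate a model_params object
#'
#' Checks positivity of rates and time constants, the weight ordering
#' `0 < w0 < w_off < w_max`, `d1 < d0`, and `dt < tau`.
#'
#' @param p A `model_params` object.
#' @return `p`, invisibly, if valid; otherwise an error listing every
#'   violated constraint.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  bad <- character(0)
  num <- p[setdiff(names(p), "adaptation_mode")]
  nf <- names(num)[!vapply(num, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x), logical(1))]
  if (length(nf))
    stop("non-finite or non-scalar parameter(s): ", paste(nf, collapse = ", "))
  pos <- c("tau", "n_cells", "s_max", "w_max", "w_inh", "b", "d0", "d1",
           "beta", "w0", "delta_decay", "delta_ltp", "delta_ltd",
           "tau_relax", "f_dep", "alpha_adapt", "tau_adapt", "dt")
  for (nm in pos) if (p[[nm]] <= 0) bad <- c(bad, paste0(nm, " must be > 0"))
  if (p$noise_sd < 0) bad <- c(bad, "noise_sd must be >= 0")
  if (p$dt >= p$tau) bad <- c(bad, "dt must be smaller than tau")
  if (!(p$w0 < p$w_off && p$w_off < p$w_max))
    bad <- c(bad, "weights must satisfy 0 < w0 < w_off < w_max")
  if (p$d1 >= p$d0) bad <- c(bad, "d1 must be smaller than d0")
  if (!p$adaptation_mode %in% c("short_term_depression",
                                "spike_frequency_adaptation"))
    bad <- c(bad, "unknown adaptation_mode")
  if (length(bad)) stop("invalid parameters:\n  ", paste(bad, collapse = "\n  "))
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  %d neurons, s_max = %d, dt = %g s, adaptation = %s\n",
              x$n_cells, x$s_max, x$dt, x$adaptation_mode))
  cat(sprintf("  weights: w_max = %g, w_inh = %g, w_off = %g, w0 = %g\n",
              x$w_max, x$w_inh, x$w_off, x$w0))
  cat(sprintf("  structural: b = %g/day, d0 = %g/day, d1 = %g/day, beta = %g\n",
              x$b, x$d0, x$d1, x$beta))
  cat(sprintf("  Hebbian: LTP %g/s, LTD %g/s, decay %g/s\n",
              x$delta_ltp, x$delta_ltd, x$delta_decay))
  invisible(x)
}

#' Read / write model parameters as a flat config file
#'
#' Parameters are stored as a flat key-value mapping in JSON or YAML. On
#' reading, unknown keys are rejected and omitted keys fall back to defaults;
#' the derived fields `w_inh` and `w_off` are recomputed from an overridden
#' `w_max` unless the file sets them explicitly.
#'
#' @param path File path; format is inferred from the extension
#'   (`.json`, `.yaml`/`.yml`).
#' @param p A `model_params` object.
#' @return `read_params` returns a `model_params` object; `write_params`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  vals <- read_kv(path)
  params_from_list(vals)
}

#' @rdname read_params
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "model_params"))
  write_kv(unclass(p), path)
  invisible(path)
}

# Build model_params from a plain named list of overrides (unknown keys fatal).
params_from_list <- function(vals) {
  stopifnot(is.list(vals))
  known <- names(formals(model_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown parameter key(s): ", paste(unknown, collapse = ", "))
  do.call(model_params, vals)
}

read_kv <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext))
  if (is.null(vals)) vals <- list()
  as.list(vals)
}

write_kv <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    yaml = ,
    yml = yaml::write_yaml(x, path),
    stop("unsupported config format: .", ext))
  invisible(path)
}
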
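#' Load a full experiment configuration
#'
#' Reads a YAML or JSON experiment description and resolves it to a fully
#' explicit manifest. Recognised top-level keys:
#' \describe{
#'   \item{`params`}{[model_params()] overrides (flat key-value map).}
#'   \item{`assembly`}{`groups` (list of id vectors), `s_init`, optional
#'     `w_init`.}
#'   \item{`phases`}{`mode` (`exponential` / `truncated_normal`),
#'     `mean_sens`, `mean_rest` (seconds), `total_time` (seconds), or an
#'     explicit `cycles` list of `[sens, rest]` pairs.}
#'   \item{`run`}{`seed`, `snapshot_every`, `record_every`, `log_events`,
#'     `hebbian`, `structural`.}
#' }
#' Unknown keys at any level are rejected; every validation failure is
#' reported.
#'
#' @param path Config file path (`.json`, `.yaml`, `.yml`). An empty file
#'   resolves to all defaults.
#' @return A list with elements `params` (`model_params`), `assembly`
#'   (`assembly_spec` or `NULL`), `phases` (resolved list), `run`
#'   (`run_config`).
#' @export
load_config <- function(path) {
  raw <- read_kv(path)
  unknown <- setdiff(names(raw), c("params", "assembly", "phases", "run"))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  params <- params_from_list(as.list(raw$params))
  assembly <- NULL
  if (!is.null(raw$assembly)) {
    a <- raw$assembly
    bad <- setdiff(names(a), c("groups", "s_init", "w_init"))
    if (length(bad))
      stop("unknown assembly key(s): ", paste(bad, collapse = ", "))
    if (is.null(a$groups) || is.null(a$s_init))
      stop("assembly section requires groups and s_init")
    assembly <- assembly_spec(a$groups, a$s_init, a$w_init)
  }
  ph <- as.list(raw$phases)
  bad <- setdiff(names(ph), c("mode", "mean_sens", "mean_rest", "total_time",
                              "cycles"))
  if (length(bad)) stop("unknown phases key(s): ", paste(bad, collapse = ", "))
  phases <- list(mode = if (is.null(ph$mode)) "exponential" else ph$mode,
                 mean_sens = if (is.null(ph$mean_sens)) 4 * 3600 else ph$mean_sens,
                 mean_rest = if (is.null(ph$mean_rest)) 2 * 3600 else ph$mean_rest,
                 total_time = ph$total_time,
                 cycles = if (!is.null(ph$cycles))
                   as.data.frame(do.call(rbind, lapply(ph$cycles, function(cy)
                     stats::setNames(as.numeric(cy), c("sens", "rest"))))))
  if (!phases$mode %in% c("exponential", "truncated_normal"))
    stop("phases$mode must be exponential or truncated_normal")
  rn <- as.list(raw$run)
  bad <- setdiff(names(rn), c("seed", "snapshot_every", "record_every",
                              "log_events", "hebbian", "structural"))
  if (length(bad)) stop("unknown run key(s): ", paste(bad, collapse = ", "))
  run <- do.call(run_config, rn)
  list(params = params, assembly = assembly, phases = phases, run = run)
}

#' Save an experiment configuration
#'
#' Writes the fully resolved manifest back to YAML or JSON;
#' `load_config(save_config(cfg, path))` round-trips.
#'
#' @param cfg A list as returned by [load_config()].
#' @param path Output path (`.json`, `.yaml`, `.yml`).
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  out <- list(params = unclass(cfg$params))
  if (!is.null(cfg$assembly))
    out$assembly <- list(groups = cfg$assembly$groups,
                         s_init = cfg$assembly$s_init,
                         w_init = cfg$assembly$w_init)
  ph <- cfg$phases
  out$phases <- ph[!vapply(ph, is.null, logical(1))]
  if (!is.null(out$phases$cycles))
    out$phases$cycles <- lapply(seq_len(nrow(ph$cycles)), function(i)
      c(ph$cycles$sens[i], ph$cycles$rest[i]))
  run <- unclass(cfg$run)
  out$run <- run[!vapply(run, is.null, logical(1))]
  write_kv(out, path)
  invisible(path)
}
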
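#' Table of functional synapses on the potential-synapse lattice
#'
#' Every directed neuron pair (post i, pre j), i != j, owns `s_max` potential
#' synaptic locations, indexed by slot k in 1..s_max. A `synapse_table` lists
#' the currently occupied (functional) locations together with their weights
#' and creation times; all other locations are vacant. Conservation holds by
#' construction: occupied + vacant = `s_max` for every pair.
#'
#' @param n_cells Number of neurons.
#' @param s_max Potential synaptic locations per directed pair.
#' @param post,pre,slot Integer vectors describing occupied locations.
#' @param w Weights of the occupied locations, in `[0, w_max]`.
#' @param t_create Creation time of each occupied location, seconds. Used by
#'   the turnover/persistence analysis as a slot-occupancy identity.
#' @param t Current time of the table, seconds.
#' @return An object of class `synapse_table`.
#' @examples
#' tab <- synapse_table(4, 16)        # empty lattice
#' n_synapses(tab)                    # 0
#' @export
synapse_table <- function(n_cells, s_max, post = integer(0), pre = integer(0),
                          slot = integer(0), w = numeric(0),
                          t_create = numeric(0), t = 0) {
  n_cells <- as.integer(n_cells); s_max <- as.integer(s_max)
  post <- as.integer(post); pre <- as.integer(pre); slot <- as.integer(slot)
  m <- length(post)
  if (length(pre) != m || length(slot) != m || length(w) != m)
    stop("post, pre, slot, w must have equal length")
  if (length(t_create) == 0L) t_create <- rep(t, m)
  if (length(t_create) != m) stop("t_create length mismatch")
  if (m) {
    if (any(post < 1L | post > n_cells | pre < 1L | pre > n_cells))
      stop("neuron index out of range")
    if (any(post == pre)) stop("self-connections are not allowed")
    if (any(slot < 1L | slot > s_max)) stop("slot index out of range")
    if (anyDuplicated(cbind(post, pre, slot)))
      stop("duplicate (post, pre, slot) entries")
    if (any(w < 0)) stop("negative synaptic weight")
  }
  structure(list(n_cells = n_cells, s_max = s_max, post = post, pre = pre,
                 slot = slot, w = as.numeric(w),
                 t_create = as.numeric(t_create), t = t),
            class = "synapse_table")
}

#' @rdname synapse_table
#' @param table A `synapse_table`.
#' @export
n_synapses <- function(table) length(table$post)

#' @export
print.synapse_table <- function(x, ...) {
  np <- x$n_cells * (x$n_cells - 1L)
  cat(sprintf("<synapse_table> %d neurons, s_max = %d: %d functional synapses (%.3f per pair) at t = %g s\n",
              x$n_cells, x$s_max, n_synapses(x),
              if (np) n_synapses(x) / np else 0, x$t))
  invisible(x)
}

#' @export
as.data.frame.synapse_table <- function(x, ...) {
  data.frame(post = x$post, pre = x$pre, slot = x$slot, w = x$w,
             t_create = x$t_create)
}

#' Pair-level connectivity summaries
#'
#' Collapses a synapse table to dense matrices: the number of synapses
#' `S[i, j]` and the summed weight `W[i, j]` of each directed connection
#' (row = postsynaptic, column = presynaptic neuron).
#'
#' @param table A [synapse_table()].
#' @return A list with integer matrix `S` and numeric matrix `W`, both
#'   `n_cells x n_cells` with zero diagonal.
#' @export
pair_summaries <- function(table) {
  n <- table$n_cells
  S <- matrix(0L, n, n)
  W <- matrix(0, n, n)
  if (n_synapses(table)) {
    cnt <- tapply(rep(1L, length(table$post)),
                  list(factor(table$post, seq_len(n)),
                       factor(table$pre, seq_len(n))), sum, default = 0L)
    ws <- tapply(table$w,
                 list(factor(table$post, seq_len(n)),
                      factor(table$pre, seq_len(n))), sum, default = 0)
    S[] <- as.integer(cnt)
    W[] <- ws
  }
  list(S = S, W = W)
}

#' Write / read a synapse-table snapshot as tabular text
#'
#' The sparse triplet representation (post, pre, slot, weight, creation time)
#' is written as a tab-separated file with a two-line header carrying
#' `n_cells`, `s_max` and the snapshot time.
#'
#' @param table A [synapse_table()].
#' @param path Output file path.
#' @return `write_synapse_table` returns `path` invisibly;
#'   `read_synapse_table` returns a `synapse_table`.
#' @export
write_synapse_table <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_cells=%d s_max=%d t=%.17g",
                     table$n_cells, table$s_max, table$t), con)
  utils::write.table(as.data.frame(table), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_synapse_table
#' @export
read_synapse_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "n_cells=([0-9]+) s_max=([0-9]+) t=([-0-9.eE+]+)", hdr))[[1]]
  if (length(m) != 4L) stop("not a synapse_table snapshot: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  synapse_table(as.integer(m[2]), as.integer(m[3]),
                post = df$post, pre = df$pre, slot = df$slot, w = df$w,
                t_create = df$t_create, t = as.numeric(m[4]))
}
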
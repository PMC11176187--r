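#' Synchronous Boolean networks
#'
#' A `boolean_network` couples `n` named nodes, each with an ordered regulator
#' list and an update rule stored as a [truth_table()] whose arity equals the
#' number of listed regulators. All nodes are updated synchronously: the map
#' `F` sends a state `x` to `(f_1(x), ..., f_n(x))`, each `f_j` reading only
#' its regulators. Node order in state vectors follows the order of `rules`.
#'
#' @param rules list of [truth_table()] objects, one per node.
#' @param regulators list of integer vectors; `regulators[[j]]` are the node
#'   indices feeding rule `j`, in the order of that rule's inputs.
#' @param node_names unique character names (default `x1, ..., xn`).
#' @return An object of class `boolean_network` with fields `n`,
#'   `node_names`, `regulators`, `rules`.
#' @examples
#' swap <- boolean_network(
#'   rules = list(truth_table(c(0, 1)), truth_table(c(0, 1))),
#'   regulators = list(2L, 1L), node_names = c("A", "B"))
#' synchronous_step(swap, c(0, 1))
#' @export
boolean_network <- function(rules, regulators, node_names = NULL) {
  n <- length(rules)
  stopifnot(length(regulators) == n)
  node_names <- node_names %||% paste0("x", seq_len(n))
  if (anyDuplicated(node_names)) stop("node names must be unique")
  for (j in seq_len(n)) {
    if (!inherits(rules[[j]], "truth_table"))
      stop("rule ", j, " is not a truth_table")
    regs <- as.integer(regulators[[j]])
    if (length(regs) != rules[[j]]$k)
      stop("node ", node_names[j], ": rule arity ", rules[[j]]$k,
           " does not match its ", length(regs), " regulators")
    if (length(regs) && (any(regs < 1) || any(regs > n)))
      stop("node ", node_names[j], ": regulator index out of range")
    regulators[[j]] <- regs
  }
  structure(list(n = n, node_names = as.character(node_names),
                 regulators = regulators, rules = rules),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network with", x$n, "node(s)\n")
  k <- vapply(x$rules, function(r) r$k, integer(1))
  cat("in-degrees (listed):", paste(k, collapse = ","), "\n")
  invisible(x)
}

#' Synchronous update of a Boolean network
#'
#' @param net a [boolean_network()].
#' @param state bit vector of length `net$n`.
#' @return The successor state (integer 0/1 vector).
#' @export
synchronous_step <- function(net, state) {
  stopifnot(inherits(net, "boolean_network"))
  if (length(state) != net$n)
    stop("state has length ", length(state), " but the network has n = ", net$n)
  state <- as.integer(state)
  vapply(seq_len(net$n), function(j)
    net$rules[[j]]$outputs[tt_index(state[net$regulators[[j]]]) + 1L],
    integer(1))
}

## synchronous step on a matrix of states (rows = states); used by the
## dynamics and approximation machinery
step_states <- function(net, X) {
  Xn <- X
  for (j in seq_len(net$n)) {
    regs <- net$regulators[[j]]
    idx <- tt_index_matrix(X[, regs, drop = FALSE])
    Xn[, j] <- net$rules[[j]]$outputs[idx + 1L]
  }
  Xn
}

#' Wiring diagram of a Boolean network
#'
#' The directed graph with an edge `i -> j` whenever rule `j` depends
#' essentially on node `i`; regulators listed in a rule but not essential do
#' not contribute edges.
#'
#' @param net a [boolean_network()].
#' @return An object of class `wiring_diagram`: list with `n`, `node_names`,
#'   `edges` (tibble `from`, `to`, node indices), `in_degree`, `out_degree`.
#' @export
wiring_diagram <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  from <- integer(0); to <- integer(0)
  for (j in seq_len(net$n)) {
    ess <- essential_variables(net$rules[[j]])
    src <- net$regulators[[j]][ess]
    from <- c(from, src)
    to <- c(to, rep(j, length(src)))
  }
  edges <- tibble::tibble(from = from, to = to)
  structure(list(n = net$n, node_names = net$node_names, edges = edges,
                 in_degree = tabulate(to, net$n),
                 out_degree = tabulate(from, net$n)),
            class = "wiring_diagram")
}

#' @export
print.wiring_diagram <- function(x, ...) {
  cat("wiring diagram:", x$n, "node(s),", nrow(x$edges), "edge(s)\n")
  invisible(x)
}

## dense adjacency matrix A[i, j] = 1 iff edge i -> j
wiring_adjacency <- function(wd) {
  A <- matrix(0L, wd$n, wd$n)
  if (nrow(wd$edges)) A[cbind(wd$edges$from, wd$edges$to)] <- 1L
  A
}

#' Export a wiring diagram as an edge list
#'
#' @param wd a [wiring_diagram()].
#' @param path optional TSV path (columns `source`, `target`, node names).
#' @return A tibble with character columns `source` and `target`.
#' @export
wiring_edge_list <- function(wd, path = NULL) {
  el <- tibble::tibble(source = wd$node_names[wd$edges$from],
                       target = wd$node_names[wd$edges$to])
  if (!is.null(path))
    utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  el
}

#' External parameters of a Boolean network
#'
#' Node `i` is an external parameter when its reduced update rule is the
#' identity on itself (`f_i = x_i`), so its value never changes; `c` such
#' nodes split the state space into `2^c` disconnected components. A node
#' with `f_i = !x_i` is self-regulating but not external.
#'
#' @param net a [boolean_network()].
#' @return Integer vector of external-parameter node indices.
#' @export
external_parameters <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  which(vapply(seq_len(net$n), function(j) {
    red <- reduce_to_essential(net$rules[[j]])
    ess <- net$regulators[[j]][attr(red, "essential")]
    red$k == 1L && identical(ess, j) && identical(red$outputs, c(0L, 1L))
  }, logical(1)))
}

#' Dump a Boolean network as JSON
#'
#' @param net a [boolean_network()].
#' @param path optional output file.
#' @return JSON string (names, regulator names, truth-table bitstrings).
#' @export
network_to_json <- function(net, path = NULL) {
  js <- jsonlite::toJSON(list(
    n = net$n, nodes = net$node_names,
    regulators = lapply(net$regulators, function(r) net$node_names[r]),
    rules = vapply(net$rules, function(tt) paste(tt$outputs, collapse = ""),
                   character(1))),
    auto_unbox = TRUE)
  if (!is.null(path)) writeLines(js, path)
  js
}
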
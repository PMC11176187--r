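#' Attractor analysis of synchronous Boolean networks
#'
#' `exact_attractors()` enumerates the whole state space (feasible up to the
#' `max_n` cap) and assigns every state to its basin; `sampled_attractors()`
#' follows trajectories from `n_ic` distinct random initial states until a
#' state repeats, measuring each attractor's length as the number of updates
#' between the first and second visit of the repeated state. The sampled
#' attractor count is a lower bound of the true count; attractors with large
#' basins are found with high probability. Attractors are identified by the
#' lexicographically minimal rotation of their state cycle, so the same cycle
#' found from different starts deduplicates deterministically.
#'
#' @param net a [boolean_network()].
#' @param max_n refuse exact enumeration above this size.
#' @param n_ic number of distinct initial states (all states when
#'   `2^n <= n_ic`).
#' @return An object of class `attractor_set`: list with `attractors` (each a
#'   character vector of state bitstrings along the cycle, canonical
#'   rotation), `lengths`, `basin_counts`, `n_attractors`, `mode`
#'   (`"exact"` or `"sampled"`) and `n_initial_conditions` (`2^n` for exact).
#'   Basin counts always sum to `n_initial_conditions`.
#' @examples
#' swap <- boolean_network(list(truth_table(c(0, 1)), truth_table(c(0, 1))),
#'                         list(2L, 1L))
#' exact_attractors(swap)  # two fixed points and one 2-cycle
#' @export
exact_attractors <- function(net, max_n = 20) {
  stopifnot(inherits(net, "boolean_network"))
  n <- net$n
  if (n > max_n)
    stop("exact state-space enumeration requested for n = ", n, " > ", max_n,
         "; use sampled_attractors()")
  succ <- successor_table(net)
  res <- trace_basins(succ, seq_len(2^n), n)
  structure(list(attractors = res$attractors, lengths = res$lengths,
                 basin_counts = res$basin_counts,
                 n_attractors = length(res$lengths),
                 mode = "exact", n_initial_conditions = 2^n),
            class = "attractor_set")
}

## 1-based successor index for every state 0..2^n-1
successor_table <- function(net) {
  n <- net$n
  X <- tt_inputs(n)
  S <- step_states(net, X)
  tt_index_matrix(S) + 1L
}

## walk the functional graph from the given 1-based start states; returns
## attractors (canonical cycles), lengths, and per-attractor hit counts
trace_basins <- function(succ, starts, n) {
  n_states <- length(succ)
  basin <- integer(n_states)           # 0 = unexplored, else attractor id
  on_path <- integer(n_states)         # position in current path, 0 if not
  attractors <- list(); lengths <- integer(0)
  hits <- integer(0)
  for (s in starts) {
    if (basin[s] != 0L) { hits[basin[s]] <- hits[basin[s]] + 1L; next }
    path <- integer(0)
    t <- s
    while (basin[t] == 0L && on_path[t] == 0L) {
      path <- c(path, t)
      on_path[t] <- length(path)
      t <- succ[t]
    }
    if (on_path[t] != 0L) {            # new cycle discovered on this path
      cyc <- path[on_path[t]:length(path)]
      id <- length(lengths) + 1L
      start_idx <- which.min(cyc)      # canonical rotation: begin at min state
      cyc <- cyc[c(start_idx:length(cyc), seq_len(start_idx - 1L))]
      attractors[[id]] <- state_strings(cyc - 1L, n)
      lengths[id] <- length(cyc)
      hits[id] <- 0L
      basin[cyc] <- id
    }
    id <- basin[t]
    basin[path[basin[path] == 0L]] <- id
    on_path[path] <- 0L
    hits[id] <- hits[id] + 1L
  }
  list(attractors = attractors, lengths = lengths, basin_counts = hits)
}

state_strings <- function(idx0, n) {
  vapply(idx0, function(v)
    paste(bitwAnd(v %/% 2^((n - 1L):0L), 1L), collapse = ""), character(1))
}

#' @rdname exact_attractors
#' @export
sampled_attractors <- function(net, n_ic = 1000, max_n = 20) {
  stopifnot(inherits(net, "boolean_network"))
  n <- net$n
  if (n <= max_n) {
    ## small enough to precompute the successor table; sampling is then a
    ## cheap walk over the functional graph
    n_states <- 2^n
    starts <- if (n_states <= n_ic) seq_len(n_states)
              else sample.int(n_states, n_ic)
    succ <- successor_table(net)
    res <- trace_basins(succ, starts, n)
  } else {
    res <- sampled_attractors_hashed(net, n_ic)
  }
  structure(list(attractors = res$attractors, lengths = res$lengths,
                 basin_counts = res$basin_counts,
                 n_attractors = length(res$lengths),
                 mode = "sampled",
                 n_initial_conditions = sum(res$basin_counts)),
            class = "attractor_set")
}

## trajectory walking with hashed states, for n beyond the enumeration cap
sampled_attractors_hashed <- function(net, n_ic) {
  n <- net$n
  X0 <- sample_initial_states(n, n_ic)
  reg <- new.env(parent = emptyenv())   # canonical key -> attractor id
  attractors <- list(); lengths <- integer(0); hits <- integer(0)
  for (r in seq_len(nrow(X0))) {
    seen <- new.env(parent = emptyenv())
    x <- X0[r, ]
    key <- paste(x, collapse = "")
    step <- 0L
    while (is.null(seen[[key]])) {
      seen[[key]] <- step
      x <- synchronous_step(net, x)
      key <- paste(x, collapse = "")
      step <- step + 1L
    }
    L <- step - seen[[key]]
    ## collect the cycle states in order
    cyc <- character(L)
    for (i in seq_len(L)) {
      cyc[i] <- key
      x <- synchronous_step(net, x)
      key <- paste(x, collapse = "")
    }
    rot <- which(cyc == min(cyc))[1]
    cyc <- cyc[c(rot:L, seq_len(rot - 1L))]
    ckey <- cyc[1]
    id <- reg[[ckey]]
    if (is.null(id)) {
      id <- length(lengths) + 1L
      reg[[ckey]] <- id
      attractors[[id]] <- cyc
      lengths[id] <- L
      hits[id] <- 0L
    }
    hits[id] <- hits[id] + 1L
  }
  list(attractors = attractors, lengths = lengths, basin_counts = hits)
}

#' @export
print.attractor_set <- function(x, ...) {
  cat(x$n_attractors, "attractor(s) [", x$mode, "mode,",
      x$n_initial_conditions, "initial conditions ]\n")
  cat("lengths:", paste(x$lengths, collapse = ","), "\n")
  cat("basin counts:", paste(x$basin_counts, collapse = ","), "\n")
  invisible(x)
}

#' Summary metrics of an attractor landscape
#'
#' Reports the attractor count `s`, the unweighted mean attractor length
#' `(1/s) sum L_i` and steady-state proportion `(1/s) sum 1(L_i = 1)`, their
#' basin-weighted counterparts (weights `B_i / N`), and the basin entropy
#' `-sum (B_i/N) log(B_i/N)` (natural log, in `[0, Inf)`).
#'
#' @param aset an [exact_attractors()] / [sampled_attractors()] result.
#' @return A one-row tibble with columns `n_attractors`, `mean_length`,
#'   `prop_steady`, `mean_length_weighted`, `prop_steady_weighted`,
#'   `basin_entropy`, `mode`.
#' @export
attractor_metrics <- function(aset) {
  stopifnot(inherits(aset, "attractor_set"))
  L <- aset$lengths
  B <- aset$basin_counts
  w <- B / aset$n_initial_conditions
  tibble::tibble(
    n_attractors = aset$n_attractors,
    mean_length = mean(L),
    prop_steady = mean(L == 1),
    mean_length_weighted = sum(w * L),
    prop_steady_weighted = sum(w * (L == 1)),
    basin_entropy = -sum(w[w > 0] * log(w[w > 0])),
    mode = aset$mode)
}

#' Attractors per external-parameter configuration
#'
#' A network with `c` external parameters decomposes into `2^c` disconnected
#' state spaces, each retaining at least one attractor; this normalizes the
#' exact attractor count by `2^c`, so the result is always `>= 1`.
#'
#' @param net a [boolean_network()].
#' @param max_n cap passed to [exact_attractors()].
#' @return A number `>= 1`.
#' @export
attractors_per_external_configuration <- function(net, max_n = 20) {
  c_ext <- length(external_parameters(net))
  exact_attractors(net, max_n = max_n)$n_attractors / 2^c_ext
}

#' Network mean average sensitivity (Derrida coefficient)
#'
#' The mean over nodes of the average sensitivity of the reduced update
#' rules: the expected one-step size of a single-bit perturbation under the
#' annealed approximation. Values below/above 1 mark the ordered/chaotic
#' regime; random `(K, p)` ensembles average `2 K p (1 - p)`.
#'
#' @param net a [boolean_network()].
#' @return A non-negative number.
#' @export
network_average_sensitivity <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  mean(vapply(net$rules,
              function(tt) average_sensitivity(reduce_to_essential(tt)),
              numeric(1)))
}

#' Export an attractor set to JSON
#'
#' @param aset an `attractor_set`.
#' @param path optional output file.
#' @return JSON string (states as bitstrings).
#' @export
attractors_to_json <- function(aset, path = NULL) {
  js <- jsonlite::toJSON(list(
    mode = aset$mode,
    n_initial_conditions = aset$n_initial_conditions,
    attractors = aset$attractors,
    lengths = aset$lengths,
    basin_counts = aset$basin_counts), auto_unbox = TRUE)
  if (!is.null(path)) writeLines(js, path)
  js
}
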
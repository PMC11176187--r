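#' Continuous Taylor approximation of a Boolean network
#'
#' Replaces every update rule (reduced to its essential inputs) by the
#' order-`m` Taylor truncation of its multilinear extension around
#' `(1/2, ..., 1/2)`, composed with clipping to `[0, 1]`. At a binary state
#' the approximation reproduces the Boolean update exactly for every node
#' whose (essential) in-degree is at most `m`; with `m` at least the maximum
#' essential in-degree the two systems have identical trajectories from
#' binary starts.
#'
#' @param net a [boolean_network()].
#' @param m Taylor order (`m >= 0`); rules of lower arity keep their exact
#'   polynomial.
#' @return An object of class `continuous_network` with per-node truncated
#'   polynomials and regulator lists.
#' @export
approximate_network <- function(net, m) {
  stopifnot(inherits(net, "boolean_network"), m >= 0)
  nodes <- lapply(seq_len(net$n), function(j) {
    red <- reduce_to_essential(net$rules[[j]])
    regs <- net$regulators[[j]][attr(red, "essential")]
    poly <- continuous_extension(red)
    list(regulators = regs,
         poly = taylor_truncation(poly, min(m, poly$k)))
  })
  structure(list(n = net$n, node_names = net$node_names, order = m,
                 nodes = nodes),
            class = "continuous_network")
}

#' @export
print.continuous_network <- function(x, ...) {
  cat("clipped continuous network on", x$n, "node(s), Taylor order", x$order, "\n")
  invisible(x)
}

## one clipped synchronous update of a matrix of continuous states
step_states_continuous <- function(cnet, X) {
  Xn <- X
  for (j in seq_len(cnet$n)) {
    nd <- cnet$nodes[[j]]
    v <- poly_evaluate_matrix(nd$poly, X[, nd$regulators, drop = FALSE])
    Xn[, j] <- pmin(1, pmax(0, v))
  }
  Xn
}

#' Iterate a continuous network
#'
#' Synchronously updates the clipped polynomial map `steps` times.
#'
#' @param cnet an [approximate_network()].
#' @param x0 numeric start state in `[0,1]^n`.
#' @param steps number of synchronous updates (`>= 0`).
#' @return The state after `steps` updates.
#' @export
simulate_continuous <- function(cnet, x0, steps) {
  stopifnot(inherits(cnet, "continuous_network"), length(x0) == cnet$n,
            steps >= 0)
  X <- matrix(as.numeric(x0), nrow = 1)
  for (s in seq_len(steps)) X <- step_states_continuous(cnet, X)
  drop(X)
}

#' Iterate a Boolean network
#'
#' @param net a [boolean_network()].
#' @param x0 binary start state.
#' @param steps number of synchronous updates (`>= 0`).
#' @return The state after `steps` updates.
#' @export
simulate_boolean <- function(net, x0, steps) {
  stopifnot(inherits(net, "boolean_network"), length(x0) == net$n, steps >= 0)
  X <- matrix(as.integer(x0), nrow = 1)
  for (s in seq_len(steps)) X <- step_states(net, X)
  drop(X)
}

## sample `n_ic` distinct binary states of length n (all states when
## 2^n <= n_ic); for very large n, collisions are removed and resampled
sample_initial_states <- function(n, n_ic) {
  if (n <= 30 && 2^n <= n_ic) {
    return(tt_inputs(n))
  }
  if (n <= 30) {
    idx <- sample.int(2^n, n_ic) - 1L
    X <- vapply(seq_len(n), function(i) bitwAnd(idx %/% 2^(n - i), 1L),
                integer(n_ic))
    return(X)
  }
  X <- matrix(sample(0:1, n_ic * n, replace = TRUE), n_ic, n)
  X <- unique(X)
  while (nrow(X) < n_ic) {
    X <- unique(rbind(X, matrix(sample(0:1, n, replace = TRUE), 1, n)))
  }
  X
}

#' Mean approximation error of a Taylor-approximated Boolean network
#'
#' Runs the Boolean network and its clipped order-`m` continuous
#' approximation synchronously for `steps` updates from the same random
#' binary initial states, and reports the mean (over states and coordinates)
#' squared difference of the final states. The error lies in `[0, 1]`; 0.25
#' is the signature of a continuous system stuck at the central fixed point
#' `1/2` against a freely oscillating Boolean trajectory, and is the largest
#' value seen in practice. When every rule's essential arity is at most `m`
#' the error is exactly 0.
#'
#' Initial states are drawn without replacement (all `2^n` states when the
#' state space is smaller than `n_ic`); pass `initial_states` to share them
#' across approximation orders or networks. With `m` a vector, the Boolean
#' trajectory and initial states are shared across all orders.
#'
#' @param net a [boolean_network()].
#' @param m Taylor order(s).
#' @param n_ic number of random initial states.
#' @param steps synchronous updates applied to both systems.
#' @param initial_states optional binary matrix (rows = states) overriding
#'   the sampler.
#' @return A numeric vector of MAE values, one per entry of `m` (named by
#'   order).
#' @export
mean_approximation_error <- function(net, m, n_ic = 1000, steps = 25,
                                     initial_states = NULL) {
  stopifnot(inherits(net, "boolean_network"))
  X0 <- initial_states %||% sample_initial_states(net$n, n_ic)
  storage.mode(X0) <- "integer"
  XB <- X0
  for (s in seq_len(steps)) XB <- step_states(net, XB)
  out <- vapply(m, function(ord) {
    cnet <- approximate_network(net, ord)
    XC <- matrix(as.numeric(X0), nrow(X0), ncol(X0))
    for (s in seq_len(steps)) XC <- step_states_continuous(cnet, XC)
    mean((XB - XC)^2)
  }, numeric(1))
  names(out) <- paste0("order_", m)
  out
}
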
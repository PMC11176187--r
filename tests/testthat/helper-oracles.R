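# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the package's own algorithms: everything here is
# direct enumeration over the (tiny) input spaces.

# truth table from an R predicate over bit vectors
make_tt <- function(f, k, ...) {
  X <- canalax:::tt_inputs(k)
  truth_table(apply(X, 1, function(x) as.integer(as.logical(f(x, ...)))))
}

# all 2^(2^k) truth tables of arity k (k <= 3 in tests)
all_functions <- function(k) {
  n <- 2^k
  lapply(0:(2^n - 1L), function(m)
    truth_table(bitwAnd(m %/% 2^((n - 1L):0L), 1L)))
}

# oracle: essential variables by double loop over inputs and coordinates
oracle_essential <- function(tt) {
  k <- tt$k
  if (k == 0L) return(integer(0))
  X <- canalax:::tt_inputs(k)
  ess <- logical(k)
  for (i in seq_len(k)) {
    for (r in seq_len(nrow(X))) {
      x <- X[r, ]; y <- x; y[i] <- 1L - y[i]
      if (tt_evaluate(tt, x) != tt_evaluate(tt, y)) { ess[i] <- TRUE; break }
    }
  }
  which(ess)
}

# oracle: canalizing depth by exhaustive recursion (try every canalizing
# variable/input pair, take the maximum peel count)
oracle_depth <- function(tt) {
  k <- tt$k
  if (k == 0L || all(tt$outputs == tt$outputs[1])) return(0L)
  best <- 0L
  for (i in seq_len(k)) for (a in 0:1) {
    fixed <- canalax:::tt_restrict(tt, i, a)
    if (all(fixed$outputs == fixed$outputs[1])) {
      rest <- canalax:::tt_restrict(tt, i, 1L - a)
      best <- max(best, 1L + oracle_depth(rest))
    }
  }
  best
}

# oracle: Spearman rho via explicit average ranks + Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# common example functions
AND2 <- truth_table(c(0, 0, 0, 1))
OR2 <- truth_table(c(0, 1, 1, 1))
XOR2 <- truth_table(c(0, 1, 1, 0))
NOT1 <- truth_table(c(1, 0))
ID1 <- truth_table(c(0, 1))

# 2-node swap network: F(x1, x2) = (x2, x1)
swap_network <- function() {
  boolean_network(list(ID1, ID1), list(2L, 1L), c("A", "B"))
}

identity_network <- function(n) {
  boolean_network(replicate(n, ID1, simplify = FALSE),
                  as.list(seq_len(n)), paste0("x", seq_len(n)))
}
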
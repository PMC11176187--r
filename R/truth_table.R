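#' Boolean functions as truth tables
#'
#' A `truth_table` stores a Boolean function of `k` named inputs as the vector
#' of its `2^k` output bits. The input tuple `(x_1, ..., x_k)` maps to the
#' 0-based row index `sum(x_i * 2^(k - i))`, i.e. `x_1` is the most
#' significant bit; `outputs[index + 1]` is the function value. This index
#' convention is used consistently by the serializers, the multilinear
#' extension and the canalization machinery.
#'
#' @param outputs vector of `2^k` values coercible to bits (0/1 or logical),
#'   row-ordered by the index convention above.
#' @param variable_names optional character vector of `k` input labels.
#' @return An object of class `truth_table` with fields `k`, `outputs`
#'   (integer 0/1 of length `2^k`) and `variable_names`.
#' @examples
#' tt_and <- truth_table(c(0, 0, 0, 1))   # x1 AND x2
#' tt_evaluate(tt_and, c(1, 1))
#' @export
truth_table <- function(outputs, variable_names = NULL) {
  outputs <- as.integer(outputs)
  if (length(outputs) < 1 || bitwAnd(length(outputs), length(outputs) - 1L) != 0L)
    stop("`outputs` must have length 2^k for some integer k >= 0")
  if (!all(outputs %in% c(0L, 1L))) stop("`outputs` entries must be 0 or 1")
  k <- as.integer(round(log2(length(outputs))))
  if (!is.null(variable_names)) {
    variable_names <- as.character(variable_names)
    if (length(variable_names) != k)
      stop("`variable_names` must have length k = ", k)
  }
  structure(list(k = k, outputs = outputs, variable_names = variable_names),
            class = "truth_table")
}

#' @export
print.truth_table <- function(x, ...) {
  cat("Boolean function on", x$k, "input(s)\n")
  if (!is.null(x$variable_names))
    cat("variables:", paste(x$variable_names, collapse = ", "), "\n")
  cat("outputs:", paste(x$outputs, collapse = ""), "\n")
  invisible(x)
}

## 0-based row index of a bit tuple (x1 most significant)
tt_index <- function(x) {
  k <- length(x)
  if (k == 0L) return(0L)
  as.integer(sum(as.integer(x) * 2^((k - 1L):0L)))
}

## matrix (rows = bit tuples) -> 0-based indices, vectorized
tt_index_matrix <- function(X) {
  k <- ncol(X)
  if (k == 0L) return(rep(0L, nrow(X)))
  as.integer(X %*% 2^((k - 1L):0L))
}

## all 2^k input tuples in row-index order (matrix 2^k x k)
tt_inputs <- function(k) {
  if (k == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  v <- 0:(2^k - 1L)
  vapply(seq_len(k), function(i) bitwAnd(v %/% 2^(k - i), 1L), integer(2^k))
}

#' Evaluate a truth table at one input tuple
#'
#' @param tt a [truth_table()].
#' @param x bit vector of length `tt$k`.
#' @return The output bit (integer 0/1).
#' @export
tt_evaluate <- function(tt, x) {
  stopifnot(inherits(tt, "truth_table"))
  if (length(x) != tt$k)
    stop("input has length ", length(x), " but the function has k = ", tt$k)
  tt$outputs[tt_index(x) + 1L]
}

#' Essential variables of a Boolean function
#'
#' Input `i` is essential if flipping coordinate `i` changes the output for at
#' least one assignment of the other inputs; the wiring diagram of a network
#' keeps only essential dependencies.
#'
#' @param tt a [truth_table()].
#' @return Integer vector of essential variable indices (possibly empty).
#' @export
essential_variables <- function(tt) {
  stopifnot(inherits(tt, "truth_table"))
  k <- tt$k
  if (k == 0L) return(integer(0))
  v <- 0:(2^k - 1L)
  ess <- logical(k)
  for (i in seq_len(k)) {
    b <- 2^(k - i)
    lo <- v[bitwAnd(v, b) == 0L]
    ess[i] <- any(tt$outputs[lo + 1L] != tt$outputs[lo + b + 1L])
  }
  which(ess)
}

#' Restrict a truth table to its essential variables
#'
#' Returns a table of arity `k' = `number of essential inputs that agrees with
#' `tt` on every input (the dropped coordinates are irrelevant). Constant
#' functions reduce to `k' = 0`. The operation is idempotent and preserves the
#' output bias.
#'
#' @param tt a [truth_table()].
#' @return A [truth_table()] on the essential variables, with an integer
#'   attribute `"essential"` giving their original indices.
#' @export
reduce_to_essential <- function(tt) {
  stopifnot(inherits(tt, "truth_table"))
  ess <- essential_variables(tt)
  kp <- length(ess)
  X <- matrix(0L, nrow = 2^kp, ncol = tt$k)
  X[, ess] <- tt_inputs(kp)
  out <- tt$outputs[tt_index_matrix(X) + 1L]
  res <- truth_table(out,
                     variable_names = if (!is.null(tt$variable_names))
                       tt$variable_names[ess] else NULL)
  attr(res, "essential") <- ess
  res
}

#' Output bias of a Boolean function
#'
#' The bias `p` is the fraction of ones in the truth table. The absolute bias
#' is reported on both scales in use: `2 * abs(0.5 - p)` and
#' `1 - 4 p (1 - p)`; both are 0 exactly for balanced functions.
#'
#' @param tt a [truth_table()].
#' @return A one-row tibble with columns `p`, `abs_bias_linear`,
#'   `abs_bias_quadratic`, `ones_count`.
#' @export
function_bias <- function(tt) {
  stopifnot(inherits(tt, "truth_table"))
  q <- sum(tt$outputs)
  p <- q / length(tt$outputs)
  tibble::tibble(p = p,
                 abs_bias_linear = 2 * abs(0.5 - p),
                 abs_bias_quadratic = 1 - 4 * p * (1 - p),
                 ones_count = as.integer(q))
}

## fast scalar bias
tt_p <- function(tt) mean(tt$outputs)

#' Average sensitivity of a Boolean function
#'
#' The sum over inputs of the probability (under a uniform input) that
#' flipping that single bit changes the output. A random function with `k`
#' inputs and bias `p` has expectation `2 k p (1 - p)`; nested canalizing
#' functions have expectation 1. The network mean of this quantity is the
#' Derrida coefficient.
#'
#' @param tt a [truth_table()].
#' @return A non-negative number in `[0, k]`.
#' @export
average_sensitivity <- function(tt) {
  stopifnot(inherits(tt, "truth_table"))
  k <- tt$k
  if (k == 0L) return(0)
  v <- 0:(2^k - 1L)
  s <- 0
  for (i in seq_len(k)) {
    b <- 2^(k - i)
    lo <- v[bitwAnd(v, b) == 0L]
    s <- s + 2 * sum(tt$outputs[lo + 1L] != tt$outputs[lo + b + 1L]) / 2^k
  }
  s
}

#' Random Boolean functions
#'
#' `random_function()` draws each of the `2^k` outputs independently as a
#' Bernoulli(`p`) bit. `random_function_exact_ones()` places exactly `q` ones
#' on a uniformly chosen size-`q` subset of the input space.
#' `random_nondegenerate_function()` rejection-samples `random_function()`
#' until every variable is essential. All generators use R's global RNG;
#' seed with [set.seed()] for reproducibility.
#'
#' @param k number of inputs (`k >= 0`).
#' @param p probability that an output bit is 1, in `[0, 1]`.
#' @param q exact number of ones, `0 <= q <= 2^k`.
#' @param max_tries rejection cap before a deterministic error.
#' @param variable_names optional input labels.
#' @return A [truth_table()].
#' @export
random_function <- function(k, p = 0.5, variable_names = NULL) {
  stopifnot(k >= 0)
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1)
    stop("`p` must be a probability in [0, 1]")
  truth_table(stats::rbinom(2^k, 1L, p), variable_names = variable_names)
}

#' @rdname random_function
#' @export
random_function_exact_ones <- function(k, q, variable_names = NULL) {
  stopifnot(k >= 0)
  if (q < 0 || q > 2^k) stop("`q` must satisfy 0 <= q <= 2^k")
  out <- integer(2^k)
  out[sample.int(2^k, q)] <- 1L
  truth_table(out, variable_names = variable_names)
}

#' @rdname random_function
#' @export
random_nondegenerate_function <- function(k, p = 0.5, max_tries = 1e5,
                                          variable_names = NULL) {
  stopifnot(k >= 1)
  if (p <= 0 || p >= 1)
    stop("a non-degenerate function requires p strictly inside (0, 1)")
  for (try in seq_len(max_tries)) {
    tt <- random_function(k, p, variable_names)
    if (length(essential_variables(tt)) == k) return(tt)
  }
  stop("rejection cap of ", max_tries,
       " reached while sampling a non-degenerate function (k = ", k, ", p = ", p, ")")
}

#' Serialize truth tables as plain text
#'
#' The format is a header line `k q` (arity and ones-count) followed by the
#' `2^k`-character output bitstring in row-index order.
#'
#' @param tt a [truth_table()].
#' @param path file path; `write_truth_table()` returns the two lines
#'   invisibly, so `path = NULL` can be used to get the text only.
#' @return `read_truth_table()` returns a [truth_table()].
#' @export
write_truth_table <- function(tt, path = NULL) {
  stopifnot(inherits(tt, "truth_table"))
  lines <- c(paste(tt$k, sum(tt$outputs)),
             paste(tt$outputs, collapse = ""))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  lines <- if (length(path) == 1 && file.exists(path)) readLines(path) else path
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  bits <- as.integer(strsplit(trimws(lines[2]), "")[[1]])
  if (length(bits) != 2^hdr[1] || sum(bits) != hdr[2])
    stop("truth-table text is inconsistent with its `k q` header")
  truth_table(bits)
}

#' Render a truth table as a logical expression
#'
#' Produces a sum-of-products expression over the given variable names (used
#' by the rule-file writer); constants render as `0` / `1`.
#'
#' @param tt a [truth_table()].
#' @param variable_names input labels; defaults to the table's own names or
#'   `x1, ..., xk`.
#' @return A single character string using `&`, `|`, `!` and parentheses.
#' @export
tt_to_expression <- function(tt, variable_names = NULL) {
  stopifnot(inherits(tt, "truth_table"))
  nm <- variable_names %||% tt$variable_names %||% paste0("x", seq_len(tt$k))
  if (tt$k == 0L || all(tt$outputs == tt$outputs[1]))
    return(as.character(tt$outputs[1]))
  X <- tt_inputs(tt$k)
  ones <- which(tt$outputs == 1L)
  terms <- vapply(ones, function(r) {
    lits <- ifelse(X[r, ] == 1L, nm, paste0("!", nm))
    paste0("(", paste(lits, collapse = " & "), ")")
  }, character(1))
  paste(terms, collapse = " | ")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
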
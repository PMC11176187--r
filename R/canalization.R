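#' Canalizing variables of a Boolean function
#'
#' A variable `x_i` canalizes `f` with input `a` and output `b` if fixing
#' `x_i = a` forces `f = b` regardless of the other inputs.
#' `canalizing_variables()` lists every such witness; `is_canalizing()` is the
#' corresponding predicate. Whether constant functions count as canalizing is
#' a convention that differs between analyses, exposed via
#' `constants_canalizing` (default `FALSE`).
#'
#' @param tt a [truth_table()].
#' @param constants_canalizing should constant functions be reported as
#'   canalizing?
#' @return `canalizing_variables()`: a tibble with columns `variable`,
#'   `input`, `output` (zero rows when none, or when `tt` is constant).
#'   `is_canalizing()`: `TRUE`/`FALSE`, with the first witness as attribute
#'   `"witness"` (list `i`, `a`, `b`) when `TRUE`.
#' @export
canalizing_variables <- function(tt) {
  stopifnot(inherits(tt, "truth_table"))
  k <- tt$k
  res <- list()
  if (k == 0L || all(tt$outputs == tt$outputs[1]))
    return(tibble::tibble(variable = integer(0), input = integer(0),
                          output = integer(0)))
  v <- 0:(2^k - 1L)
  for (i in seq_len(k)) {
    b <- 2^(k - i)
    half1 <- bitwAnd(v, b) != 0L
    for (a in 0:1) {
      slice <- tt$outputs[if (a == 1L) v[half1] + 1L else v[!half1] + 1L]
      if (all(slice == slice[1]))
        res[[length(res) + 1L]] <-
          tibble::tibble(variable = i, input = a, output = slice[1])
    }
  }
  if (length(res) == 0)
    tibble::tibble(variable = integer(0), input = integer(0), output = integer(0))
  else dplyr::bind_rows(res)
}

#' @rdname canalizing_variables
#' @export
is_canalizing <- function(tt, constants_canalizing = FALSE) {
  stopifnot(inherits(tt, "truth_table"))
  if (tt$k == 0L || all(tt$outputs == tt$outputs[1]))
    return(constants_canalizing)
  w <- canalizing_variables(tt)
  if (nrow(w) == 0) return(FALSE)
  structure(TRUE, witness = list(i = w$variable[1], a = w$input[1], b = w$output[1]))
}

## restrict f by fixing variable `i` (index into current arity) to value `val`
tt_restrict <- function(tt, i, val) {
  k <- tt$k
  v <- 0:(2^k - 1L)
  b <- 2^(k - i)
  keep <- if (val == 1L) v[bitwAnd(v, b) != 0L] else v[bitwAnd(v, b) == 0L]
  truth_table(tt$outputs[keep + 1L],
              variable_names = if (!is.null(tt$variable_names))
                tt$variable_names[-i] else NULL)
}

#' Canalizing depth and layer structure of a Boolean function
#'
#' Iteratively peels canalizing variables: at each stage all currently
#' canalizing variables form one layer (they provably share the canalized
#' output), the function is restricted to the non-canalizing inputs of that
#' layer, and the process repeats until the remainder (the core) has no
#' canalizing variable. The number of peeled variables is the canalizing
#' depth; the layer sizes `(k_1, ..., k_r)` are the layer structure of the
#' unique standard monomial form. Depth `k` means the function is nested
#' canalizing (NCF).
#'
#' Constant functions report depth 0 with an `is_constant` flag; by the
#' standard-form uniqueness argument the last layer of an NCF on `k >= 2`
#' variables always has size at least 2.
#'
#' @param tt a [truth_table()].
#' @return An object of class `canalization_report`: a list with `depth`,
#'   `layer_structure` (integer vector, `sum == depth`), `variable_order`
#'   (peel order, original indices), `canalizing_inputs`, `canalized_outputs`
#'   (per peeled variable), `core` (a [truth_table()] on the remaining
#'   variables), `core_variables` (their original indices), `is_canalizing`,
#'   `is_ncf`, `is_constant`, and `k` (the arity of `tt`).
#' @export
canalization_report <- function(tt) {
  stopifnot(inherits(tt, "truth_table"))
  k <- tt$k
  var_ids <- seq_len(k)
  g <- tt
  layers <- integer(0)
  peel <- integer(0); a_seq <- integer(0); b_seq <- integer(0)
  repeat {
    if (g$k == 0L || all(g$outputs == g$outputs[1])) break
    w <- canalizing_variables(g)
    if (nrow(w) == 0) break
    ## a variable may canalize with both inputs only when g is that literal;
    ## keep the a = 0 witness in that case
    w <- w[!duplicated(w$variable), , drop = FALSE]
    stopifnot(length(unique(w$output)) == 1 || nrow(w) == 1)
    layers <- c(layers, nrow(w))
    peel <- c(peel, var_ids[w$variable])
    a_seq <- c(a_seq, w$input)
    b_seq <- c(b_seq, w$output)
    ## restrict to x_i != a_i for all layer variables (descending local index
    ## so earlier restrictions do not shift later ones)
    for (j in order(w$variable, decreasing = TRUE))
      g <- tt_restrict(g, w$variable[j], 1L - w$input[j])
    var_ids <- var_ids[-w$variable]
  }
  is_const <- k == 0L || all(tt$outputs == tt$outputs[1])
  structure(list(k = k,
                 depth = length(peel),
                 layer_structure = layers,
                 variable_order = peel,
                 canalizing_inputs = a_seq,
                 canalized_outputs = b_seq,
                 core = g,
                 core_variables = var_ids,
                 is_canalizing = length(peel) > 0L,
                 is_ncf = k > 0L && length(peel) == k,
                 is_constant = is_const),
            class = "canalization_report")
}

#' @export
print.canalization_report <- function(x, ...) {
  cat("canalizing depth", x$depth, "of", x$k, "variable(s)")
  if (x$is_ncf) cat("  [NCF]")
  if (x$is_constant) cat("  [constant]")
  cat("\n")
  if (x$depth > 0) {
    cat("layer structure: (", paste(x$layer_structure, collapse = ","), ")\n",
        sep = "")
    cat("peel order:", paste(x$variable_order, collapse = ","),
        " inputs a:", paste(x$canalizing_inputs, collapse = ","),
        " outputs b:", paste(x$canalized_outputs, collapse = ","), "\n")
  }
  if (x$depth < x$k)
    cat("core on variables:", paste(x$core_variables, collapse = ","), "\n")
  invisible(x)
}

#' Rebuild a truth table from a canalization report
#'
#' Inverts [canalization_report()]: fills the cascade in peel order (first
#' peeled variable checked first) with the report's core on the remaining
#' coordinates. Round-tripping any function through its report reproduces the
#' truth table exactly.
#'
#' @param report a `canalization_report`.
#' @return A [truth_table()] on `report$k` variables.
#' @export
reconstruct_from_report <- function(report) {
  build_cascade(report$k, report$variable_order, report$canalizing_inputs,
                report$canalized_outputs, report$core, report$core_variables)
}

## cascade fill: peeled vars `order` (original indices) with inputs a /
## outputs b, core truth table on `core_vars`
build_cascade <- function(k, order, a, b, core, core_vars) {
  X <- tt_inputs(k)
  out <- integer(2^k)
  ## core values where no canalizing condition fires
  if (core$k > 0L) {
    out <- core$outputs[tt_index_matrix(X[, core_vars, drop = FALSE]) + 1L]
  } else {
    out <- rep(core$outputs[1], 2^k)
  }
  for (j in rev(seq_along(order)))
    out[X[, order[j]] == a[j]] <- b[j]
  truth_table(out)
}

#' Is a function nested canalizing?
#'
#' `TRUE` when the canalizing depth equals the arity `k`, i.e. every variable
#' is eventually canalizing. A function with non-essential inputs is not an
#' NCF in its ambient arity (apply [reduce_to_essential()] first for the
#' reduced notion); exactly 8 of the 16 two-input functions are NCFs.
#'
#' @param tt a [truth_table()].
#' @return `TRUE`/`FALSE`.
#' @export
is_nested_canalizing <- function(tt) {
  stopifnot(inherits(tt, "truth_table"))
  tt$k > 0L && canalization_report(tt)$depth == tt$k
}

#' Random non-canalizing core functions
#'
#' Rejection-samples a Boolean function on `m` variables that is
#' non-canalizing and depends on all `m` variables, optionally with an exact
#' ones-count. No such function exists for `m = 1` (both non-degenerate
#' 1-input functions are canalizing); for `m = 2` only the parity functions
#' qualify, forcing `ones_count = 2`.
#'
#' @param m number of core variables (`m = 0` or `m >= 2`).
#' @param ones_count optional exact number of ones.
#' @param max_tries rejection cap.
#' @return A [truth_table()].
#' @export
random_noncanalizing_core <- function(m, ones_count = NULL, max_tries = 1e5) {
  if (m == 1) stop("no non-degenerate non-canalizing function on 1 variable exists")
  if (m == 0) {
    out <- if (is.null(ones_count)) sample(0:1, 1) else as.integer(ones_count > 0)
    return(truth_table(out))
  }
  if (!is.null(ones_count)) {
    if (ones_count <= 0 || ones_count >= 2^m)
      stop("ones_count = ", ones_count, " is infeasible for a non-canalizing ",
           "function on ", m, " variables")
    if (m == 2 && ones_count != 2)
      stop("the only non-canalizing non-degenerate 2-input functions are the ",
           "parity functions (ones_count = 2)")
  }
  for (try in seq_len(max_tries)) {
    tt <- if (is.null(ones_count)) random_function(m, 0.5)
          else random_function_exact_ones(m, ones_count)
    if (length(essential_variables(tt)) == m && !isTRUE(is_canalizing(tt)))
      return(tt)
  }
  stop("rejection cap of ", max_tries, " reached while sampling a ",
       "non-canalizing core (m = ", m, ", ones_count = ",
       ones_count %||% "free", ")")
}

check_depth_feasible <- function(k, d) {
  if (d < 0 || d > k) stop("depth d must lie in {0, ..., k}")
  if (k >= 1 && d == k - 1)
    stop("canalizing depth k - 1 = ", d, " is impossible: a 1-variable core ",
         "is always canalizing")
}

#' Random functions with prescribed canalization
#'
#' `random_with_exact_depth()` draws a function whose canalizing depth is
#' exactly `d`: a uniformly random arrangement of `d` canalizing variables
#' with uniform canalizing inputs `a_i` and canalized outputs `b_i`, completed
#' by a non-canalizing, fully essential core (depth `k - 1` is
#' mathematically impossible and is rejected loudly rather than bumped).
#' `random_with_min_depth()` allows the core to be canalizing, so the realized
#' depth may exceed `d`; `d = 0` reduces to an unrestricted non-degenerate
#' function. `random_with_exact_depth_and_bias()` additionally fixes the
#' ones-count `q` by reusing a reference function's canalized output sequence
#' and core ones-count (the null-model-3 construction).
#' `random_ncf_with_layers()` draws a nested canalizing function with a
#' prescribed layer structure: canalized outputs are constant within a layer
#' and alternate between consecutive layers, variable order and canalizing
#' inputs are uniform.
#'
#' @param k arity.
#' @param d (minimal) canalizing depth requested.
#' @param q exact ones-count of the result (must be consistent with
#'   `b_sequence` and `core_ones`).
#' @param b_sequence canalized outputs `b_1, ..., b_d` taken from a reference
#'   function's [canalization_report()].
#' @param core_ones ones-count of the reference core.
#' @param layer_structure integer vector `(k_1, ..., k_r)` with positive
#'   entries summing to `k`; the last layer must have size `>= 2` when
#'   `k >= 2`.
#' @param max_tries rejection cap for the core sampler.
#' @return A [truth_table()].
#' @export
random_with_exact_depth <- function(k, d, max_tries = 1e5) {
  stopifnot(k >= 1)
  check_depth_feasible(k, d)
  if (d == 0) return(random_noncanalizing_core(k, max_tries = max_tries))
  sigma <- sample.int(k)
  a <- sample(0:1, d, replace = TRUE)
  b <- sample(0:1, d, replace = TRUE)
  core <- if (d == k) truth_table(1L - b[d])
          else random_noncanalizing_core(k - d, max_tries = max_tries)
  build_cascade(k, sigma[seq_len(d)], a, b, core, sigma[-seq_len(d)])
}

#' @rdname random_with_exact_depth
#' @export
random_with_min_depth <- function(k, d, max_tries = 1e5) {
  stopifnot(k >= 1)
  if (d < 0 || d > k) stop("minimal depth d must lie in {0, ..., k}")
  if (d == 0) return(random_nondegenerate_function(k, 0.5, max_tries))
  if (d == k) return(random_with_exact_depth(k, k))
  sigma <- sample.int(k)
  a <- sample(0:1, d, replace = TRUE)
  b <- sample(0:1, d, replace = TRUE)
  ## core may be canalizing (so realized depth >= d) but is non-degenerate,
  ## hence non-constant, which keeps every cascade variable essential
  core <- random_nondegenerate_function(k - d, 0.5, max_tries)
  build_cascade(k, sigma[seq_len(d)], a, b, core, sigma[-seq_len(d)])
}

#' @rdname random_with_exact_depth
#' @export
random_with_exact_depth_and_bias <- function(k, d, q, b_sequence, core_ones,
                                             max_tries = 1e5) {
  stopifnot(k >= 1, length(b_sequence) == d)
  check_depth_feasible(k, d)
  if (d == 0) {
    if (q != core_ones) stop("q and core_ones disagree for depth 0")
    return(random_noncanalizing_core(k, ones_count = q, max_tries = max_tries))
  }
  ## ones contributed by the cascade: b_i fires on 2^(k-i) inputs
  cascade_ones <- sum(b_sequence * 2^(k - seq_len(d)))
  if (d == k) {
    forced_core <- 1L - b_sequence[d]
    if (q != cascade_ones + forced_core)
      stop("requested q = ", q, " is infeasible for an NCF with this ",
           "canalized output sequence (it forces q = ",
           cascade_ones + forced_core, ")")
    core <- truth_table(forced_core)
  } else {
    if (q != cascade_ones + core_ones)
      stop("requested q = ", q, " is inconsistent with the canalized outputs ",
           "and core ones-count (they force q = ", cascade_ones + core_ones, ")")
    core <- random_noncanalizing_core(k - d, ones_count = core_ones,
                                      max_tries = max_tries)
  }
  sigma <- sample.int(k)
  a <- sample(0:1, d, replace = TRUE)
  build_cascade(k, sigma[seq_len(d)], a, b_sequence, core, sigma[-seq_len(d)])
}

#' @rdname random_with_exact_depth
#' @export
random_ncf_with_layers <- function(k, layer_structure) {
  stopifnot(k >= 1)
  ls <- as.integer(layer_structure)
  if (any(ls < 1) || sum(ls) != k)
    stop("layer structure must have positive entries summing to k")
  if (k >= 2 && ls[length(ls)] < 2)
    stop("the last layer of an NCF on k >= 2 variables must have size >= 2 ",
         "(standard monomial form uniqueness)")
  b1 <- sample(0:1, 1)
  b <- unlist(lapply(seq_along(ls), function(i)
    rep(if (i %% 2 == 1) b1 else 1L - b1, ls[i])))
  sigma <- sample.int(k)
  a <- sample(0:1, k, replace = TRUE)
  core <- truth_table(1L - b[k])
  build_cascade(k, sigma, a, b, core, integer(0))
}

#' Serialize a canalization report to JSON
#'
#' @param report a `canalization_report`.
#' @return A JSON string (depth, layer structure, peel order, inputs,
#'   outputs, core bitstring).
#' @export
report_to_json <- function(report) {
  jsonlite::toJSON(list(
    k = report$k, depth = report$depth,
    layer_structure = report$layer_structure,
    variable_order = report$variable_order,
    canalizing_inputs = report$canalizing_inputs,
    canalized_outputs = report$canalized_outputs,
    core = paste(report$core$outputs, collapse = ""),
    is_ncf = report$is_ncf, is_constant = report$is_constant),
    auto_unbox = TRUE)
}
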
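#' Multilinear (square-free) extension of a Boolean function
#'
#' Every Boolean function `f` on `{0,1}^k` has a unique multilinear
#' polynomial extension to `[0,1]^k`: the probabilistic interpolant
#' `sum over f(x)=1 of prod_i p_i^{x_i} (1-p_i)^{1-x_i}`, which agrees with
#' `f` at every hypercube vertex. The polynomial is stored in the basis of
#' centered monomials `prod_{i in A} (x_i - 1/2)` — the Taylor basis at the
#' expansion point `p = (1/2, ..., 1/2)` — so the empty-set coefficient is
#' the output bias of `f` and order-`m` truncation simply drops all subsets
#' with more than `m` elements. Because the polynomial is square-free, the
#' Taylor expansion is exact at order `k` (multi-index factorials are 1).
#'
#' Coefficients are computed by a Walsh-Hadamard transform: the coefficient
#' of subset `A` is `2^{|A|-k} sum_x f(x) prod_{i in A} (2 x_i - 1)`.
#'
#' @param tt a [truth_table()].
#' @return An object of class `multilinear_poly`: list with `k`, `coef`
#'   (numeric of length `2^k`, indexed by subset mask + 1, where bit
#'   `2^(k-i)` of the mask marks variable `i`, matching the truth-table row
#'   convention), `degree` (attr-like field: max retained subset size) and
#'   `variable_names`.
#' @examples
#' p <- continuous_extension(truth_table(c(0, 0, 0, 1)))  # AND
#' poly_evaluate(p, c(0.5, 0.5))  # = bias 0.25
#' @export
continuous_extension <- function(tt) {
  stopifnot(inherits(tt, "truth_table"))
  k <- tt$k
  g <- as.numeric(tt$outputs)
  h <- 1L
  n <- length(g)
  while (h < n) {  # in-place Walsh-Hadamard butterfly
    for (i in seq(1L, n, by = 2L * h)) {
      lo <- i:(i + h - 1L); hi <- lo + h
      a <- g[lo]; b <- g[hi]
      g[lo] <- a + b
      g[hi] <- b - a
    }
    h <- 2L * h
  }
  sz <- mask_sizes(k)
  structure(list(k = k, coef = g / n * 2^sz, degree = k,
                 variable_names = tt$variable_names),
            class = "multilinear_poly")
}

## number of set bits for each mask 0..2^k-1 (memoized per k)
mask_sizes <- local({
  cache <- list()
  function(k) {
    key <- as.character(k)
    if (is.null(cache[[key]])) {
      if (k == 0L) sz <- 0L
      else {
        sz <- integer(2^k)
        for (i in seq_len(k)) sz <- sz + bitwAnd((0:(2^k - 1L)) %/% 2^(i - 1L), 1L)
      }
      cache[[key]] <<- sz
    }
    cache[[key]]
  }
})

#' @export
print.multilinear_poly <- function(x, ...) {
  nz <- sum(x$coef != 0)
  cat("multilinear polynomial on", x$k, "variable(s), centered at 1/2\n")
  cat(nz, "non-zero coefficient(s), retained order <=", x$degree, "\n")
  invisible(x)
}

#' Taylor truncation of a multilinear polynomial
#'
#' Drops every centered monomial involving more than `m` variables. `m = 0`
#' leaves the constant term (the output bias); `m = k` returns the polynomial
#' unchanged. Truncation is nested: increasing `m` only adds coefficients.
#'
#' @param poly a [continuous_extension()].
#' @param m retained order, `0 <= m <= k`.
#' @return A `multilinear_poly` with the same coefficient layout.
#' @export
taylor_truncation <- function(poly, m) {
  stopifnot(inherits(poly, "multilinear_poly"))
  if (m < 0 || m > poly$k) stop("order m must lie in {0, ..., k}")
  coef <- poly$coef
  coef[mask_sizes(poly$k) > m] <- 0
  structure(list(k = poly$k, coef = coef, degree = as.integer(m),
                 variable_names = poly$variable_names),
            class = "multilinear_poly")
}

#' Evaluate a multilinear polynomial
#'
#' @param poly a `multilinear_poly`.
#' @param x numeric vector in `[0,1]^k` (a single point).
#' @return The polynomial value (not clipped).
#' @export
poly_evaluate <- function(poly, x) {
  stopifnot(inherits(poly, "multilinear_poly"), length(x) == poly$k)
  drop(poly_evaluate_matrix(poly, matrix(x, nrow = 1)))
}

## rows of X are points; returns numeric vector. Products over subsets are
## built by doubling from variable k (mask bit 1) up to variable 1.
poly_evaluate_matrix <- function(poly, X) {
  k <- poly$k
  if (k == 0L) return(rep(poly$coef[1], nrow(X)))
  P <- matrix(1.0, nrow(X), 1L)
  for (i in k:1) {
    z <- X[, i] - 0.5
    P <- cbind(P, P * z)
  }
  drop(P %*% poly$coef)
}
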
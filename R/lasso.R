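#' Standardize predictor columns
#'
#' Centers each numeric column to mean 0 and scales to standard deviation 1,
#' the preprocessing required by [lasso_path()].
#'
#' @param data a data frame of numeric columns.
#' @return A tibble of the standardized columns.
#' @export
standardize_columns <- function(data) {
  tibble::as_tibble(lapply(data, function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("cannot standardize a constant column")
    (v - mean(v)) / s
  }))
}

#' LASSO regularization path for approximability predictors
#'
#' Solves, for a decreasing grid of penalties `alpha`, the L1-penalized
#' least-squares problem
#' `min_beta (1/N) ||y - X beta||_2^2 + alpha ||beta||_1`
#' by cyclic coordinate descent with warm starts (note the `1/N` residual
#' scaling, not `1/(2N)`: penalties here are twice the `lambda` of solvers
#' that use the half scaling). Both `y` and the columns of `x` must be
#' standardized beforehand (mean 0, sd 1; see [standardize_columns()]) —
#' unstandardized input is an error, not silently rescaled. The path starts
#' at the smallest all-zero penalty `alpha_max = 2 max_j |x_j' y| / N` and is
#' followed down until `n_nonzero_stop` predictors have entered the model
#' (or the grid is exhausted).
#'
#' @param x standardized predictor matrix or data frame (`N x d`).
#' @param y standardized response vector.
#' @param alpha optional decreasing penalty grid; default log-spaced over
#'   three decades below `alpha_max`, extended as needed.
#' @param n_nonzero_stop stop after the first alpha with this many non-zero
#'   coefficients (`Inf` to follow the full grid).
#' @param n_alpha grid resolution per three decades.
#' @param tol,max_iter coordinate-descent convergence controls.
#' @return An object of class `lasso_path`: list with `alpha` (the grid
#'   actually followed), `beta` (matrix `d x length(alpha)`), `path` (tidy
#'   tibble: `alpha`, `term`, `estimate`, `n_nonzero`), `alpha_stop`,
#'   `n_nonzero_stop`.
#' @export
lasso_path <- function(x, y, alpha = NULL, n_nonzero_stop = 9,
                       n_alpha = 100, tol = 1e-12, max_iter = 1e5) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  N <- nrow(X); d <- ncol(X)
  stopifnot(length(y) == N, N >= 2)
  mu <- colMeans(X); sds <- apply(X, 2, stats::sd)
  if (max(abs(mu)) > 1e-8 || max(abs(sds - 1)) > 1e-6 ||
      abs(mean(y)) > 1e-8 || abs(stats::sd(y) - 1) > 1e-6)
    stop("`x` columns and `y` must be standardized to mean 0, sd 1 ",
         "(see standardize_columns()); refusing to rescale silently")
  terms <- colnames(X) %||% paste0("x", seq_len(d))
  alpha_max <- 2 * max(abs(crossprod(X, y))) / N
  grid <- alpha %||% exp(seq(log(alpha_max), log(alpha_max * 1e-3),
                             length.out = n_alpha))
  grid <- sort(grid, decreasing = TRUE)
  z <- colSums(X^2)                      # = N - 1 for standardized columns
  beta <- numeric(d)
  betas <- matrix(NA_real_, d, 0)
  alphas <- numeric(0)
  repeat {
    for (a in grid) {
      beta <- coordinate_descent(X, y, beta, a, z, tol, max_iter)
      betas <- cbind(betas, beta)
      alphas <- c(alphas, a)
      if (sum(beta != 0) >= n_nonzero_stop) break
    }
    if (sum(beta != 0) >= n_nonzero_stop || is.null(alpha) == FALSE ||
        min(grid) < alpha_max * 1e-12) break
    grid <- exp(seq(log(min(grid)) - log(10) / (n_alpha / 3),
                    log(min(grid)) - 3 * log(10), length.out = n_alpha))
  }
  rownames(betas) <- terms
  nnz <- colSums(betas != 0)
  path <- tibble::tibble(
    alpha = rep(alphas, each = d),
    term = rep(terms, length(alphas)),
    estimate = as.vector(betas),
    n_nonzero = rep(nnz, each = d))
  structure(list(alpha = alphas, beta = betas, path = path,
                 alpha_stop = if (sum(beta != 0) >= n_nonzero_stop)
                   alphas[length(alphas)] else NA_real_,
                 n_nonzero_stop = n_nonzero_stop,
                 terms = terms),
            class = "lasso_path")
}

## cyclic coordinate descent for (1/N)||y - X b||^2 + alpha ||b||_1
coordinate_descent <- function(X, y, beta, alpha, z, tol, max_iter) {
  N <- nrow(X)
  r <- y - X %*% beta
  for (it in seq_len(max_iter)) {
    delta_max <- 0
    for (j in seq_along(beta)) {
      bj <- beta[j]
      rho <- (2 / N) * sum(X[, j] * r) + (2 / N) * z[j] * bj
      bnew <- soft_threshold(rho, alpha) / ((2 / N) * z[j])
      if (bnew != bj) {
        r <- r - X[, j] * (bnew - bj)
        beta[j] <- bnew
        delta_max <- max(delta_max, abs(bnew - bj))
      }
    }
    if (delta_max < tol) break
  }
  beta
}

soft_threshold <- function(x, a) sign(x) * max(abs(x) - a, 0)

#' Subgradient optimality check for a LASSO solution
#'
#' Verifies the Karush-Kuhn-Tucker conditions of the `(1/N)`-scaled L1
#' objective at every reported penalty: for active coefficients the gradient
#' balances `alpha * sign(beta_j)` exactly; for inactive ones it is bounded
#' by `alpha`.
#'
#' @param fit a [lasso_path()].
#' @param x,y the standardized data the path was fit on.
#' @param tol violation tolerance.
#' @return Maximum KKT violation across the path (invisibly `TRUE`-worthy
#'   when below `tol`).
#' @export
lasso_kkt_violation <- function(fit, x, y, tol = 1e-8) {
  X <- as.matrix(x); y <- as.numeric(y); N <- nrow(X)
  worst <- 0
  for (s in seq_along(fit$alpha)) {
    beta <- fit$beta[, s]
    a <- fit$alpha[s]
    g <- -(2 / N) * crossprod(X, y - X %*% beta)   # d/dbeta of the fit term
    active <- beta != 0
    if (any(active))
      worst <- max(worst, max(abs(g[active] + a * sign(beta[active]))))
    if (any(!active))
      worst <- max(worst, max(pmax(abs(g[!active]) - a, 0)))
  }
  worst
}

#' @export
print.lasso_path <- function(x, ...) {
  cat("LASSO path over", length(x$alpha), "penalties; stop rule:",
      x$n_nonzero_stop, "non-zero coefficients\n")
  if (!is.na(x$alpha_stop))
    cat("reached at alpha =", format(x$alpha_stop, digits = 4), "\n")
  invisible(x)
}
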
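#' Structural predictors of network approximability
#'
#' Summarizes a Boolean network by the rule- and wiring-level properties used
#' to screen for correlates of approximability: mean essential in-degree
#' `<K>`, mean bias product `<p(1-p)>`, mean absolute bias `<2|0.5-p|>`, the
#' covariance between `p(1-p)` and in-degree across rules, the mean
#' normalized canalizing depth (depth/k over rules with `k >= 1`), the
#' proportion of nested canalizing rules, and motif counts on the essential
#' wiring diagram: feed-forward loops (ordered triples `i->j`, `j->k`,
#' `i->k` of distinct nodes) and simple directed cycles of length 3 and 4.
#' Self-loops are ignored in motif counts. All rule statistics are computed
#' on essential-reduced rules.
#'
#' @param net a [boolean_network()].
#' @return A one-row tibble with columns `n`, `mean_degree`,
#'   `mean_bias_product`, `mean_abs_bias`, `cov_biasproduct_degree`,
#'   `mean_norm_canalizing_depth`, `prop_ncf`, `n_ffl`, `n_3loops`,
#'   `n_4loops`.
#' @export
structural_predictors <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  red <- lapply(net$rules, reduce_to_essential)
  k <- vapply(red, function(r) r$k, integer(1))
  p <- vapply(red, tt_p, numeric(1))
  depth <- vapply(red, function(r) canalization_report(r)$depth, integer(1))
  ncf <- vapply(red, function(r) r$k > 0L && canalization_report(r)$depth == r$k,
                logical(1))
  pq <- p * (1 - p)
  wd <- wiring_diagram(net)
  A <- wiring_adjacency(wd)
  diag(A) <- 0L
  cyc <- count_simple_cycles(A, max_len = 4)
  tibble::tibble(
    n = net$n,
    mean_degree = mean(k),
    mean_bias_product = mean(pq),
    mean_abs_bias = mean(2 * abs(0.5 - p)),
    cov_biasproduct_degree = if (net$n > 1) stats::cov(pq, k) else NA_real_,
    mean_norm_canalizing_depth = if (any(k >= 1))
      mean((depth / k)[k >= 1]) else NA_real_,
    prop_ncf = mean(ncf),
    n_ffl = sum((A %*% A) * A),
    n_3loops = cyc[["3"]],
    n_4loops = cyc[["4"]])
}

## counts of simple directed cycles of each length 2..max_len, by DFS over
## paths whose smallest node is the start (each cycle counted once)
count_simple_cycles <- function(A, max_len = 4) {
  n <- nrow(A)
  counts <- stats::setNames(numeric(max_len - 1L), as.character(2:max_len))
  adj <- lapply(seq_len(n), function(i) which(A[i, ] == 1L))
  dfs <- function(start, v, depth, visited) {
    for (w in adj[[v]]) {
      if (w == start && depth >= 2)
        counts[[as.character(depth)]] <<- counts[[as.character(depth)]] + 1
      else if (depth < max_len && w > start && !visited[w]) {
        visited[w] <- TRUE
        dfs(start, w, depth + 1L, visited)
        visited[w] <- FALSE
      }
    }
  }
  for (s in seq_len(n)) {
    visited <- logical(n)
    dfs(s, s, 1L, visited)
  }
  counts
}

#' Dynamical predictors of network approximability
#'
#' Attractor-landscape metrics ([attractor_metrics()]) plus the network mean
#' average sensitivity, from either exact state-space enumeration or
#' trajectory sampling.
#'
#' @param net a [boolean_network()].
#' @param mode `"sampled"` (default) or `"exact"`.
#' @param n_ic initial conditions for sampled mode.
#' @param max_n cap for exact mode.
#' @return A one-row tibble: `mean_avg_sensitivity`, `n_attractors`,
#'   `mean_length`, `prop_steady`, `mean_length_weighted`,
#'   `prop_steady_weighted`, `basin_entropy`, `mode`.
#' @export
dynamical_predictors <- function(net, mode = c("sampled", "exact"),
                                 n_ic = 1000, max_n = 20) {
  mode <- match.arg(mode)
  aset <- if (mode == "exact") exact_attractors(net, max_n = max_n)
          else sampled_attractors(net, n_ic = n_ic, max_n = max_n)
  dplyr::bind_cols(
    tibble::tibble(mean_avg_sensitivity = network_average_sensitivity(net)),
    attractor_metrics(aset))
}

#' Spearman correlation screen
#'
#' Rank correlations (average ranks for ties) between all numeric columns of
#' a predictor table, or between `columns` and `targets` when given.
#' Constant columns yield `NA` with a warning rather than a silent zero.
#'
#' @param data a data frame of numeric columns (`>= 3` rows).
#' @param columns,targets optional character vectors of column names; default
#'   all numeric columns.
#' @return A correlation matrix (rows = `columns`, cols = `targets`),
#'   symmetric with unit diagonal in the default all-vs-all case.
#' @export
spearman_screen <- function(data, columns = NULL, targets = NULL) {
  num <- names(data)[vapply(data, is.numeric, logical(1))]
  if (nrow(data) < 3) stop("need at least 3 rows for a rank correlation")
  columns <- columns %||% num
  targets <- targets %||% columns
  stopifnot(all(c(columns, targets) %in% num))
  const <- vapply(unique(c(columns, targets)),
                  function(cl) stats::sd(data[[cl]]) == 0, logical(1))
  if (any(const))
    warning("constant column(s): ",
            paste(names(const)[const], collapse = ", "),
            "; their correlations are undefined (NA)")
  suppressWarnings(
    stats::cor(as.matrix(data[columns]), as.matrix(data[targets]),
               method = "spearman"))
}

#' Paired two-sided Wilcoxon signed-rank comparison
#'
#' Compares paired per-network values (e.g. the MAE of each reference network
#' against its null model). Zero differences are dropped following the
#' classical signed-rank convention; if all differences are zero the test is
#' degenerate and flagged instead of computed.
#'
#' @param x,y equal-length paired numeric vectors.
#' @return An object of class `paired_comparison`: list with `statistic`,
#'   `p_value`, `n`, `n_zero_diff`, `degenerate`, `median_difference`.
#' @export
paired_comparison <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  nz <- sum(d == 0)
  res <- if (all(d == 0)) {
    list(statistic = NA_real_, p_value = NA_real_, degenerate = TRUE)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              alternative = "two.sided"))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         degenerate = FALSE)
  }
  structure(c(res, list(n = length(x), n_zero_diff = nz,
                        median_difference = stats::median(d))),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat("paired Wilcoxon signed-rank: degenerate (all", x$n,
        "differences are zero)\n")
  } else {
    cat("paired Wilcoxon signed-rank: V =", x$statistic,
        ", p =", format.pval(x$p_value), " (n =", x$n, ",",
        x$n_zero_diff, "zero differences dropped)\n")
  }
  invisible(x)
}
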
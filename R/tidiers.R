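#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a LASSO path
#'
#' @param x a [lasso_path()].
#' @param ... unused.
#' @return A tibble with one row per penalty and term: `alpha`, `term`,
#'   `estimate`, `n_nonzero`.
#' @export
tidy.lasso_path <- function(x, ...) x$path

#' @rdname tidy.lasso_path
#' @return `glance()`: a one-row tibble with `alpha_max`, `alpha_stop`,
#'   `n_alpha`, `n_terms`, `n_nonzero_final`.
#' @export
glance.lasso_path <- function(x, ...) {
  tibble::tibble(alpha_max = x$alpha[1],
                 alpha_stop = x$alpha_stop,
                 n_alpha = length(x$alpha),
                 n_terms = length(x$terms),
                 n_nonzero_final = sum(x$beta[, ncol(x$beta)] != 0))
}

#' Tidy a paired Wilcoxon comparison
#'
#' @param x a [paired_comparison()].
#' @param ... unused.
#' @return A one-row tibble: `statistic`, `p_value`, `n`, `n_zero_diff`,
#'   `median_difference`, `degenerate`.
#' @export
tidy.paired_comparison <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value, n = x$n,
                 n_zero_diff = x$n_zero_diff,
                 median_difference = x$median_difference,
                 degenerate = x$degenerate)
}

#' Tidy an attractor set
#'
#' @param x an [exact_attractors()] / [sampled_attractors()] result.
#' @param ... unused.
#' @return A tibble with one row per attractor: `attractor`, `length`,
#'   `basin_count`, `basin_fraction`, `states` (list-column of bitstrings).
#' @export
tidy.attractor_set <- function(x, ...) {
  tibble::tibble(attractor = seq_len(x$n_attractors),
                 length = x$lengths,
                 basin_count = x$basin_counts,
                 basin_fraction = x$basin_counts / x$n_initial_conditions,
                 states = x$attractors)
}

#' @rdname tidy.attractor_set
#' @return `glance()`: the [attractor_metrics()] row.
#' @export
glance.attractor_set <- function(x, ...) attractor_metrics(x)

#' Tidy a canalization report
#'
#' @param x a [canalization_report()].
#' @param ... unused.
#' @return A tibble with one row per peeled variable: `position`, `variable`,
#'   `layer`, `canalizing_input`, `canalized_output`.
#' @export
tidy.canalization_report <- function(x, ...) {
  layer_of <- rep(seq_along(x$layer_structure), x$layer_structure)
  tibble::tibble(position = seq_len(x$depth),
                 variable = x$variable_order,
                 layer = layer_of,
                 canalizing_input = x$canalizing_inputs,
                 canalized_output = x$canalized_outputs)
}

#' @rdname tidy.canalization_report
#' @export
glance.canalization_report <- function(x, ...) {
  tibble::tibble(k = x$k, depth = x$depth,
                 n_layers = length(x$layer_structure),
                 layer_structure = paste(x$layer_structure, collapse = ","),
                 is_canalizing = x$is_canalizing,
                 is_ncf = x$is_ncf, is_constant = x$is_constant)
}
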
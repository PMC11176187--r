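#' Bias-degree grid of Taylor approximability (random ensembles)
#'
#' Generates `reps` strongly connected N-K Kauffman networks for each
#' combination of constant in-degree `K` and rule bias `p`, and computes the
#' mean approximation error of each network at every requested Taylor order,
#' sharing the initial states and Boolean trajectory across orders within a
#' network. Optionally also records each network's mean average sensitivity
#' and attractor metrics, which turns the grid into the dynamics-correlation
#' ensemble.
#'
#' @param K_set,p_set grids of in-degrees and biases.
#' @param reps networks per `(K, p)` cell.
#' @param orders Taylor orders to evaluate.
#' @param N network size.
#' @param n_ic,steps MAE settings (see [mean_approximation_error()]).
#' @param family rule family passed to [random_network()] (the
#'   non-degenerate variant is the published sensitivity analysis).
#' @param dynamics also compute [dynamical_predictors()] per network
#'   (`"none"`, `"sensitivity"`, or `"full"`).
#' @return A tibble of class `approx_grid` with one row per network and
#'   order: `K`, `p`, `rep`, `order`, `mae`, plus `mean_avg_sensitivity` and
#'   attractor metrics when requested.
#' @export
run_approximability_grid <- function(K_set = 2:5,
                                     p_set = seq(0.1, 0.5, by = 0.1),
                                     reps = 100, orders = 1:4, N = 15,
                                     n_ic = 1000, steps = 25,
                                     family = c("kauffman",
                                                "kauffman_nondegenerate"),
                                     dynamics = c("sensitivity", "none", "full")) {
  family <- match.arg(family)
  dynamics <- match.arg(dynamics)
  rows <- list()
  for (K in K_set) for (p in p_set) for (r in seq_len(reps)) {
    net <- random_network(N, K, family = family, p = p)
    mae <- mean_approximation_error(net, orders, n_ic = n_ic, steps = steps)
    row <- tibble::tibble(K = K, p = p, rep = r, order = orders,
                          mae = unname(mae))
    if (dynamics != "none")
      row$mean_avg_sensitivity <- network_average_sensitivity(net)
    if (dynamics == "full") {
      dp <- dynamical_predictors(net, mode = if (N <= 20) "exact" else "sampled",
                                 n_ic = n_ic)
      row <- dplyr::bind_cols(row, dp[rep(1, nrow(row)),
                                      setdiff(names(dp), "mean_avg_sensitivity")])
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("approx_grid", class(out))
  out
}

#' Canalization frequency across degree and bias (random functions)
#'
#' For each `(k, p)` cell, draws random Boolean functions with `k` inputs
#' and Bernoulli(`p`) outputs and reports how often they are canalizing or
#' nested canalizing and their mean canalizing depth. Constant functions
#' count as canalizing here (`constants_canalizing = TRUE` by default,
#' matching how these frequencies are usually tabulated; set `FALSE` for the
#' stricter convention).
#'
#' @param k_set,p_set grids of arity and bias.
#' @param n_funcs random functions per cell.
#' @param constants_canalizing convention flag for constant draws.
#' @return A tibble: `k`, `p`, `prop_canalizing`, `prop_ncf`, `mean_depth`,
#'   `mean_norm_depth`.
#' @export
run_canalization_grid <- function(k_set = 1:6,
                                  p_set = seq(0.1, 0.9, by = 0.1),
                                  n_funcs = 1000,
                                  constants_canalizing = TRUE) {
  rows <- list()
  for (k in k_set) for (p in p_set) {
    can <- logical(n_funcs); ncf <- logical(n_funcs); dep <- integer(n_funcs)
    for (i in seq_len(n_funcs)) {
      tt <- random_function(k, p)
      rp <- canalization_report(tt)
      can[i] <- if (rp$is_constant) constants_canalizing else rp$is_canalizing
      ncf[i] <- rp$is_ncf
      dep[i] <- rp$depth
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      k = k, p = p, prop_canalizing = mean(can), prop_ncf = mean(ncf),
      mean_depth = mean(dep), mean_norm_depth = mean(dep) / k)
  }
  dplyr::bind_rows(rows)
}

#' Approximability under constrained canalization (fixed-degree ensembles)
#'
#' `run_depth_experiment()` compares networks whose rules have different
#' minimal canalizing depths (depth 0 = unconstrained non-degenerate rules);
#' `run_layer_experiment()` compares networks governed entirely by NCFs with
#' different layer structures. Both use strongly connected `N`-node networks
#' of constant in-degree `K` and share initial states across orders within a
#' network.
#'
#' @param depths minimal canalizing depths to compare (depth `K - 1` is
#'   impossible and rejected by the generator).
#' @param layers list of layer-structure vectors (each summing to `K`).
#' @param reps networks per condition.
#' @param orders Taylor orders.
#' @param N,K,n_ic,steps as in [run_approximability_grid()].
#' @return A tibble with one row per network and order: the condition
#'   (`min_depth` or `layer_structure` label), `rep`, `order`, `mae`.
#' @export
run_depth_experiment <- function(depths = c(0, 1, 2, 4), reps = 100,
                                 orders = 1:4, N = 15, K = 4,
                                 n_ic = 1000, steps = 25) {
  rows <- list()
  for (d in depths) for (r in seq_len(reps)) {
    net <- random_network(N, K, family = "min_depth", min_depth = d)
    mae <- mean_approximation_error(net, orders, n_ic = n_ic, steps = steps)
    rows[[length(rows) + 1L]] <-
      tibble::tibble(min_depth = d, rep = r, order = orders, mae = unname(mae))
  }
  dplyr::bind_rows(rows)
}

#' @rdname run_depth_experiment
#' @export
run_layer_experiment <- function(layers = list(c(4), c(1, 3), c(2, 2),
                                               c(1, 1, 2)),
                                 reps = 100, orders = 1:4, N = 15, K = 4,
                                 n_ic = 1000, steps = 25) {
  rows <- list()
  for (ls in layers) for (r in seq_len(reps)) {
    net <- random_network(N, K, family = "ncf_layers", layer_structure = ls)
    mae <- mean_approximation_error(net, orders, n_ic = n_ic, steps = steps)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      layer_structure = paste(ls, collapse = ","),
      rep = r, order = orders, mae = unname(mae))
  }
  dplyr::bind_rows(rows)
}

#' Null-model comparison of approximability
#'
#' For each reference network, computes the MAE at the requested orders and
#' the MAE of one or more constrained null models of each type (sharing the
#' reference's initial states), then summarizes each (type, order) pair by a
#' paired two-sided Wilcoxon signed-rank test across networks. Raw p-values
#' are reported without multiplicity adjustment.
#'
#' @param networks list of [boolean_network()] objects (e.g. a curated corpus
#'   or [pseudo_biological_network()] draws).
#' @param types null-model types (see [null_model()]).
#' @param orders Taylor orders.
#' @param n_null null models per network and type (their MAEs are averaged).
#' @param n_ic,steps MAE settings.
#' @return A list with `mae` (tibble: `network`, `ensemble`, `order`, `mae`)
#'   and `tests` (tibble: `ensemble`, `order`, `statistic`, `p_value`,
#'   `median_difference`, `degenerate`).
#' @export
run_null_model_comparison <- function(networks,
                                      types = c("unconstrained", "type1",
                                                "type2", "type3"),
                                      orders = 1:3, n_null = 1,
                                      n_ic = 1000, steps = 25) {
  rows <- list()
  for (i in seq_along(networks)) {
    net <- networks[[i]]
    X0 <- sample_initial_states(net$n, n_ic)
    mae <- mean_approximation_error(net, orders, steps = steps,
                                    initial_states = X0)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      network = i, ensemble = "reference", order = orders, mae = unname(mae))
    for (ty in types) {
      acc <- matrix(0, n_null, length(orders))
      for (b in seq_len(n_null)) {
        nm <- null_model(net, ty)
        acc[b, ] <- mean_approximation_error(nm, orders, steps = steps,
                                             initial_states = X0)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        network = i, ensemble = ty, order = orders, mae = colMeans(acc))
    }
  }
  mae_tbl <- dplyr::bind_rows(rows)
  ref <- dplyr::filter(mae_tbl, .data$ensemble == "reference")
  tests <- list()
  for (ty in types) for (m in orders) {
    a <- dplyr::filter(ref, .data$order == m)$mae
    b <- dplyr::filter(mae_tbl, .data$ensemble == ty, .data$order == m)$mae
    pc <- paired_comparison(a, b)
    tests[[length(tests) + 1L]] <- tibble::tibble(
      ensemble = ty, order = m, statistic = pc$statistic,
      p_value = pc$p_value, median_difference = pc$median_difference,
      degenerate = pc$degenerate)
  }
  list(mae = mae_tbl, tests = dplyr::bind_rows(tests))
}

#' Attractor variability across null-model ensembles
#'
#' Generates an ensemble of null models of each type per reference network
#' and reports the mean and standard deviation of the exact attractor count,
#' together with the reference's count and its attractors per
#' external-parameter configuration.
#'
#' @param networks list of networks small enough for exact enumeration.
#' @param types null-model types.
#' @param n_models ensemble size per network and type.
#' @param max_n exact-enumeration cap.
#' @return A tibble: `network`, `ensemble`, `mean_n_attractors`,
#'   `sd_n_attractors`, `n_attractors_reference`,
#'   `attractors_per_configuration`.
#' @export
run_null_variability <- function(networks,
                                 types = c("unconstrained", "type1",
                                           "type2", "type3"),
                                 n_models = 100, max_n = 20) {
  rows <- list()
  for (i in seq_along(networks)) {
    net <- networks[[i]]
    s_ref <- exact_attractors(net, max_n = max_n)$n_attractors
    apc <- attractors_per_external_configuration(net, max_n = max_n)
    for (ty in types) {
      ens <- null_ensemble(net, ty, n_models = n_models)
      s <- vapply(ens$models, function(m)
        exact_attractors(m, max_n = max_n)$n_attractors, numeric(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        network = i, ensemble = ty,
        mean_n_attractors = mean(s), sd_n_attractors = stats::sd(s),
        n_attractors_reference = s_ref,
        attractors_per_configuration = apc)
    }
  }
  dplyr::bind_rows(rows)
}

#' Assemble the predictor table for a corpus of networks
#'
#' Binds [structural_predictors()], [dynamical_predictors()] and the MAE at
#' the requested orders into one row per network — the input for
#' [spearman_screen()] and [lasso_path()].
#'
#' @param networks list of [boolean_network()] objects.
#' @param orders Taylor orders for the MAE columns (`mae_order_<m>`).
#' @param mode,n_ic,max_n,steps passed to the dynamics and MAE machinery.
#' @return A tibble with one row per network.
#' @export
predictor_table <- function(networks, orders = 1:3,
                            mode = c("sampled", "exact"),
                            n_ic = 1000, steps = 25, max_n = 20) {
  mode <- match.arg(mode)
  rows <- lapply(seq_along(networks), function(i) {
    net <- networks[[i]]
    mae <- mean_approximation_error(net, orders, n_ic = n_ic, steps = steps)
    dplyr::bind_cols(
      tibble::tibble(network = i),
      structural_predictors(net),
      dplyr::select(dynamical_predictors(net, mode, n_ic, max_n), -"mode"),
      tibble::as_tibble(as.list(stats::setNames(
        mae, paste0("mae_order_", orders)))))
  })
  dplyr::bind_rows(rows)
}
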
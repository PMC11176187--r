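test_that("structural predictors on hand-countable networks", {
  idn <- identity_network(3)
  sp <- structural_predictors(idn)
  expect_equal(sp$mean_degree, 1)
  expect_equal(sp$prop_ncf, 1)
  expect_equal(sp$n_ffl, 0)
  expect_equal(sp$mean_norm_canalizing_depth, 1)
  # 3-cycle of identity-like rules: one 3-loop, no FFLs
  ring <- boolean_network(list(ID1, ID1, ID1), list(3L, 1L, 2L))
  sp_ring <- structural_predictors(ring)
  expect_equal(sp_ring$n_3loops, 1)
  expect_equal(sp_ring$n_ffl, 0)
  expect_equal(sp_ring$n_4loops, 0)
  # complete digraph minus self-loops on 3 nodes: 6 FFLs and two 3-loops
  full <- boolean_network(
    replicate(3, truth_table(c(0, 1, 1, 1)), simplify = FALSE),
    list(c(2L, 3L), c(1L, 3L), c(1L, 2L)))
  sp_full <- structural_predictors(full)
  expect_equal(sp_full$n_ffl, 6)
  expect_equal(sp_full$n_3loops, 2)
})

test_that("cycle counting by DFS agrees with the trace formula", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    A <- matrix(as.integer(stats::runif(n * n) < 0.3), n, n)
    diag(A) <- 0L
    counts <- canalax:::count_simple_cycles(A, max_len = 4)
    A3 <- A %*% A %*% A
    expect_equal(unname(counts[["3"]]), sum(diag(A3)) / 3)
    # 4-cycles via inclusion-exclusion on closed 4-walks
    M <- A * t(A)  # mutual edges
    walks4 <- sum(diag(A3 %*% A))
    deg_mut <- rowSums(M)
    nonsimple <- sum(deg_mut^2) + sum(M %*% M) - sum(deg_mut)
    expect_equal(unname(counts[["4"]]), (walks4 - nonsimple) / 4)
  }
})

test_that("dynamical predictors delegate to the attractor machinery", {
  set.seed(72)
  dp <- dynamical_predictors(swap_network(), mode = "exact")
  expect_equal(dp$n_attractors, 3)
  expect_equal(dp$mean_length, 4 / 3)
  expect_equal(dp$mean_avg_sensitivity, 1)
  dp2 <- dynamical_predictors(identity_network(4), mode = "sampled", n_ic = 16)
  expect_equal(dp2$prop_steady, 1)
})

test_that("Spearman screen equals the rank-Pearson oracle", {
  set.seed(73)
  tb <- tibble::tibble(a = stats::rnorm(12), b = stats::rnorm(12),
                       c = sample(1:3, 12, replace = TRUE))
  m <- spearman_screen(tb)
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  expect_equal(m["a", "b"], oracle_spearman(tb$a, tb$b))
  expect_equal(m["a", "c"], oracle_spearman(tb$a, tb$c))
  expect_equal(m, t(m))
  expect_equal(spearman_screen(tibble::tibble(x = 1:5, y = -(1:5)))["x", "y"], -1)
  expect_warning(spearman_screen(tibble::tibble(x = 1:5, y = rep(1, 5))),
                 "constant")
})

test_that("paired Wilcoxon comparison: monotonicity, symmetry, degeneracy", {
  set.seed(74)
  x <- stats::rnorm(12)
  pc0 <- paired_comparison(x, x)
  expect_true(pc0$degenerate)
  expect_true(is.na(pc0$p_value))
  # p decreases as a constant shift grows
  shift <- abs(stats::rnorm(12, 0, 0.05))
  p1 <- paired_comparison(x, x + 0.5 + shift)$p_value
  p2 <- paired_comparison(x, x + 0.05 * (seq_len(12) %% 3 == 0))$p_value
  expect_lt(p1, p2)
  # two-sidedness: swapping the inputs leaves p unchanged
  y <- x + stats::rnorm(12, 0.3)
  expect_equal(paired_comparison(x, y)$p_value, paired_comparison(y, x)$p_value)
  expect_equal(tidy(paired_comparison(x, y))$n, 12)
})

test_that("LASSO path satisfies KKT optimality and known limits", {
  set.seed(75)
  N <- 50; d <- 6
  X <- matrix(stats::rnorm(N * d), N, d)
  beta_true <- c(2, -1, 0.5, 0, 0, 0)
  y <- X %*% beta_true + stats::rnorm(N, 0, 0.3)
  Xs <- as.matrix(standardize_columns(as.data.frame(X)))
  ys <- drop(scale(y))
  fit <- lasso_path(Xs, ys, n_nonzero_stop = Inf)
  expect_lt(lasso_kkt_violation(fit, Xs, ys), 1e-8)
  # all coefficients vanish at alpha >= 2 max|x'y|/N
  a_max <- 2 * max(abs(crossprod(Xs, ys))) / N
  fit0 <- lasso_path(Xs, ys, alpha = a_max * 1.01)
  expect_true(all(fit0$beta == 0))
  # alpha -> 0 approaches least squares
  fit_ls <- lasso_path(Xs, ys, alpha = 1e-10)
  expect_equal(unname(drop(fit_ls$beta)), unname(coef(stats::lm(ys ~ Xs - 1))),
               tolerance = 1e-5)
  # single predictor: soft-threshold closed form
  x1 <- Xs[, 1, drop = FALSE]
  a <- 0.4
  f1 <- lasso_path(x1, ys, alpha = a)
  rho <- 2 * sum(x1 * ys) / N
  expect_equal(drop(f1$beta),
               sign(rho) * max(abs(rho) - a, 0) / (2 * sum(x1^2) / N),
               tolerance = 1e-10)
})

test_that("LASSO path matches glmnet at matched penalties", {
  set.seed(76)
  N <- 60; d <- 8
  X <- matrix(stats::rnorm(N * d), N, d)
  y <- X %*% stats::rnorm(d) + stats::rnorm(N)
  Xs <- as.matrix(standardize_columns(as.data.frame(X)))
  ys <- drop(scale(y))
  alphas <- c(0.8, 0.4, 0.1, 0.02)
  fit <- lasso_path(Xs, ys, alpha = alphas)
  # the (1/N) objective here equals glmnet's (1/2N) objective at lambda = a/2
  g <- glmnet::glmnet(Xs, ys, lambda = alphas / 2, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14)
  expect_equal(unname(fit$beta), unname(as.matrix(g$beta)), tolerance = 1e-5)
})

test_that("the path stops once enough predictors are active", {
  set.seed(77)
  N <- 40; d <- 10
  X <- matrix(stats::rnorm(N * d), N, d)
  y <- rowSums(X[, 1:5]) + stats::rnorm(N, 0, 0.2)
  Xs <- as.matrix(standardize_columns(as.data.frame(X)))
  ys <- drop(scale(y))
  fit <- lasso_path(Xs, ys, n_nonzero_stop = 4)
  nnz <- colSums(fit$beta != 0)
  expect_true(all(nnz[-length(nnz)] < 4))
  expect_gte(nnz[length(nnz)], 4)
  expect_false(is.na(fit$alpha_stop))
  expect_equal(glance(fit)$n_nonzero_final, sum(fit$beta[, ncol(fit$beta)] != 0))
  expect_error(lasso_path(X, ys), "standardized")
})

test_that("experiment runners return tidy per-condition tables", {
  set.seed(78)
  g <- run_approximability_grid(K_set = 2, p_set = c(0.3, 0.5), reps = 2,
                                orders = 1:2, N = 8, n_ic = 64, steps = 10)
  expect_s3_class(g, "approx_grid")
  expect_equal(nrow(g), 2 * 2 * 2)
  expect_true(all(g$mae[g$order == 2] == 0))  # K = 2 rules are order-2 exact
  expect_true(all(c("K", "p", "rep", "order", "mae",
                    "mean_avg_sensitivity") %in% names(g)))

  cg <- run_canalization_grid(k_set = 1, p_set = c(0.2, 0.5), n_funcs = 50)
  expect_true(all(cg$prop_canalizing == 1))  # every 1-input function canalizes

  d <- run_depth_experiment(depths = c(0, 4), reps = 2, orders = 1, N = 8,
                            K = 4, n_ic = 64, steps = 10)
  expect_equal(nrow(d), 4)
  expect_true(all(c("min_depth", "mae") %in% names(d)))

  l <- run_layer_experiment(layers = list(4, c(1, 3)), reps = 2, orders = 1,
                            N = 8, K = 4, n_ic = 64, steps = 10)
  expect_equal(nrow(l), 4)
})

test_that("null-model comparison runner pairs networks with their nulls", {
  set.seed(79)
  nets <- replicate(4, pseudo_biological_network(8, n_external = 1),
                    simplify = FALSE)
  res <- run_null_model_comparison(nets, types = c("type1", "type3"),
                                   orders = 1, n_ic = 64, steps = 10)
  expect_setequal(unique(res$mae$ensemble), c("reference", "type1", "type3"))
  expect_equal(nrow(res$tests), 2)
  expect_true(all(res$mae$mae >= 0 & res$mae$mae <= 1))

  v <- run_null_variability(nets[1:2], types = "type2", n_models = 4)
  expect_equal(nrow(v), 2)
  expect_true(all(is.finite(v$sd_n_attractors)))
  expect_true(all(v$attractors_per_configuration >= 1))
})

test_that("predictor tables assemble and screen end to end", {
  set.seed(80)
  nets <- replicate(6, pseudo_biological_network(9), simplify = FALSE)
  tb <- predictor_table(nets, orders = 1, mode = "exact", n_ic = 64, steps = 10)
  expect_equal(nrow(tb), 6)
  expect_true(all(c("mean_degree", "prop_ncf", "basin_entropy",
                    "mae_order_1") %in% names(tb)))
  expect_true(all(is.finite(tb$mae_order_1)))
})

test_that("autoplot and tidiers produce the advertised shapes", {
  set.seed(81)
  g <- run_approximability_grid(K_set = 2, p_set = 0.5, reps = 2, orders = 1,
                                N = 8, n_ic = 32, steps = 5)
  expect_s3_class(autoplot(g), "ggplot")
  expect_s3_class(plot_canalization_mae(
    run_depth_experiment(depths = 0, reps = 2, orders = 1, N = 8, K = 4,
                         n_ic = 32, steps = 5)), "ggplot")
  X <- matrix(stats::rnorm(60), 20, 3)
  Xs <- as.matrix(standardize_columns(as.data.frame(X)))
  ys <- drop(scale(rowSums(X) + stats::rnorm(20, 0, 0.2)))
  fit <- lasso_path(Xs, ys, n_nonzero_stop = 2)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_equal(ncol(tidy(fit)), 4)
  rp <- canalization_report(AND2)
  expect_equal(nrow(tidy(rp)), 2)
  expect_true(glance(rp)$is_ncf)
})
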
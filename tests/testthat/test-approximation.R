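test_that("the multilinear extension interpolates every vertex (k <= 3 exhaustive)", {
  for (k in 0:3) for (tt in all_functions(k)) {
    poly <- continuous_extension(tt)
    X <- canalax:::tt_inputs(k)
    v <- canalax:::poly_evaluate_matrix(poly, matrix(as.numeric(X), nrow(X), k))
    expect_identical(as.numeric(v), as.numeric(tt$outputs))
  }
  set.seed(41)
  for (i in 1:20) {
    tt <- random_function(4, 0.5)
    poly <- continuous_extension(tt)
    X <- canalax:::tt_inputs(4)
    v <- canalax:::poly_evaluate_matrix(poly, matrix(as.numeric(X), 16, 4))
    expect_identical(as.numeric(v), as.numeric(tt$outputs))
  }
})

test_that("known closed-form extensions", {
  # AND: 1/4 + (x1-1/2)/2 + (x2-1/2)/2 + (x1-1/2)(x2-1/2)
  p_and <- continuous_extension(AND2)
  expect_equal(unname(p_and$coef), c(0.25, 0.5, 0.5, 1))
  # NOT: 1 - x = 1/2 - (x - 1/2)
  p_not <- continuous_extension(NOT1)
  expect_equal(unname(p_not$coef), c(0.5, -1))
  # constants
  expect_equal(continuous_extension(truth_table(rep(1, 4)))$coef[1], 1)
  # empty-set coefficient is always the output bias
  set.seed(42)
  for (i in 1:10) {
    tt <- random_function(3, 0.3)
    expect_equal(continuous_extension(tt)$coef[1], canalax:::tt_p(tt))
  }
})

test_that("Taylor truncation drops exactly the high-order terms", {
  # XOR at order 1 is the constant 1/2: both first partials vanish at center
  px <- taylor_truncation(continuous_extension(XOR2), 1)
  expect_equal(px$coef[1], 0.5)
  expect_true(all(px$coef[-1] == 0))
  # m = k returns the polynomial unchanged
  p_and <- continuous_extension(AND2)
  expect_equal(taylor_truncation(p_and, 2)$coef, p_and$coef)
  # m = 0 leaves the bias
  set.seed(43)
  tt <- random_function(3, 0.4)
  p0 <- taylor_truncation(continuous_extension(tt), 0)
  expect_equal(p0$coef[1], canalax:::tt_p(tt))
  expect_true(all(p0$coef[-1] == 0))
  # nesting: raising m only adds coefficients
  poly <- continuous_extension(random_function(4, 0.5))
  for (m in 0:3) {
    lo <- taylor_truncation(poly, m)$coef
    hi <- taylor_truncation(poly, m + 1)$coef
    expect_true(all(hi[lo != 0] == lo[lo != 0]))
  }
  expect_error(taylor_truncation(poly, 5), "order")
})

test_that("approximate networks reproduce Boolean updates when exact", {
  set.seed(44)
  net <- random_network(8, 3, family = "kauffman", p = 0.5)
  cnet <- approximate_network(net, 3)
  for (r in 1:5) {
    x <- sample(0:1, 8, replace = TRUE)
    expect_equal(simulate_continuous(cnet, x, 1),
                 as.numeric(synchronous_step(net, x)))
  }
  # m = 0 on a NOT node: constant map 1/2
  notnet <- boolean_network(list(NOT1), list(1L))
  c0 <- approximate_network(notnet, 0)
  expect_equal(simulate_continuous(c0, 0, 1), 0.5)
  expect_equal(simulate_continuous(c0, 0.9, 5), 0.5)
  # clipping keeps all evaluations inside [0, 1]
  net5 <- random_network(8, 4, family = "kauffman", p = 0.5)
  c1 <- approximate_network(net5, 1)
  x <- stats::runif(8)
  y <- simulate_continuous(c1, x, 10)
  expect_true(all(y >= 0 & y <= 1))
})

test_that("MAE is zero iff the approximation captures every rule", {
  set.seed(45)
  # identity rules have degree 1
  expect_equal(unname(mean_approximation_error(identity_network(6), 1,
                                               n_ic = 50)), 0)
  # K = 4 rules at order 4: exact, including through 25 steps of chaos
  net <- random_network(12, 4, family = "kauffman", p = 0.5)
  expect_equal(unname(mean_approximation_error(net, 4, n_ic = 200)), 0)
  # NOT node at order 0: continuous stuck at 1/2, Boolean oscillates -> 0.25
  notnet <- boolean_network(list(NOT1), list(1L))
  expect_equal(unname(mean_approximation_error(notnet, 0, n_ic = 2)), 0.25)
})

test_that("MAE shares initial states across orders and stays in [0, 1]", {
  set.seed(46)
  net <- random_network(10, 3, family = "kauffman", p = 0.5)
  mae <- mean_approximation_error(net, 0:3, n_ic = 300)
  expect_named(mae, c("order_0", "order_1", "order_2", "order_3"))
  expect_true(all(mae >= 0 & mae <= 1))
  expect_equal(unname(mae["order_3"]), 0)
})

test_that("MAE is equivariant under node relabeling", {
  set.seed(47)
  net <- random_network(8, 2, family = "kauffman", p = 0.5)
  perm <- sample(8)
  inv <- order(perm)
  pnet <- boolean_network(
    rules = net$rules[perm],
    regulators = lapply(net$regulators[perm], function(r) inv[r]),
    node_names = paste0("y", 1:8))
  X0 <- canalax:::tt_inputs(8)
  m1 <- mean_approximation_error(net, 1, initial_states = X0)
  m2 <- mean_approximation_error(pnet, 1, initial_states = X0[, perm])
  expect_equal(unname(m1), unname(m2))
})

test_that("initial-state sampler draws distinct states and covers small spaces", {
  set.seed(48)
  X <- canalax:::sample_initial_states(4, 100)
  expect_equal(nrow(X), 16)          # whole space when 2^n <= n_ic
  X2 <- canalax:::sample_initial_states(12, 500)
  expect_equal(nrow(X2), 500)
  expect_equal(nrow(unique(X2)), 500)
  X3 <- canalax:::sample_initial_states(40, 50)
  expect_equal(nrow(unique(X3)), 50)
})
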
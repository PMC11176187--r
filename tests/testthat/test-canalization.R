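test_that("canalizing detection with witnesses and the constant convention", {
  expect_true(is_canalizing(AND2))
  w <- attr(is_canalizing(AND2), "witness")
  expect_equal(w$a, 0)
  expect_equal(w$b, 0)
  expect_false(is_canalizing(XOR2))
  const1 <- truth_table(rep(1, 4))
  expect_false(is_canalizing(const1))
  expect_true(is_canalizing(const1, constants_canalizing = TRUE))
})

test_that("depth agrees with the exhaustive max-peeling oracle (all k <= 3)", {
  for (k in 0:3) {
    for (tt in all_functions(k)) {
      expect_equal(canalization_report(tt)$depth, oracle_depth(tt))
    }
  }
})

test_that("depth agrees with the oracle on sampled 4-input functions", {
  set.seed(11)
  for (i in 1:60) {
    tt <- random_function(4, sample(c(0.25, 0.5), 1))
    expect_equal(canalization_report(tt)$depth, oracle_depth(tt))
  }
})

test_that("layer structure of the textbook examples", {
  and_not <- make_tt(function(x) x[1] & !x[2] & !x[3] & x[4], 4)
  rp <- canalization_report(and_not)
  expect_equal(rp$depth, 4L)
  expect_equal(rp$layer_structure, 4L)
  expect_true(rp$is_ncf)

  or_and <- make_tt(function(x) x[1] | (x[2] & x[3] & x[4]), 4)
  rp2 <- canalization_report(or_and)
  expect_equal(rp2$depth, 4L)
  expect_equal(rp2$layer_structure, c(1L, 3L))

  rp3 <- canalization_report(XOR2)
  expect_equal(rp3$depth, 0L)
  expect_length(rp3$layer_structure, 0)
  expect_identical(rp3$core$outputs, XOR2$outputs)

  # constant: depth 0, flagged
  rpc <- canalization_report(truth_table(rep(0, 4)))
  expect_equal(rpc$depth, 0L)
  expect_true(rpc$is_constant)
})

test_that("report reconstruction is exact (exhaustive k <= 3, sampled k = 4)", {
  for (k in 0:3) for (tt in all_functions(k)) {
    expect_identical(reconstruct_from_report(canalization_report(tt))$outputs,
                     tt$outputs)
  }
  set.seed(12)
  for (i in 1:50) {
    tt <- random_function(4, 0.5)
    expect_identical(reconstruct_from_report(canalization_report(tt))$outputs,
                     tt$outputs)
  }
})

test_that("depth is invariant under variable permutation and input negation", {
  set.seed(13)
  for (i in 1:25) {
    k <- sample(2:4, 1)
    tt <- random_function(k, 0.5)
    d <- canalization_report(tt)$depth
    perm <- sample(k)
    flip <- sample(0:1, k, replace = TRUE)
    X <- canalax:::tt_inputs(k)
    Y <- X[, perm, drop = FALSE]
    Y <- bitwXor(Y, matrix(flip, nrow(Y), k, byrow = TRUE))
    dim(Y) <- dim(X)
    tt2 <- truth_table(tt$outputs[canalax:::tt_index_matrix(Y) + 1L])
    expect_equal(canalization_report(tt2)$depth, d)
  }
})

test_that("NCF predicate counts 8 of the 16 two-input functions", {
  expect_true(is_nested_canalizing(AND2))
  expect_true(is_nested_canalizing(OR2))
  expect_false(is_nested_canalizing(XOR2))
  n_ncf <- sum(vapply(all_functions(2), is_nested_canalizing, logical(1)))
  expect_equal(n_ncf, 8L)
})

test_that("NCF frequency among random balanced 2-input functions is ~ 1/2", {
  set.seed(14)
  frac <- mean(replicate(800, is_nested_canalizing(random_function(2, 0.5))))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 800))
})

test_that("non-canalizing core generator: only parity functions at m = 2", {
  set.seed(15)
  for (i in 1:25) {
    tt <- random_noncanalizing_core(2)
    expect_true(identical(tt$outputs, c(0L, 1L, 1L, 0L)) ||
                  identical(tt$outputs, c(1L, 0L, 0L, 1L)))
  }
  tt <- random_noncanalizing_core(2, ones_count = 2)
  expect_equal(sum(tt$outputs), 2)
  expect_error(random_noncanalizing_core(1), "1 variable")
  expect_error(random_noncanalizing_core(3, ones_count = 0), "infeasible")
  expect_error(random_noncanalizing_core(3, ones_count = 8), "infeasible")
  expect_error(random_noncanalizing_core(2, ones_count = 1), "parity")
})

test_that("exact-depth generator realizes the requested depth every draw", {
  set.seed(16)
  for (i in 1:25) {
    expect_equal(canalization_report(random_with_exact_depth(4, 2))$depth, 2L)
    expect_true(is_nested_canalizing(random_with_exact_depth(4, 4)))
    expect_equal(canalization_report(random_with_exact_depth(4, 0))$depth, 0L)
  }
  expect_error(random_with_exact_depth(3, 2), "impossible")
  expect_error(random_with_exact_depth(4, 5), "d must lie")
})

test_that("min-depth generator: realized depth >= d, never the impossible k-1", {
  set.seed(17)
  d_seen <- replicate(60, canalization_report(random_with_min_depth(4, 2))$depth)
  expect_true(all(d_seen %in% c(2L, 4L)))
  expect_true(all(replicate(10,
    canalization_report(random_with_min_depth(4, 4))$depth) == 4L))
  d0 <- replicate(10, {
    tt <- random_with_min_depth(4, 0)
    length(essential_variables(tt))
  })
  expect_true(all(d0 == 4))
})

test_that("depth-and-bias generator preserves q and d of its reference", {
  set.seed(18)
  refs <- list(AND2, OR2,
               make_tt(function(x) x[1] | (x[2] & x[3] & x[4]), 4),
               make_tt(function(x) xor(x[1], x[2] & x[3]), 3))
  for (ref in refs) {
    rp <- canalization_report(ref)
    q <- sum(ref$outputs)
    for (i in 1:10) {
      g <- random_with_exact_depth_and_bias(ref$k, rp$depth, q,
                                            rp$canalized_outputs,
                                            sum(rp$core$outputs))
      expect_equal(sum(g$outputs), q)
      expect_equal(canalization_report(g)$depth, rp$depth)
    }
  }
  # inconsistent bias request fails loudly
  rp <- canalization_report(AND2)
  expect_error(
    random_with_exact_depth_and_bias(2, 2, 3, rp$canalized_outputs,
                                     sum(rp$core$outputs)),
    "infeasible|inconsistent")
})

test_that("layer-constrained NCF generator realizes the requested layers", {
  set.seed(19)
  for (ls in list(4L, c(1L, 3L), c(2L, 2L), c(1L, 1L, 2L))) {
    for (i in 1:10) {
      tt <- random_ncf_with_layers(4, ls)
      rp <- canalization_report(tt)
      expect_true(rp$is_ncf)
      expect_equal(rp$layer_structure, ls)
    }
  }
  expect_error(random_ncf_with_layers(4, c(2, 1, 1)), "size >= 2")
  expect_error(random_ncf_with_layers(4, c(2, 3)), "summing to k")
})

test_that("reports serialize to JSON", {
  js <- report_to_json(canalization_report(AND2))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$depth, 2)
  expect_equal(parsed$core, "1")
})
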
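#' Constrained rule-randomized null models of a Boolean network
#'
#' Replaces every update rule of a reference network by a random Boolean
#' function matching chosen characteristics, on the reference wiring diagram
#' reduced to essential regulators. Four ensembles are available:
#'
#' * `"unconstrained"` — a random function of the same (essential) degree;
#' * `"type1"` — additionally preserves each rule's ones-count `q` (bias),
#'   by placing `q` ones on a uniform random subset of the input space;
#' * `"type2"` — preserves each rule's exact canalizing depth `d` (random
#'   canalizing variables, inputs and outputs, non-canalizing essential
#'   core), with arbitrary bias;
#' * `"type3"` — preserves degree, bias and depth: the reference rule's
#'   canalized output sequence and core ones-count are reused, so the
#'   replacement has exactly the reference's `q` and `d`.
#'
#' Every reference rule is first reduced to its essential variables (about 2%
#' of regulators in curated models are non-essential, and keeping them would
#' bias the comparison). External parameters (`f_i = x_i`) are copied
#' unchanged and never replaced — in particular never by the negation, which
#' shares degree, bias and depth. Constant rules (degree 0 after reduction)
#' carry no degrees of freedom and are copied too. A self-regulating
#' non-external node is never allowed to become the self-identity, which
#' would create a new external parameter.
#'
#' @param net the reference [boolean_network()].
#' @param type one of `"unconstrained"`, `"type1"`, `"type2"`, `"type3"`.
#' @param require_nondegenerate should unconstrained/type-1 replacements be
#'   resampled until all retained inputs are essential (default `TRUE`)?
#'   Type-2/3 replacements are non-degenerate by construction.
#' @param max_tries per-rule rejection cap; infeasible constraints raise an
#'   error naming the node.
#' @return A [boolean_network()] with the same node names and the reduced
#'   reference wiring.
#' @export
null_model <- function(net, type = c("unconstrained", "type1", "type2", "type3"),
                       require_nondegenerate = TRUE, max_tries = 1e5) {
  stopifnot(inherits(net, "boolean_network"))
  type <- match.arg(type)
  ext <- external_parameters(net)
  rules <- vector("list", net$n)
  regulators <- vector("list", net$n)
  for (j in seq_len(net$n)) {
    red <- reduce_to_essential(net$rules[[j]])
    regs <- net$regulators[[j]][attr(red, "essential")]
    regulators[[j]] <- regs
    if (j %in% ext || red$k == 0L) { rules[[j]] <- red; next }
    rules[[j]] <- tryCatch(
      draw_null_rule(red, type, require_nondegenerate, max_tries,
                     forbid_self_identity = identical(regs, j)),
      error = function(e)
        stop("null model (", type, ") infeasible at node `",
             net$node_names[j], "`: ", conditionMessage(e), call. = FALSE))
  }
  boolean_network(rules, regulators, node_names = net$node_names)
}

draw_null_rule <- function(red, type, require_nondegenerate, max_tries,
                           forbid_self_identity = FALSE) {
  k <- red$k
  q <- sum(red$outputs)
  gen <- switch(type,
    unconstrained = function() random_function(k, 0.5),
    type1 = function() random_function_exact_ones(k, q),
    type2 = {
      d <- canalization_report(red)$depth
      function() random_with_exact_depth(k, d, max_tries)
    },
    type3 = {
      rep_ <- canalization_report(red)
      function() random_with_exact_depth_and_bias(
        k, rep_$depth, q, rep_$canalized_outputs,
        sum(rep_$core$outputs), max_tries)
    })
  need_nondeg <- if (type %in% c("unconstrained", "type1"))
    require_nondegenerate else FALSE
  identity_outputs <- c(0L, 1L)
  for (try in seq_len(max_tries)) {
    tt <- gen()
    if (all(tt$outputs == tt$outputs[1])) next          # never constant
    if (need_nondeg && length(essential_variables(tt)) < k) next
    if (forbid_self_identity && k == 1L &&
        identical(tt$outputs, identity_outputs)) next
    return(tt)
  }
  stop("rejection cap of ", max_tries, " reached")
}

#' Ensembles of null models with a constraint audit
#'
#' Draws `n_models` independent null models and verifies, for every generated
#' rule, that the measured degree, ones-count and canalizing depth match what
#' the chosen type must preserve.
#'
#' @inheritParams null_model
#' @param n_models ensemble size.
#' @return A list with `models` (list of networks) and `audit` (tibble with
#'   one row per model and node: `model`, `node`, `k`, `q_ref`, `q_new`,
#'   `d_ref`, `d_new`, `ok`).
#' @export
null_ensemble <- function(net, type = c("unconstrained", "type1", "type2", "type3"),
                          n_models = 100, require_nondegenerate = TRUE,
                          max_tries = 1e5) {
  type <- match.arg(type)
  models <- vector("list", n_models)
  audits <- vector("list", n_models)
  for (i in seq_len(n_models)) {
    models[[i]] <- null_model(net, type, require_nondegenerate, max_tries)
    a <- null_model_audit(net, models[[i]], type)
    a$model <- i
    audits[[i]] <- a
  }
  list(models = models, audit = dplyr::bind_rows(audits))
}

#' @rdname null_ensemble
#' @param null_net a generated null model to compare against `net`.
#' @export
null_model_audit <- function(net, null_net,
                             type = c("unconstrained", "type1", "type2", "type3")) {
  type <- match.arg(type)
  rows <- lapply(seq_len(net$n), function(j) {
    ref <- reduce_to_essential(net$rules[[j]])
    new <- null_net$rules[[j]]
    d_ref <- canalization_report(ref)$depth
    d_new <- canalization_report(new)$depth
    ok <- new$k == ref$k &&
      (!(type %in% c("type1", "type3")) || sum(new$outputs) == sum(ref$outputs)) &&
      (!(type %in% c("type2", "type3")) || ref$k == 0L || d_new == d_ref)
    tibble::tibble(node = net$node_names[j], k = ref$k,
                   q_ref = sum(ref$outputs), q_new = sum(new$outputs),
                   d_ref = d_ref, d_new = d_new, ok = ok)
  })
  dplyr::bind_rows(rows)
}
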
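#' Random K-in-regular strongly connected wiring diagrams
#'
#' Samples, for each of `N` nodes, `K` distinct regulators other than the
#' node itself (no self-loops, no duplicate edges), and regenerates the whole
#' diagram until it is strongly connected — rejection keeps the distribution
#' uniform over admissible diagrams. Without strong connectivity the
#' dynamics would decouple into independent pieces.
#'
#' @param N number of nodes (`N > K`).
#' @param K constant in-degree (`K >= 1`).
#' @param max_tries regeneration cap.
#' @return A `wiring_diagram` whose `regulators` field (list of length `N`)
#'   can seed rule generation.
#' @export
random_regular_digraph <- function(N, K, max_tries = 1e4) {
  if (N <= K) stop("need N > K to avoid self-loops with distinct regulators")
  stopifnot(K >= 1)
  for (try in seq_len(max_tries)) {
    regulators <- lapply(seq_len(N), function(j) sample((1:N)[-j], K))
    edges <- tibble::tibble(
      from = unlist(regulators),
      to = rep(seq_len(N), each = K))
    g <- igraph::graph_from_edgelist(as.matrix(edges), directed = TRUE)
    if (igraph::is_connected(g, mode = "strong")) {
      wd <- structure(list(n = N, node_names = paste0("x", seq_len(N)),
                           edges = edges,
                           in_degree = rep(K, N),
                           out_degree = tabulate(edges$from, N)),
                      class = "wiring_diagram")
      wd$regulators <- regulators
      return(wd)
    }
  }
  stop("no strongly connected K-regular digraph found in ", max_tries,
       " attempts (N = ", N, ", K = ", K, ")")
}

#' Random Boolean networks with constrained rule families
#'
#' Generates a modified N-K Kauffman network: a strongly connected simple
#' wiring diagram with constant in-degree `K` ([random_regular_digraph()])
#' and independent random update rules drawn from the requested family:
#'
#' * `"kauffman"` — each of the `2^K` outputs is an independent
#'   Bernoulli(`p`) draw;
#' * `"kauffman_nondegenerate"` — as above, resampled until all `K` inputs
#'   are essential;
#' * `"min_depth"` — canalizing cascade with minimal depth `min_depth`
#'   ([random_with_min_depth()]; the realized depth may be larger);
#' * `"ncf_layers"` — nested canalizing rules with the prescribed
#'   `layer_structure` ([random_ncf_with_layers()]).
#'
#' @param N network size.
#' @param K constant in-degree.
#' @param family rule family (see above).
#' @param p output bias for the Kauffman families.
#' @param min_depth minimal canalizing depth for `family = "min_depth"`.
#' @param layer_structure layer vector for `family = "ncf_layers"`.
#' @param max_tries rejection caps passed through.
#' @return A [boolean_network()].
#' @export
random_network <- function(N, K,
                           family = c("kauffman", "kauffman_nondegenerate",
                                      "min_depth", "ncf_layers"),
                           p = 0.5, min_depth = NULL, layer_structure = NULL,
                           max_tries = 1e4) {
  family <- match.arg(family)
  wd <- random_regular_digraph(N, K, max_tries)
  draw <- switch(family,
    kauffman = function() random_function(K, p),
    kauffman_nondegenerate = function() random_nondegenerate_function(K, p),
    min_depth = {
      if (is.null(min_depth)) stop("family `min_depth` needs `min_depth`")
      function() random_with_min_depth(K, min_depth)
    },
    ncf_layers = {
      if (is.null(layer_structure)) stop("family `ncf_layers` needs `layer_structure`")
      if (sum(layer_structure) != K)
        stop("layer structure must sum to K = ", K)
      function() random_ncf_with_layers(K, layer_structure)
    })
  rules <- replicate(N, draw(), simplify = FALSE)
  boolean_network(rules, wd$regulators, node_names = wd$node_names)
}

#' Pseudo-biological random Boolean networks (synthetic)
#'
#' A synthetic stand-in emulating the summary statistics of curated
#' biological Boolean models: sparse in-degrees (shifted Poisson with mean
#' about 2.5, truncated at `max_degree`), a high fraction of nested
#' canalizing rules, and optional external parameters (identity nodes whose
#' state never changes). It reproduces corpus-level statistics, not any real
#' network's wiring; self-regulation is allowed for non-external nodes.
#'
#' @param N network size.
#' @param mean_degree target mean in-degree of the shifted-Poisson sampler.
#' @param ncf_fraction probability that a non-external rule is a random NCF
#'   (remainder: random non-degenerate functions at `p = 0.5`).
#' @param n_external number of external-parameter nodes (`<= N`); the exact
#'   attractor count is then at least `2^n_external`.
#' @param max_degree in-degree cap (mirrors the exclusion of very high
#'   in-degree rules from the curated corpus).
#' @return A [boolean_network()].
#' @export
pseudo_biological_network <- function(N, mean_degree = 2.5, ncf_fraction = 0.95,
                                      n_external = 0, max_degree = 10) {
  stopifnot(N >= 1, n_external >= 0, n_external <= N,
            ncf_fraction >= 0, ncf_fraction <= 1, max_degree >= 1)
  ext <- if (n_external > 0) sample.int(N, n_external) else integer(0)
  lambda <- mean_degree - 1
  rules <- vector("list", N)
  regulators <- vector("list", N)
  for (j in seq_len(N)) {
    if (j %in% ext) {
      rules[[j]] <- truth_table(c(0L, 1L))
      regulators[[j]] <- j
      next
    }
    repeat {
      k <- 1L + stats::rpois(1, lambda)
      if (k <= min(max_degree, N)) break
    }
    regulators[[j]] <- sample.int(N, k)
    rules[[j]] <- if (stats::runif(1) < ncf_fraction)
      random_with_exact_depth(k, k)
    else if (k == 1L) truth_table(sample(list(c(0L, 1L), c(1L, 0L)), 1)[[1]])
    else random_nondegenerate_function(k, 0.5)
    ## a chance self-identity would silently add an external parameter
    if (k == 1L && identical(regulators[[j]], j) &&
        identical(rules[[j]]$outputs, c(0L, 1L)))
      rules[[j]] <- truth_table(c(1L, 0L))
  }
  boolean_network(rules, regulators, node_names = paste0("x", seq_len(N)))
}
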
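---
title: "Canalization and the Taylor approximability of Boolean network dynamics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canalization and the Taylor approximability of Boolean network dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canalax)
```

This vignette is the package's own account of the models and procedures it
implements, the conventions it fixes where several are in circulation, and
the design choices made where the design was genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The model

A Boolean network is a map `F = (f_1, ..., f_n)` on `{0,1}^n`, each
coordinate rule `f_j` reading an ordered list of regulators; all nodes
update synchronously. Only the synchronous scheme is implemented:
asynchronous and probabilistic schedules are out of scope, as are
multi-valued logics and partially defined rules.

Truth tables are the atom of everything. A rule of arity `k` is stored as
its `2^k`-bit output vector with the fixed index convention that the input
tuple `(x_1, ..., x_k)` maps to row `sum(x_i 2^(k-i))` — `x_1` is the most
significant bit. Every serializer (`write_truth_table()`, `write_rules()`,
JSON dumps) and the polynomial machinery share this convention, so files
round-trip bit-exactly.

A variable is *essential* if flipping it changes the output for some context.
Wiring diagrams contain only essential dependencies, and all rule-level
statistics (bias, sensitivity, canalizing depth, null-model matching) are
computed after `reduce_to_essential()`. A node is an *external parameter*
when its reduced rule is the identity on itself; `c` of them split the state
space into `2^c` non-communicating components.

## Canalization algebra

`canalization_report()` peels, at each stage, *all* currently canalizing
variables as one layer and recurses on the restriction to their
non-canalizing inputs. This greedy grouping is exactly the standard monomial
form's layer structure: any two variables canalizing at the same stage must
share the canalized output (fix both canalizing inputs simultaneously to see
the outputs coincide), and peeling cannot destroy the canalization of the
remaining layer members. The recursion stops at the first non-canalizing
remainder, the *core*. Reconstruction from the report (the canalizing
cascade, first peeled variable checked first) reproduces the truth table
bit-exactly; the tests verify this exhaustively for all functions of arity
up to 3 and on sampled 4-input functions, against an independent brute-force
maximizer over peel sequences.

Conventions fixed here:

* **Constant functions** report depth 0 with an `is_constant` flag, and
  `is_canalizing()` takes a `constants_canalizing` switch (default `FALSE`)
  because both conventions are in active use; the canalization-frequency
  grid (`run_canalization_grid()`) defaults the switch to `TRUE`, the
  convention under which every 1-input cell has canalizing probability 1.
  A "depth `n`" convention for constants was considered and rejected: it
  would break the invariant that the layer sizes sum to the depth.
* **NCF in ambient arity.** `is_nested_canalizing()` asks whether the depth
  equals the arity of the table as given, so a two-input table that really
  depends on one variable is not a 2-variable NCF; compose with
  `reduce_to_essential()` for the reduced notion. This choice makes the
  enumeration come out the classical way (8 of the 16 two-input functions).
* **Depth `k − 1` is impossible** (a 1-variable core is always canalizing),
  and generators asked for it fail loudly rather than silently bumping to
  `k`.
* **Literal ambiguity.** A single remaining literal canalizes with both
  input values; the report keeps the `a = 0` witness. Either choice
  reconstructs the function; fixing one makes reports deterministic.

The constrained generators all build the same cascade. `random_with_exact_depth()`
samples a uniform variable order, uniform canalizing inputs `a_i` and
canalized outputs `b_i`, and completes with a non-canalizing, fully
essential core (rejection-sampled with a `1e5` cap and a deterministic
error). `random_with_min_depth()` lets the core be canalizing, so realized
depth can exceed the request. `random_ncf_with_layers()` derives the `b`
sequence from the layer vector — constant within a layer, alternating
between consecutive layers, which is precisely what makes layer boundaries
well defined — and enforces a final layer of size at least 2 for `k >= 2`
(standard-form uniqueness). `random_with_exact_depth_and_bias()` reuses a
reference report's `b` sequence and core ones-count, which pins the
ones-count of the result through the cascade identity
`q = sum_i b_i 2^(k-i) + q_core`; inconsistent requests are an error, never
silently relaxed. The exact sampling distribution over variable orders and
canalizing inputs for layer-constrained NCFs is not canonical in the
literature; uniform sampling is used throughout and flagged here.

## Continuous extensions and the approximation error

The multilinear extension is computed as a Walsh–Hadamard transform and
stored in the basis of centered monomials `prod_{i in A}(x_i − 1/2)`: the
coefficient of `A` is `2^{|A|−k} sum_x f(x) prod_{i in A}(2x_i − 1)`. The
empty-set coefficient is the output bias; order-`m` truncation zeroes all
subsets larger than `m`, so truncations are nested by construction. Because
the polynomial is square-free, every multi-index factorial in the Taylor
formula equals 1 and the order-`k` polynomial *is* the extension — the
package takes vertex agreement (tested exhaustively at small arity) as the
defining property rather than any printed factorial.

All coefficients are dyadic rationals and centered monomials at binary
points are powers of 1/2, so evaluating a full-order polynomial at a binary
state is exact in double precision. This is what lets "MAE exactly 0" be a
meaningful floating-point predicate rather than a tolerance.

`approximate_network()` reduces each rule to essential inputs, truncates at
`min(m, k)` and clips node values to `[0,1]` after every update. The mean
approximation error runs the Boolean network and its approximation for a
fixed number of synchronous steps (default 25) from shared random binary
initial states and averages the squared coordinate differences of the final
states. Two numerical decisions matter:

* **Per-coordinate normalization.** The error divides by the number of
  nodes as well as by the number of initial states. This is what puts the
  "continuous system stuck at 1/2" plateau at 0.25 regardless of network
  size, the scale on which the results are interpreted.
* **Literal long-term comparison.** The two systems are compared after
  exactly `steps` updates, not after phase alignment on attractors. A pair
  of trajectories that reach the same cycle time-shifted therefore scores a
  positive error; this artifact is inherited deliberately, because the
  plateau interpretation depends on it. Attractor-aware variants are out of
  scope.
* **Shared initial states.** Within a network, all approximation orders use
  the same initial states and the same Boolean endpoint (variance
  reduction); runners draw initial states without replacement, and use the
  whole state space when it has at most `n_ic` states.

## Dynamics metrics

Exact analysis enumerates the full state space (cap `max_n = 20` by
default, overridable) and assigns every state to its basin; sampled analysis
follows 1000 distinct random initial states to the first repeated state,
with the attractor length measured between the first and second visit.
Sampling without replacement removes small-network bias, and when
`2^n <= n_ic` the "sample" is the whole space, which makes the sampled and
exact sets coincide — a tested invariant. Attractors are identified by the
lexicographically minimal rotation of their cycle, a deterministic
deduplication. Basin entropy uses the natural logarithm. The sampled
attractor count is a lower bound of the true count. Mean attractor length
and steady-state proportion are reported both unweighted (the primary
versions) and basin-weighted.

The network mean of per-rule average sensitivity (the Derrida coefficient)
is computed exhaustively per rule, not by perturbation sampling.

## Null models

All null models share the reference's essential wiring and replace rules
node by node: type 1 preserves the ones-count (a uniform random size-`q`
subset of inputs mapped to 1), type 2 the exact canalizing depth, type 3
both, by reusing the reference's canalized output sequence and core
ones-count. External parameters are copied unchanged — in particular a
replacement equal to the self-negation is never accepted for them — and,
conversely, a self-regulating non-external node is never allowed to receive
the self-identity, which would create a new external parameter; the
reference literature is silent on this reverse direction, so the package
closes it explicitly. Constant reduced rules carry no degrees of freedom and
are copied in every type. Unconstrained and type-1 replacements are
resampled to non-degeneracy by default (`require_nondegenerate = TRUE`);
only non-constancy is enforced when the flag is off, since published usage
states only "non-constant" for the unconstrained ensemble. Every ensemble
draw is audited: measured degree, ones-count and depth per rule are checked
against the type's contract in the tests.

## Random ensembles and what they stand in for

`random_network()` generates modified N–K Kauffman networks: per-node
uniform choice of `K` distinct non-self regulators, full regeneration until
the digraph is strongly connected (rejection preserves the uniform
conditional distribution; local rewiring would not), rules per family —
unbiased-or-biased Bernoulli tables, their non-degenerate variant, minimal
canalizing depth `d`, or NCFs with a fixed layer structure. Duplicate
wiring diagrams across replicates are allowed.

`pseudo_biological_network()` is a clearly synthetic stand-in for a corpus
of expert-curated models: in-degrees from a shifted Poisson (mean 2.5,
truncated at 10, mirroring the sparsity and the exclusion of very
high-degree rules in curated collections), 95% nested canalizing rules by
default, and a configurable number of external parameters. It emulates
corpus-level summary statistics only — it has no modular structure, no
signed-motif enrichment, no realistic out-degree hubs — so pipeline results
on it demonstrate that the machinery behaves as designed, not that any
biological claim holds; corpus-scale biological magnitudes require the real
curated models, which can be dropped in as `.bnet`-style rule files via
`read_rules()`.

## Statistics layer

Spearman screens use average ranks (`stats::cor`), with constant columns
reported as `NA` plus a warning rather than a silent zero. Paired
comparisons use the two-sided Wilcoxon signed-rank test with the classical
convention of dropping zero differences; an all-zero comparison is flagged
degenerate instead of tested. No multiplicity adjustment is applied —
p-values are reported raw, and the output says so.

The LASSO solves the `(1/N) ||y − X b||² + alpha ||b||₁` objective by cyclic
coordinate descent with warm starts along a decreasing log-spaced penalty
grid, stopping when a configurable number of predictors (default 9) has
entered. The `1/N` scaling (rather than `1/2N`) is part of the definition —
it shifts the penalty axis by a factor of 2 relative to solvers using the
half scaling, and the tests pin the correspondence (`lambda = alpha/2`)
against an independent solver as well as the subgradient optimality
conditions at `1e-8`. Inputs must be standardized by the caller
(`standardize_columns()`); unstandardized input is an error because silent
rescaling would silently change the penalty scale. The exact penalty grid
is not canonical; a log-spaced grid over three decades below the smallest
all-zero penalty, extended downward on demand, is used with the stop rule.

Motif counts (feed-forward loops, simple 3- and 4-cycles) are taken on the
essential wiring diagram with self-loops removed; FFL coherence
classification needs edge signs, which Boolean truth tables do not supply
canonically, and is deliberately not computed. Effective-connectivity and
canalizing-strength predictors are likewise out of scope (extension hooks:
any per-rule statistic can be added as a column to `predictor_table()`).

## Problem sizes and determinism

The published experiments use on the order of 100 networks per condition
with 1000 initial states and 25 update steps. The package keeps 1000/25 as
defaults and scales the *number of networks* in its own test and acceptance
runs: 20 per `(K, p)` cell for the 400-network grid, 30 per condition for
error-level means, 10–20 for exactness checks, 1000 functions for
sensitivity means. These sizes were chosen once so that every stochastic
assertion sits several standard errors inside its tolerance; they are the
package's desk-scale defaults, and every runner exposes `reps` to run at
publication scale. All generators draw from R's global RNG: a single
`set.seed()` makes any figure-style experiment bit-reproducible, and
rejection samplers carry explicit caps with deterministic errors.

## Known limitations

* Exact attractor enumeration is O(2^n) in memory and time; beyond
  `n ≈ 20` only sampled analysis is practical.
* The MAE's fixed-horizon comparison conflates genuine divergence with
  attractor phase shifts (see above).
* The canalization report is exponential in arity (it manipulates full
  truth tables); arities beyond ~15 are impractical, which matches the
  in-degree range of curated models the design targets.
* `sampled_attractors()` underestimates the attractor count by design;
  weighted and unweighted landscape metrics are both reported so the
  sampling bias is visible.
* The pseudo-biological generator is a statistical stand-in only (see
  above); no conclusion about real regulatory networks should be read off
  it.
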
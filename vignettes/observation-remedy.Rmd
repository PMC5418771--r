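---
title: "Designing minimum observation remedies for network identifiability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing minimum observation remedies for network identifiability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obsremedy)
```

## The model and its assumptions

obsremedy works on linear recursive structural equation models: a
directed acyclic graph G = (V, E) with node variables
$Y_i = \sum_j c_{ij} Y_j + \varepsilon_i$, independent error terms, and
one unknown coefficient per edge ($c_{ij}$ sits on the edge
$V_j \to V_i$; $N_u = |E|$). Feedback loops, bidirected (correlated
error) arcs and nonlinear or dynamic models are out of scope; cyclic or
bidirectional input is rejected at load time.

The package uses the *standardized* convention of Wright's path
analysis: every node variable is scaled to unit variance, so the
coefficients are path coefficients and the observable quantities are the
correlations of observed node pairs. Under this convention the
correlation of a d-connected pair is exactly the sum over *simple treks*
(collider-free walks made of two directed paths descending from a common
top node, sharing no node but the top) of the product of edge
coefficients along the trek. This is the convention the whole counting
machinery is built on, and it is also what makes the package internally
consistent: the off-diagonal entries of `implied_covariance()` equal the
monomial sums of `build_equation()` to machine precision, which the test
suite asserts on random networks. Error variances never appear as
unknowns; only edge coefficients are counted, and variance (same-node)
equations are excluded everywhere.

"Identifiable" always means *generically, at least locally*: a finite
number of parameter values compatible with the observable correlations,
for parameter values outside a measure-zero set. Sign ambiguities — e.g.
flipping all coefficients out of an unobserved source — are inherent and
deliberate: local identifiability is the target, matching what
measurement of the remaining nodes can ever deliver.

## Counting non-redundant equations

Each d-connected pair of observed nodes contributes one polynomial
identifiability equation. The cardinality f(O) of a strategy O is the
number of *non-redundant* such equations; all coefficients are at least
locally identifiable when $f(O) \ge N_u$. f is accumulated by inserting
the observed nodes one at a time and adding the per-node
*identifiability gain*. For a newly observed node $u$ and each observed
partner $w$:

* **Direct edges.** If a single edge joins $w$ and $u$, the new equation
  is counted as non-redundant: it is the only equation in which that
  edge coefficient appears linearly on its own.
* **Blocked paths.** If every trek between $w$ and $u$ passes some other
  observed node, the new equation is redundant — its information is a
  composition of shorter, already-counted relations — *unless* a
  detour-path intervenes (next paragraph).
* **Detour-paths.** A detour-path is a directed segment from an observed
  *collider* node to an observed *downstream* node, witnessed by an
  observed *upstream* node whose path enters the collider and by an
  alternative, internally unobserved route that also enters the
  collider. The Wright coefficient of the segment behaves like a single
  compound parameter. It counts as determined when it has an exclusive
  upstream witness, or when an intersecting group of detour-paths has at
  least as many pooled shared upstream nodes as members. When a blocked
  pair's treks carry a detour-path whose coefficient is *not yet*
  determined, the new equation is kept: it is what determines the
  compound coefficient. One subtlety matters here: for the pair
  $(w, u)$, a witness equal to $w$ itself cannot certify the detour,
  because that would be the pair's own equation certifying itself — so
  the package requires either determination before $u$ is observed or an
  exclusive witness other than $w$ after it.
* **On-path insertions.** If $u$ lies on a trek between two observed
  nodes $a, b$ and every trek between them is blocked once $u$ counts as
  observed (again with determined detour coefficients), one of the two
  new equations IE(a, u), IE(b, u) is redundant: the old equation
  IE(a, b) becomes a composition of the new ones.

When several on-path structures fire at once, the package counts the
discards by a maximum matching: each structure may discard one of its
own two equations, each equation at most once, and a structure one of
whose equations is already discarded adds nothing (it restates a known
dependency). A matching — rather than greedy processing in some order —
is used because the count must not depend on the order in which
structures are examined; triangle configurations (an unobserved
pass-through node with one observed parent and two observed children)
genuinely need all three discards, while chain configurations need
fewer.

## The edge-removal route

Computing the gain of observing $V$ through all pairwise rules is the
*reference* route (`method = "lemmas"`). The default route
(`method = "removal"`) follows the graphical shortcut: delete (i) the
in-edges of observed ancestors of $V$ that are not detour-path
colliders, (ii) the out-edges of observed descendants and relatives that
are not colliders of undetermined detour-paths, and (iii) the edges from
observed boundary ancestors into the relative set. In the reduced graph
G′ only "fresh" connections survive; the gain is the number of observed
nodes still trek-connected to $V$ (that is $N_w$) minus the residual
redundancies $N_r$ among those pairs, so $g = N_w - N_r$. The package
evaluates the residual-redundancy predicates on the *original* graph
restricted to the surviving pairs: the identifiability equations are
properties of the model, not of the pruned graph, and this choice makes
the two routes agree exactly on the package's randomized cross-check
suite. `method = "both"` runs both routes on every call and raises a
classed error on disagreement — the recommended self-audit mode for
anything unusual.

## Must-be-observed nodes and the dynamic program

Three degree rules give nodes whose observation is necessary: sinks
(out-degree 0), out-degree-1 nodes, and sources with out-degree below 3.
Their coefficients either appear in no observable correlation or only in
products with a one-dimensional scaling freedom. The search therefore
starts from the element-wise OR of the user's strategy with this
must-be-observed set. One boundary case: an isolated node is formally a
sink, hence forced, but carries no coefficient — observing it is
harmless but vacuous, and necessity arguments do not apply to it.

The search itself is a stage/state dynamic program: stage k has one
state per unobserved node (in canonical order, which is first-appearance
order in the input), state j at stage k is reachable from states i < j
at stage k − 1 — a triangular layout that enumerates each subset once —
and transitions maximize gain plus predecessor value. Two design choices
deserve note:

* Each state stores its realized observed set, because the gain depends
  on the whole set, not the last added node.
* A state's value is the cardinality of its realized set *recomputed
  from scratch* (canonical insertion), with the transition maximization
  used to choose predecessors. Accumulated and recomputed values agree
  in the vast majority of cases; where they differ (see Limitations) the
  recomputed value is authoritative and the difference is logged on the
  result as a divergence note.

The program stops at the first stage where a state reaches
$f \ge N_u$. Ties in the maximization keep all argmax back-pointers;
`all_optimal = TRUE` enumerates every minimum-size strategy (duplicates
removed), and all reported strategies are returned regardless of how far
their f exceeds $N_u$. If no stage reaches the threshold the result is
flagged infeasible rather than asserted impossible. An exhaustive
verifier (`exhaustive_remedy()`) enumerates supersets of the initial
strategy by increasing size under the same criterion — or, in oracle
mode, under the Jacobian-rank criterion — and is the reference the
dynamic program is tested against.

## The independent oracle

`jacobian_identifiable()` never touches the trek machinery. It evaluates
the implied correlation matrix by the exact recursion
$r_{ab} = \sum_{p \in \mathrm{pa}(b)} c_{bp}\, r_{ap}$ in topological
order, differentiates that recursion analytically to get the Jacobian of
the coefficient → observed-pair-correlation map, evaluates it at random
parameter points (coefficients drawn from ±[0.5, 1.5], bounded away from
zero to avoid measure-zero degeneracies), and takes the maximum
numerical rank across draws, with singular values below $10^{-8}$ of the
largest treated as zero. Rank equal to $N_u$ certifies generic local
identifiability; the per-coefficient status vector flags the columns
participating in the null space. Three draws are the default — the
generic rank is attained almost surely, and the suite checks rank
stability across draws — and the analytic Jacobian is itself verified
against central finite differences at $10^{-6}$ relative tolerance.

## The synthetic generator and what passing tests mean

`random_dag(n, p, seed)` draws a uniformly random node order and includes
each forward pair independently with probability p — an Erdős–Rényi
model over a random order, acyclic by construction. It emulates the
*combinatorics* of sparse biological topologies (density is controlled by
p, defaulting in the test suite to 0.35 on 4–9 nodes with observation
probability 0.5, sizes chosen so exhaustive verification stays
enumerable), but not their degree heterogeneity, modularity or
hub structure; scale-free or biologically motivated generators are
future work. Passing randomized tests therefore supports correctness of
the algorithms on arbitrary DAGs of moderate size, not calibration to
any particular biological network class. The named fixtures (chain,
fork, star, diamond, collider-with-detour, two-factor) pin every rule to
hand-derivable values, and `benchmark_family(s)` builds the scalable
two-choices-plus-decoys family used to measure the empirical complexity
of the dynamic program (the gain-evaluation count grows at most
quadratically in the unobserved-node count there, consistent with the
triangular state space and early stopping).

## Numerical and interface choices

* Canonical node order = first appearance in the input file; all
  deterministic tie-breaking, DP staging and printed output derive from
  it, so runs are byte-reproducible.
* Monomials are canonical sorted edge-id tuples with multiplicities; no
  symbolic algebra anywhere.
* Trek enumeration is depth-first with reachability pruning; exponential
  worst case is accepted (networks of interest are sparse) behind a
  node-count cap (`options(obsremedy.trek_node_cap = )`, default 100)
  with a classed error.
* Degenerate inputs: empty networks give $N_u = 0$ and vacuous
  identifiability; d-separated pairs raise a distinct condition rather
  than a redundancy verdict; isolated nodes are admitted and contribute
  nothing.
* All randomness (parameter draws, random DAGs, random strategies) is
  seed-scoped and restores the caller's RNG state.

## Known limitations

The redundancy rules are *pairwise*: each rule inspects one new pair or
one (pair, inserted node) triple. There exist configurations — typically
several direct-edge-protected equations that are jointly dependent
through substitution chains — where the true dependency involves three
or more new equations at once and no pairwise rule fires, or fires only
under some insertion orders. Three consequences, all quantified by the
shipped verification machinery rather than hidden:

* f can differ across insertion orders on a small fraction of dense
  random instances (about 5% of the randomized family above);
* f can overcount at the stopping threshold, so a remedy can satisfy
  $f \ge N_u$ while the rank oracle reports a deficient rank (under 5%
  of randomized runs) — which is why `find_remedy(verify = "oracle")`
  attaches the oracle verdict per strategy and flags disagreements, and
  why the oracle-mode exhaustive search exists;
* very rarely f undercounts even at full observation, producing a
  spurious infeasibility flag.

For planning a real panel the recommended workflow is therefore:
`find_remedy(net, given, all_optimal = TRUE, verify = "oracle")`, treat
the oracle column as the final word on each strategy, and escalate to
`exhaustive_remedy(criterion = "oracle")` when the number of unobserved
nodes after initialization is small enough to enumerate.
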
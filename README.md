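# obsremedy

Minimum additional observations for structural identifiability of
directed biological networks.

## The problem

Biological networks — gene regulatory circuits, signalling cascades,
virus replication pathways — are routinely modelled as **linear recursive
structural equation models** on a directed acyclic graph G = (V, E):

    Y_i = Σ_j c_ij Y_j + ε_i

where `c_ij` is the unknown coefficient on the edge V_j → V_i and the
error terms are independent. In practice only some node variables can be
measured (cost, assay limits, ethics), and with a partial observation
scheme many edge coefficients are not even *structurally* identifiable —
no amount of data determines them. The question this package answers is
the experiment-design one: **which minimum set of currently unobserved
nodes should be measured so that every edge coefficient becomes at least
locally identifiable?**

It is aimed at systems biologists and statisticians planning measurement
panels on a known network topology, before any data are collected.

## The method

Identifiability is counted through Wright's path-coefficient rules. For
each d-connected pair of observed nodes, the observable covariance equals
a sum of monomials, one per *trek* (a collider-free walk formed by two
directed paths from a common top node):

    Cov(V_i, V_j) = Σ_treks Π_edges c

The number of *non-redundant* equations available under a strategy O is
its cardinality f(O); all N_u = |E| coefficients are at least locally
identifiable when f(O) ≥ N_u. Rather than doing symbolic algebra, f is
accumulated graphically, one observed node at a time, through a small set
of redundancy rules:

* a new pair joined by a single edge always contributes a fresh equation;
* a new pair whose every trek passes another observed node is redundant —
  unless a *detour-path* (a directed segment from an observed collider to
  an observed downstream node, witnessed by an upstream observed node and
  an unobserved alternative route into the collider) carries a Wright
  coefficient that is not yet determined;
* observing a node that sits on a blocked path between two observed
  nodes makes one of its two new equations redundant.

The per-node **identifiability gain** g(V, O) = N_w − N_r is computed on
an edge-removal subgraph (N_w: observed nodes still trek-connected to V;
N_r: residual redundancies), and a stage/state **dynamic program** over
the unobserved nodes — seeded with the *must-be-observed* nodes
(out-degree 0, out-degree 1, or sources with out-degree < 3) — finds all
minimum-cardinality remedies, stopping as soon as f reaches N_u.

Every result can be cross-checked against an independent oracle: the
generic rank of the analytic Jacobian of the coefficient → covariance map
of the standardized model, plus an exhaustive subset-search verifier.

## Worked example

A two-factor design: two unobserved source factors `s1`, `s2` each drive
three measurable indicators `x1`–`x3`. Which source must be measured?

```r
library(obsremedy)

net <- as_network(data.frame(
  from = c("s1","s1","s1","s2","s2","s2"),
  to   = c("x1","x2","x3","x1","x2","x3")))

must_be_observed(net)
#> # A tibble: 3 × 4
#>   node  in_degree out_degree reason
#>   <chr>     <int>      <int> <chr>
#> 1 x1            2          0 out-degree 0
#> 2 x2            2          0 out-degree 0
#> 3 x3            2          0 out-degree 0

remedy <- find_remedy(net, all_optimal = TRUE, verify = "oracle")
remedy
#> <obsremedy_remedy> N_u = 6, f(O0) = 3, stopped at stage 1 (ok)
#> initial observed (given | must-be-observed): x1, x2, x3
#> strategy 1: add {s1}  f = 6  oracle: identifiable
#> strategy 2: add {s2}  f = 6  oracle: identifiable
```

Reading: the three indicators are forced observations (sinks can never be
skipped); they provide f = 3 non-redundant equations against N_u = 6
unknown coefficients. Observing *either* source adds 3 more, reaching
f = N_u, and the rank oracle confirms that both one-node remedies make
all six coefficients locally identifiable — so one extra assay suffices,
and the two choices are interchangeable. `tidy(remedy)` returns the
strategies as a tibble, `glance(remedy)` the one-row summary, and
`autoplot(remedy)` the cardinality trace over DP stages.

The symbolic equations themselves are available too:

```r
build_equation(network_fixture("diamond4"), "1", "4")
#> Cov(1,4) = c42*c21 + c43*c31
```

A thin command-line interface mirrors the R functions
(`exec/obsremedy remedy NET.tsv --all-optimal --verify oracle`,
plus `gain`, `cardinality`, `mbo`, `detours`, `treks`, `check`,
`simulate`). Networks load from edge-list TSV, SIF or GraphML; a
published network such as the 22-node influenza-A virus replication
module can be run through the same pipeline once its edge list is saved
as a TSV.

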
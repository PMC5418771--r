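# Shared test helpers: independent brute-force oracles and small utilities.
# These deliberately avoid the package's trek/path internals so that they
# can serve as independent references.

# All simple collider-free walks between a and b, enumerated directly on
# the edge list: walk backwards over in-edges (ascending phase), switch at
# most once to walking forwards over out-edges (descending phase), never
# repeat a node. Returns the walk count.
brute_trek_count <- function(net, a, b) {
  edges <- network_edges(net)
  parents <- split(edges$from, edges$to)
  children <- split(edges$to, edges$from)
  n_found <- 0L
  walk <- function(cur, visited, descending) {
    if (cur == b && length(visited) > 1) {
      n_found <<- n_found + 1L
      return(invisible())
    }
    if (cur == b) return(invisible()) # a == b excluded upstream
    if (!descending) {
      for (p in parents[[cur]]) {
        if (!(p %in% visited)) walk(p, c(visited, p), FALSE)
      }
    }
    for (ch in children[[cur]]) {
      if (!(ch %in% visited)) walk(ch, c(visited, ch), TRUE)
    }
  }
  # handle b reachable directly where the first move descends or ascends
  walk(a, a, FALSE)
  n_found
}

# Generic rank of the coefficient -> observed-pair-covariance map,
# via the package's matrix-recursion Jacobian (independent of the trek
# code path under test).
jacobian_rank <- function(net, observed_nodes) {
  v <- jacobian_identifiable(net, observed_nodes, trials = 3L, seed = 7L)
  v$rank
}

# Evaluate an identifiability equation at a parameter draw.
eval_equation <- function(eq, values) {
  if (!length(eq$monomials)) return(0)
  sum(vapply(seq_along(eq$monomials), function(i) {
    eq$multiplicity[i] * prod(values[eq$monomials[[i]]])
  }, numeric(1)))
}

# The criterion-1 style random instance family used across tests.
random_instance <- function(seed) {
  n <- 4 + (seed %% 6)
  net <- random_dag(n, 0.35, seed = seed)
  strat <- random_strategy(net, 0.5, seed = 1000 + seed)
  list(net = net, strategy = strat, obs = as_strategy(net, strat))
}

fixture_names <- c("chain3", "fork3", "star4", "diamond4", "collider5", "bifactor5")
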
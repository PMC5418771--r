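# Random-DAG generation and the named hand-analyzable fixture library used
# across the test-suite and the examples.

fixture_edges <- list(
  chain3 = list(nodes = c("1", "2", "3"),
                from = c("1", "2"), to = c("2", "3")),
  fork3 = list(nodes = c("1", "2", "3"),
               from = c("1", "1"), to = c("2", "3")),
  star4 = list(nodes = c("1", "2", "3", "4"),
               from = c("1", "1", "1"), to = c("2", "3", "4")),
  diamond4 = list(nodes = c("1", "2", "3", "4"),
                  from = c("1", "1", "2", "3"), to = c("2", "3", "4", "4")),
  collider5 = list(nodes = c("I", "K", "U", "J", "W"),
                   from = c("I", "U", "K", "U", "U"),
                   to = c("K", "K", "J", "J", "W")),
  bifactor5 = list(nodes = c("s1", "x1", "x2", "x3", "s2"),
                   from = c("s1", "s1", "s1", "s2", "s2", "s2"),
                   to = c("x1", "x2", "x3", "x1", "x2", "x3"))
)

#' Named hand-analyzable fixture networks
#'
#' Small networks whose identifiability behaviour can be worked out by
#' hand; they anchor the test-suite and the examples:
#' * `chain3` — `1 -> 2 -> 3`;
#' * `fork3` — `1 -> 2`, `1 -> 3`;
#' * `star4` — hub `1` with three leaves;
#' * `diamond4` — `1 -> {2,3} -> 4`;
#' * `collider5` — `I -> K <- U`, `K -> J <- U`, `U -> W` (the canonical
#'   detour-path example: segment `K -> J` with collider `K`, downstream
#'   `J`, upstream `I`);
#' * `bifactor5` — two source factors `s1`, `s2` each loading on the three
#'   indicators `x1`, `x2`, `x3` (two equally good remedies exist).
#'
#' @param name Fixture name (case-insensitive).
#' @return An `obsremedy_network` with the frozen canonical node order.
#' @export
network_fixture <- function(name = c("chain3", "fork3", "star4", "diamond4",
                                     "collider5", "bifactor5")) {
  name <- match.arg(tolower(name), names(fixture_edges))
  fx <- fixture_edges[[name]]
  as_network(data.frame(from = fx$from, to = fx$to, stringsAsFactors = FALSE),
             nodes = fx$nodes)
}

#' Generate a random DAG
#'
#' Fixes a random topological order of `n` nodes and includes each forward
#' pair independently with probability `p` (an Erdos-Renyi draw over a
#' random order), so the result is acyclic by construction. Node
#' identifiers are `"1" ... "n"` and the canonical node order is numeric.
#'
#' @param n Number of nodes (at least 1).
#' @param p Edge inclusion probability in \[0, 1\].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return An `obsremedy_network`.
#' @examples
#' random_dag(6, 0.4, seed = 1)
#' @export
random_dag <- function(n, p, seed = 1L) {
  if (n < 1) rlang::abort("`n` must be at least 1", class = "obsremedy_param_error")
  if (p < 0 || p > 1) rlang::abort("`p` must be in [0, 1]",
                                   class = "obsremedy_param_error")
  dr <- with_local_seed(seed, {
    ord <- sample.int(n)
    pick <- if (n > 1) stats::runif(n * (n - 1) / 2) <= p else logical(0)
    list(ord = ord, pick = pick)
  })
  from <- integer(0)
  to <- integer(0)
  if (n > 1) {
    idx <- 0L
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        idx <- idx + 1L
        if (dr$pick[idx]) {
          from <- c(from, dr$ord[i])
          to <- c(to, dr$ord[j])
        }
      }
    }
  }
  nodes <- as.character(seq_len(n))
  as_network(data.frame(from = nodes[from], to = nodes[to],
                        stringsAsFactors = FALSE),
             nodes = nodes)
}

#' Generate a random observation strategy
#'
#' Each node is observed independently with probability `q`.
#'
#' @param net A network (anything accepted by [as_network()]).
#' @param q Observation probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A tibble with columns `node` and `observed`, one row per node.
#' @export
random_strategy <- function(net, q, seed = 1L) {
  net <- as_network(net)
  if (q < 0 || q > 1) rlang::abort("`q` must be in [0, 1]",
                                   class = "obsremedy_param_error")
  obs <- with_local_seed(seed, stats::runif(net$n) <= q)
  tibble::tibble(node = net$nodes, observed = obs)
}

#' Scalable benchmark family for the dynamic program
#'
#' Builds a network whose post-initialization unobserved set has exactly
#' `s` nodes while the remedy always needs exactly two additional
#' observations: two "choice" blocks (two unobserved source factors
#' loading on three observed indicators each; one source per block must be
#' observed) plus `s - 4` "decoy" gadgets (an observed parent feeding an
#' unobserved pass-through node with two observed children, whose three
#' coefficients are already identifiable, so observing the pass-through
#' node gains nothing). Used to measure how the number of gain
#' evaluations scales with the number of unobserved nodes.
#'
#' @param s Total number of unobserved nodes after initialization
#'   (at least 4).
#' @return An `obsremedy_network`.
#' @export
benchmark_family <- function(s) {
  if (s < 4) rlang::abort("`s` must be at least 4", class = "obsremedy_param_error")
  from <- character(0)
  to <- character(0)
  add <- function(f, t) {
    from <<- c(from, f)
    to <<- c(to, t)
  }
  for (blk in c("A", "B")) {
    for (src in c("s1", "s2")) {
      for (x in c("x1", "x2", "x3")) {
        add(paste0(blk, src), paste0(blk, x))
      }
    }
  }
  for (d in seq_len(s - 4)) {
    dn <- paste0("d", d)
    add(paste0("a", d), dn)
    add(dn, paste0("p", d))
    add(dn, paste0("q", d))
  }
  as_network(data.frame(from = from, to = to, stringsAsFactors = FALSE))
}
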
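# Redundancy predicates, the edge-removal construction, identifiability
# gain and the strategy cardinality f(O).
#
# f(O) counts the non-redundant identifiability equations available under
# strategy O; all parameters are at least locally identifiable when
# f(O) >= N_u (the number of edge coefficients). The gain of observing an
# unobserved node is the resulting increase in f, computed graphically.

the_counters <- new.env(parent = emptyenv())
the_counters$gain_calls <- 0L

#' Count (or reset) identifiability-gain evaluations
#'
#' Every call to the gain engine increments an internal counter; the
#' dynamic program's empirical complexity is measured by counting these
#' calls.
#'
#' @param reset If `TRUE`, reset the counter to zero after reading it.
#' @return The number of gain evaluations since the last reset.
#' @export
gain_call_count <- function(reset = FALSE) {
  x <- the_counters$gain_calls
  if (reset) the_counters$gain_calls <- 0L
  x
}

# ---- Lemma 1/4: redundancy of the equation added by a brand-new pair ----

# i: node observed in obs; u: the node that becomes observed. Returns TRUE
# when IE(i, u) is redundant. Raises a classed condition when the pair is
# d-separated (no equation exists at all).
pair_redundant_int <- function(net, obs, i, u) {
  trks <- treks_between(net, i, u)
  if (!length(trks)) {
    rlang::abort("pair is d-separated: no identifiability equation exists",
                 class = "obsremedy_d_separated")
  }
  # Lemma 1: a length-1 Wright's path makes the new equation non-redundant
  if (any(vapply(trks, function(t) length(t$edges) == 1L, logical(1)))) {
    return(FALSE)
  }
  # both lemma cases require every Wright's path between the pair to pass
  # at least one node observed in O (excluding the endpoints)
  blocked <- all(vapply(trks, function(t) any(obs[trek_interior(t)]), logical(1)))
  if (!blocked) return(FALSE)
  # detour-paths lying on a Wright's path between the pair, detected with u
  # observed (the downstream role may be u itself)
  rel <- detours_on_pair(net, obs, u, trks)
  if (!length(rel)) return(TRUE)
  # Lemma 4 case 2: additionally every such detour-path's Wright
  # coefficient must be determined without the pair's own equation:
  # either globally identifiable already in O (before u is observed), or
  # certified after observing u by an exclusive upstream witness other
  # than the pair's endpoint i (a witness equal to i would be the pair's
  # own equation certifying itself).
  obs_u <- obs
  obs_u[u] <- TRUE
  st_u <- wp_status(net, obs_u)
  all(vapply(rel, function(d) {
    if (wp_identifiable_under(net, obs, d)) return(TRUE)
    hit <- match(detour_key(d), st_u$keys)
    !is.na(hit) && length(setdiff(st_u$exclusive[[hit]], i)) > 0
  }, logical(1)))
}

# Detour-paths (under obs with `u` switched on) contained in at least one
# of the given treks; containment = the segment's edges all lie on the
# trek and the trek enters the collider with an arrow (collider != top).
detours_on_pair <- function(net, obs, u, trks) {
  obs_u <- obs
  obs_u[u] <- TRUE
  dd <- find_detours_int(net, obs_u)
  Filter(function(d) {
    any(vapply(trks, function(t) {
      d$collider != t$top && all(d$seg_edges %in% t$edges)
    }, logical(1)))
  }, dd)
}

# ---- Lemma 5: redundancy created by observing a node on a path ----

# a, b observed and d-connected; u (unobserved) lies on a Wright's path
# between them. TRUE when exactly one of IE(a, u) / IE(b, u) is redundant.
# For the blocking condition u itself counts as observed (it is on the
# path and becomes observed).
onpath_redundant_int <- function(net, obs, a, b, u, check_pre = TRUE) {
  trks <- treks_between(net, a, b)
  if (!length(trks)) {
    rlang::abort("pair is d-separated: no identifiability equation exists",
                 class = "obsremedy_d_separated")
  }
  if (check_pre && !any(vapply(trks, function(t) u %in% trek_interior(t), logical(1)))) {
    rlang::abort("node is not on any Wright's path between the pair",
                 class = "obsremedy_not_on_path")
  }
  obs_u <- obs
  obs_u[u] <- TRUE
  blocked <- all(vapply(trks, function(t) any(obs_u[trek_interior(t)]), logical(1)))
  if (!blocked) return(FALSE)
  rel <- detours_on_pair(net, obs, u, trks)
  if (!length(rel)) return(TRUE)
  all(vapply(rel, function(d) wp_identifiable_under(net, obs, d), logical(1)))
}

# ---- shared counting engine ----

# Maximum matching between Lemma-5 structures (each may discard one of its
# two implicated equations) and the pool of equations not already
# discarded by Lemma 4; each equation can be discarded at most once.
# `structs` is a list of integer pairs (node indices); `pool` the available
# equation owners. Kuhn's augmenting-path algorithm; sizes are tiny.
l5_matching_count <- function(structs, pool) {
  if (!length(structs) || !length(pool)) return(0L)
  pool_pos <- match(seq_len(max(c(pool, unlist(structs)))), pool)
  owner <- rep(NA_integer_, length(pool))   # pool slot -> structure
  try_assign <- function(s, seen) {
    for (v in structs[[s]]) {
      slot <- pool_pos[v]
      if (is.na(slot) || seen[slot]) next
      seen[slot] <- TRUE
      if (is.na(owner[slot]) || Recall(owner[slot], seen)) {
        owner[slot] <<- s
        return(TRUE)
      }
    }
    FALSE
  }
  matched <- 0L
  for (s in seq_along(structs)) {
    if (try_assign(s, rep(FALSE, length(pool)))) matched <- matched + 1L
  }
  matched
}

# Count the non-redundant equations gained when `focal` becomes observed.
# Treks/detours are always taken in the original graph `g` (the
# identifiability equations are properties of the model, not of the
# pruned graph); `W_keep` optionally restricts the candidate pairs to the
# observed nodes still trek-connected to focal in the edge-removal
# subgraph (Theorem-1 route). Returns counts plus an audit.
count_gain_int <- function(g, obs, focal, W_keep = NULL) {
  W <- which(obs & d_connected_vec(g, focal))
  if (!is.null(W_keep)) W <- intersect(W, W_keep)
  if (!length(W)) {
    return(list(W = W, n_candidates = 0L, l4 = integer(0), structs = list(),
                live_structs = list(), n_l5 = 0L, gain = 0L))
  }
  l4 <- integer(0)
  for (w in W) {
    if (pair_redundant_int(g, obs, w, focal)) l4 <- c(l4, w)
  }
  structs <- list()
  if (length(W) >= 2) {
    for (ai in seq_len(length(W) - 1L)) {
      for (bi in seq.int(ai + 1L, length(W))) {
        a <- W[ai]; b <- W[bi]
        trks <- treks_between(g, a, b)
        if (!length(trks)) next
        if (!any(vapply(trks, function(t) focal %in% trek_interior(t), logical(1)))) next
        if (onpath_redundant_int(g, obs, a, b, focal, check_pre = FALSE)) {
          structs[[length(structs) + 1L]] <- c(a, b)
        }
      }
    }
  }
  # a structure whose pair already contains a discarded equation restates
  # a known dependency and contributes no additional discard
  live <- Filter(function(s) !any(s %in% l4), structs)
  pool <- setdiff(W, l4)
  n_l5 <- l5_matching_count(live, pool)
  list(W = W, n_candidates = length(W), l4 = l4, structs = structs,
       live_structs = live, n_l5 = n_l5,
       gain = length(W) - length(l4) - n_l5)
}

# ---- Theorem 1: edge-removal construction ----

# Edges to delete from G for focal (unobserved in obs). Detour structures
# are detected with focal observed; Wright-coefficient identifiability is
# judged in obs itself.
removal_edge_ids <- function(net, obs, focal) {
  obs_u <- obs
  obs_u[focal] <- TRUE
  dd <- find_detours_int(net, obs_u)
  colliders_any <- unique(vapply(dd, `[[`, integer(1), "collider"))
  if (length(dd)) {
    unident <- vapply(dd, function(d) !wp_identifiable_under(net, obs, d), logical(1))
    colliders_unident <- unique(vapply(dd[unident], `[[`, integer(1), "collider"))
  } else {
    colliders_unident <- integer(0)
  }
  parts <- neighborhood_sets(net, focal)
  rem <- logical(net$n_edges)
  # (i) in-edges of observed non-collider ancestors
  for (a in parts$anc) {
    if (obs[a] && !(a %in% colliders_any) && length(net$adj_in[[a]])) {
      rem[net$eid[cbind(net$adj_in[[a]], a)]] <- TRUE
    }
  }
  # (ii) out-edges of observed descendants/relatives that are not collider
  # nodes of detour-paths with unidentifiable Wright coefficient
  for (v in c(parts$des, parts$rel)) {
    if (obs[v] && !(v %in% colliders_unident) && length(net$adj_out[[v]])) {
      rem[net$eid[cbind(v, net$adj_out[[v]])]] <- TRUE
    }
  }
  # (iii) edges from observed boundary ancestors into the relative set
  for (a in parts$bound) {
    if (obs[a]) {
      heads <- intersect(net$adj_out[[a]], parts$rel)
      if (length(heads)) rem[net$eid[cbind(a, heads)]] <- TRUE
    }
  }
  which(rem)
}

#' Edge-removal subgraph used by the identifiability-gain computation
#'
#' Builds the reduced graph G' for an unobserved focal node by deleting
#' (i) in-edges of observed ancestors that are not detour-path colliders,
#' (ii) out-edges of observed descendants/relatives that are not colliders
#' of detour-paths with unidentifiable Wright coefficient, and (iii) edges
#' from observed boundary ancestors into the relative set. Nodes are never
#' deleted.
#'
#' @param net A network (anything accepted by [as_network()]).
#' @param observed An observation strategy (see [as_strategy()]).
#' @param focal An unobserved node identifier.
#' @return An `obsremedy_network` (same node set); the deleted edges are
#'   attached as attribute `"removed_edges"` (a tibble).
#' @export
edge_removal_subgraph <- function(net, observed, focal) {
  net <- as_network(net)
  obs <- as_strategy(net, observed)
  fi <- node_index(net, focal)
  if (obs[fi]) {
    rlang::abort("focal node is already observed", class = "obsremedy_strategy_error")
  }
  rem <- removal_edge_ids(net, obs, fi)
  g2 <- subnetwork(net, setdiff(seq_len(net$n_edges), rem))
  attr(g2, "removed_edges") <- tibble::tibble(
    from = net$nodes[net$from[rem]],
    to = net$nodes[net$to[rem]]
  )
  g2
}

# One gain evaluation; method "removal" applies Theorem 1 (count observed
# nodes trek-connected to focal in G', minus residual redundancies in G'),
# "lemmas" exhaustively applies Lemmas 1/4/5 on the original graph,
# "both" runs the two and raises on mismatch.
gain_int <- function(net, obs, focal, method = c("removal", "lemmas", "both")) {
  method <- match.arg(method)
  the_counters$gain_calls <- the_counters$gain_calls + 1L
  res <- NULL
  if (method %in% c("removal", "both")) {
    rem <- removal_edge_ids(net, obs, focal)
    g2 <- if (length(rem)) subnetwork(net, setdiff(seq_len(net$n_edges), rem)) else net
    W_keep <- which(obs & d_connected_vec(g2, focal))
    cg <- count_gain_int(net, obs, focal, W_keep = W_keep)
    res <- list(n_w = cg$n_candidates, n_r = length(cg$l4) + cg$n_l5,
                gain = cg$gain, removed = rem, audit = cg, graph = g2)
  }
  if (method %in% c("lemmas", "both")) {
    cg0 <- count_gain_int(net, obs, focal)
    res_l <- list(n_w = cg0$n_candidates, n_r = length(cg0$l4) + cg0$n_l5,
                  gain = cg0$gain, removed = integer(0), audit = cg0, graph = net)
    if (method == "lemmas") {
      res <- res_l
    } else if (res$gain != res_l$gain) {
      rlang::abort(paste0(
        "identifiability-gain divergence for node '", net$nodes[focal],
        "': edge-removal route ", res$gain, " vs exhaustive-lemma route ",
        res_l$gain), class = "obsremedy_divergence")
    }
  }
  res
}

#' Identifiability gain of observing one node
#'
#' The gain g(V, O) is the number of additional non-redundant
#' identifiability equations obtained when the unobserved node V becomes
#' observed. The default route builds the edge-removal subgraph G' and
#' computes g = N_w - N_r there (N_w: observed nodes joined to V by a trek
#' in G'; N_r: residual redundancies found by the Lemma 4/5 rules inside
#' G'). `method = "lemmas"` instead applies the redundancy rules
#' exhaustively on the original graph; `method = "both"` runs both and
#' raises a classed error on mismatch (the package's self-audit mode).
#'
#' @param net A network (anything accepted by [as_network()]).
#' @param observed An observation strategy (see [as_strategy()]).
#' @param node The unobserved focal node.
#' @param method `"removal"` (default), `"lemmas"` or `"both"`.
#' @return An object of class `obsremedy_gain`: a list with `node`, `n_w`,
#'   `n_r`, `gain`, `removed_edges` (tibble) and an audit of redundancy
#'   findings; `tidy()` returns the one-row summary.
#' @examples
#' identifiability_gain(network_fixture("diamond4"), c("1", "2", "3"), "4")
#' @export
identifiability_gain <- function(net, observed, node,
                                 method = c("removal", "lemmas", "both")) {
  net <- as_network(net)
  obs <- as_strategy(net, observed)
  fi <- node_index(net, node)
  if (obs[fi]) {
    rlang::abort("focal node is already observed", class = "obsremedy_strategy_error")
  }
  res <- gain_int(net, obs, fi, match.arg(method))
  audit <- res$audit
  structure(
    list(
      node = net$nodes[fi],
      n_w = res$n_w,
      n_r = res$n_r,
      gain = res$gain,
      removed_edges = tibble::tibble(
        from = net$nodes[net$from[res$removed]],
        to = net$nodes[net$to[res$removed]]
      ),
      connected_observed = net$nodes[audit$W],
      audit = tibble::tibble(
        pair = c(net$nodes[audit$l4],
                 vapply(audit$structs, function(s) {
                   paste(net$nodes[s], collapse = ",")
                 }, character(1))),
        rule = c(rep("new-pair redundancy", length(audit$l4)),
                 rep("on-path redundancy", length(audit$structs)))
      )
    ),
    class = "obsremedy_gain"
  )
}

#' @export
print.obsremedy_gain <- function(x, ...) {
  cat("<obsremedy_gain> node ", x$node, ": gain = ", x$gain,
      " (N_w = ", x$n_w, ", N_r = ", x$n_r, ")\n", sep = "")
  if (nrow(x$removed_edges)) {
    cat("removed edges: ",
        paste(paste0(x$removed_edges$from, "->", x$removed_edges$to),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @method tidy obsremedy_gain
#' @export
tidy.obsremedy_gain <- function(x, ...) {
  tibble::tibble(node = x$node, n_w = x$n_w, n_r = x$n_r, gain = x$gain,
                 n_removed_edges = nrow(x$removed_edges))
}

# f for a whole strategy by sequential insertion. `order_idx` optionally
# fixes the insertion order (indices into which(obs)); default canonical.
cardinality_int <- function(net, obs, order_idx = NULL,
                            method = "removal") {
  ins <- unname(which(obs))
  if (!is.null(order_idx)) ins <- unname(order_idx)
  cur <- rep(FALSE, net$n)
  total <- 0L
  steps <- vector("list", length(ins))
  for (s in seq_along(ins)) {
    v <- ins[s]
    if (s == 1L) {
      g <- list(n_w = 0L, n_r = 0L, gain = 0L)
    } else {
      g <- gain_int(net, cur, v, method)
    }
    total <- total + g$gain
    steps[[s]] <- c(v = v, n_w = g$n_w, n_r = g$n_r, gain = g$gain, f = total)
    cur[v] <- TRUE
  }
  list(f = total, steps = steps)
}

#' Cardinality of an observation strategy
#'
#' f(O) is the number of non-redundant identifiability equations available
#' under O, accumulated by inserting the observed nodes one at a time (in
#' canonical node order by default) and summing the per-step
#' identifiability gains. The insertion order does not change f.
#'
#' @inheritParams identifiability_gain
#' @param order Optional character vector: insertion order of the observed
#'   nodes (must be exactly the observed set).
#' @return An object of class `obsremedy_cardinality` with total `f`, `n_u`
#'   and a per-step trace; `tidy()` returns the trace tibble.
#' @examples
#' cardinality(network_fixture("diamond4"), c("1", "2", "3", "4"))
#' @export
cardinality <- function(net, observed, order = NULL,
                        method = c("removal", "lemmas", "both")) {
  net <- as_network(net)
  obs <- as_strategy(net, observed)
  order_idx <- NULL
  if (!is.null(order)) {
    order_idx <- node_index(net, order)
    if (!setequal(order_idx, which(obs)) || length(order_idx) != sum(obs)) {
      rlang::abort("`order` must list exactly the observed nodes",
                   class = "obsremedy_strategy_error")
    }
  }
  res <- cardinality_int(net, obs, order_idx, match.arg(method))
  trace <- purrr::map_dfr(res$steps, function(s) {
    tibble::tibble(node = net$nodes[s[["v"]]], n_w = as.integer(s[["n_w"]]),
                   n_r = as.integer(s[["n_r"]]), gain = as.integer(s[["gain"]]),
                   f = as.integer(s[["f"]]))
  })
  if (!nrow(trace)) {
    trace <- tibble::tibble(node = character(0), n_w = integer(0),
                            n_r = integer(0), gain = integer(0), f = integer(0))
  }
  structure(
    list(f = res$f, n_u = net$n_edges, trace = trace,
         observed = net$nodes[which(obs)]),
    class = "obsremedy_cardinality"
  )
}

#' @export
print.obsremedy_cardinality <- function(x, ...) {
  cat("<obsremedy_cardinality> f = ", x$f, " (N_u = ", x$n_u, "); observed: ",
      paste(x$observed, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy obsremedy_cardinality
#' @export
tidy.obsremedy_cardinality <- function(x, ...) x$trace

#' @method glance obsremedy_cardinality
#' @export
glance.obsremedy_cardinality <- function(x, ...) {
  tibble::tibble(f = x$f, n_u = x$n_u, n_observed = length(x$observed),
                 identifiable = x$f >= x$n_u)
}

#' Is a newly added pair's identifiability equation redundant?
#'
#' Applies the length-1-path rule and the new-pair redundancy rule to the
#' equation IE(`observed_node`, `new_node`) created when `new_node` becomes
#' observed.
#'
#' @inheritParams identifiability_gain
#' @param observed_node A node observed under `observed`.
#' @param new_node The unobserved node that becomes observed.
#' @return Logical scalar. Raises a classed error (`obsremedy_d_separated`)
#'   when the pair is d-separated, since then no equation exists at all.
#' @export
new_pair_redundant <- function(net, observed, observed_node, new_node) {
  net <- as_network(net)
  obs <- as_strategy(net, observed)
  i <- node_index(net, observed_node)
  u <- node_index(net, new_node)
  if (!obs[i]) rlang::abort("`observed_node` must be observed",
                            class = "obsremedy_strategy_error")
  if (obs[u]) rlang::abort("`new_node` must be unobserved",
                           class = "obsremedy_strategy_error")
  pair_redundant_int(net, obs, i, u)
}

#' Does observing an on-path node make one of its two equations redundant?
#'
#' For observed, d-connected `node_a` and `node_b` and an unobserved
#' `new_node` lying on a Wright's path between them, decides whether one of
#' IE(`node_a`, `new_node`) / IE(`node_b`, `new_node`) is redundant once
#' `new_node` becomes observed (`new_node` itself counts as observed for
#' the path-blocking condition).
#'
#' @inheritParams identifiability_gain
#' @param node_a,node_b Observed node identifiers.
#' @param new_node The unobserved node on a path between them.
#' @return Logical scalar.
#' @export
on_path_pair_redundant <- function(net, observed, node_a, node_b, new_node) {
  net <- as_network(net)
  obs <- as_strategy(net, observed)
  a <- node_index(net, node_a)
  b <- node_index(net, node_b)
  u <- node_index(net, new_node)
  if (!obs[a] || !obs[b]) rlang::abort("`node_a` and `node_b` must be observed",
                                       class = "obsremedy_strategy_error")
  if (obs[u]) rlang::abort("`new_node` must be unobserved",
                           class = "obsremedy_strategy_error")
  onpath_redundant_int(net, obs, a, b, u)
}
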
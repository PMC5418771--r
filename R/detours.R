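# Detour-path detection and Wright's-coefficient identifiability.
#
# A detour-path is a directed path segment P_jk from an observed collider
# node V_k to an observed downstream node V_j, witnessed by (a) an observed
# upstream node V_i joined to V_k by a Wright's path entering V_k (arrow
# into the collider) and (b) an alternative Wright's path between V_k and
# V_j that also enters V_k and passes no observed node besides its
# endpoints. The Wright coefficient of the segment behaves like a single
# parameter; two sufficient conditions certify it globally identifiable:
# an exclusive upstream node, or an intersecting group with at least as
# many shared upstream nodes as member detour-paths.

# Internal detour records under a logical strategy `obs`.
# Returns a list of records: collider, downstream, segment (node idx vec
# k..j), seg_edges, upstream (int vec), witness (per upstream: p_ki nodes,
# alt nodes). Cached on the network keyed by the strategy bits.
find_detours_int <- function(net, obs) {
  key <- paste0("d", strategy_key(obs))
  if (!is.null(net$cache[[key]])) return(net$cache[[key]])
  obs_idx <- which(obs)
  out <- list()
  for (j in obs_idx) {
    for (k in obs_idx) {
      if (k == j || !net$reach[k, j]) next
      # alternative Wright's paths k..j entering k with unobserved interior
      alts <- Filter(function(t) t$top != k && !any(obs[trek_interior(t)]),
                     treks_between(net, k, j))
      if (!length(alts)) next
      segs <- paths_between(net, k, j)
      for (seg in segs) {
        ups <- integer(0)
        wit <- list()
        for (i in obs_idx) {
          if (i == k || i == j) next
          # Wright's path i..k entering k, node-disjoint from the segment
          # except at k (so P_ki + P_jk is a simple Wright's path i..j) and
          # node-disjoint from the alternative path except at k (so the
          # collider structure at k is genuine).
          cand <- Filter(function(t) t$top != k && !any(t$nodes %in% seg[-1]),
                         treks_between(net, i, k))
          hit <- NULL
          for (tr in cand) {
            for (al in alts) {
              body_al <- al$nodes[-1]                  # drop k
              if (!any(tr$nodes[-length(tr$nodes)] %in% body_al)) {
                hit <- list(p_ki = tr$nodes, alt = al$nodes)
                break
              }
            }
            if (!is.null(hit)) break
          }
          if (!is.null(hit)) {
            ups <- c(ups, i)
            wit[[length(wit) + 1L]] <- hit
          }
        }
        if (length(ups)) {
          out[[length(out) + 1L]] <- list(
            collider = k,
            downstream = j,
            segment = seg,
            seg_edges = edge_ids_of_path(net, seg),
            upstream = ups,
            witness = wit
          )
        }
      }
    }
  }
  net$cache[[key]] <- out
  out
}

detour_key <- function(d) {
  paste(d$collider, d$downstream, paste(d$segment, collapse = "."), sep = "|")
}

# Upstream classification, intersecting groups and the Lemma 2/3 verdicts
# for a detour list. Returns list(detours, exclusive (list of int vecs),
# shared (list), group (int vec), group_sun (list), identifiable (logical)).
detour_status <- function(detours) {
  nd <- length(detours)
  if (!nd) {
    return(list(detours = detours, exclusive = list(), shared = list(),
                group = integer(0), group_sun = list(),
                identifiable = logical(0)))
  }
  downstream <- vapply(detours, `[[`, integer(1), "downstream")
  # an upstream node is shared iff it is upstream of >= 2 detour-paths with
  # the same downstream node
  shared <- vector("list", nd)
  exclusive <- vector("list", nd)
  for (i in seq_len(nd)) {
    ups <- detours[[i]]$upstream
    is_shared <- vapply(ups, function(u) {
      sum(vapply(seq_len(nd), function(l) {
        downstream[l] == downstream[i] && u %in% detours[[l]]$upstream
      }, logical(1))) >= 2
    }, logical(1))
    shared[[i]] <- ups[is_shared]
    exclusive[[i]] <- ups[!is_shared]
  }
  # intersecting relation: both detours have no exclusive upstream node AND
  # (same downstream with a common upstream node, OR one's upstream node is
  # the other's collider node); closed under transitivity -> components.
  no_excl <- lengths(exclusive) == 0
  group <- seq_len(nd)
  group[!no_excl] <- NA_integer_
  idx <- which(no_excl)
  if (length(idx) > 1) {
    for (aa in idx) {
      for (bb in idx) {
        if (bb <= aa) next
        da <- detours[[aa]]; db <- detours[[bb]]
        inter <- (downstream[aa] == downstream[bb] &&
                    length(intersect(da$upstream, db$upstream)) > 0) ||
          db$collider %in% da$upstream || da$collider %in% db$upstream
        if (inter) {
          ga <- group[aa]; gb <- group[bb]
          group[group %in% c(ga, gb) & !is.na(group)] <- min(ga, gb)
        }
      }
    }
  }
  groups <- unique(group[!is.na(group)])
  group_sun <- lapply(groups, function(g) {
    sort(unique(unlist(shared[which(!is.na(group) & group == g)])))
  })
  names(group_sun) <- as.character(groups)
  identifiable <- logical(nd)
  for (i in seq_len(nd)) {
    if (length(exclusive[[i]]) > 0) {
      identifiable[i] <- TRUE                       # Lemma 2
    } else {
      members <- which(!is.na(group) & group == group[i])
      sun <- group_sun[[as.character(group[i])]]
      identifiable[i] <- length(sun) >= length(members)  # Lemma 3
    }
  }
  list(detours = detours, exclusive = exclusive, shared = shared,
       group = group, group_sun = group_sun, identifiable = identifiable)
}

# Cached detour_status under a strategy.
wp_status <- function(net, obs) {
  key <- paste0("ds", strategy_key(obs))
  if (!is.null(net$cache[[key]])) return(net$cache[[key]])
  st <- detour_status(find_detours_int(net, obs))
  st$keys <- vapply(st$detours, detour_key, character(1))
  net$cache[[key]] <- st
  st
}

# Is the Wright coefficient of the query detour (a record from any
# strategy) globally identifiable under strategy `obs`? The detour must be
# re-detected under `obs` (its defining observed nodes observed there) and
# Lemma 2 or Lemma 3 must fire.
wp_identifiable_under <- function(net, obs, detour) {
  st <- wp_status(net, obs)
  hit <- match(detour_key(detour), st$keys)
  !is.na(hit) && st$identifiable[hit]
}

#' Detect detour-paths under an observation strategy
#'
#' @param net A network (anything accepted by [as_network()]).
#' @param observed An observation strategy (see [as_strategy()]).
#' @return A tibble with one row per detour-path: `collider`, `downstream`,
#'   `segment` (list column of node sequences from collider to downstream),
#'   `upstream` (list column), `exclusive`/`shared` (list columns
#'   partitioning the upstream nodes), `group` (intersecting-group id, `NA`
#'   for detours holding an exclusive upstream node), `shared_upstream_group`
#'   (list column: the group's pooled shared upstream nodes) and
#'   `wp_identifiable` (Lemma 2/3 verdict).
#' @examples
#' find_detour_paths(network_fixture("collider5"), c("I", "K", "J", "W"))
#' @export
find_detour_paths <- function(net, observed) {
  net <- as_network(net)
  obs <- as_strategy(net, observed)
  st <- wp_status(net, obs)
  nd <- length(st$detours)
  tibble::tibble(
    collider = vapply(st$detours, function(d) net$nodes[d$collider], character(1)),
    downstream = vapply(st$detours, function(d) net$nodes[d$downstream], character(1)),
    segment = lapply(st$detours, function(d) net$nodes[d$segment]),
    upstream = lapply(st$detours, function(d) net$nodes[d$upstream]),
    exclusive = lapply(st$exclusive, function(u) net$nodes[u]),
    shared = lapply(st$shared, function(u) net$nodes[u]),
    group = st$group,
    shared_upstream_group = lapply(seq_len(nd), function(i) {
      if (is.na(st$group[i])) character(0)
      else net$nodes[st$group_sun[[as.character(st$group[i])]]]
    }),
    wp_identifiable = st$identifiable
  )
}

#' Intersecting groups of detour-paths
#'
#' Two detour-paths (both without exclusive upstream nodes) intersect when
#' they share the downstream node and at least one upstream node, or when
#' one's upstream node is the other's collider node; the relation is
#' closed transitively. For each group the pooled shared upstream nodes
#' decide identifiability: every member's Wright coefficient is globally
#' identifiable when the group has at least as many shared upstream nodes
#' as members.
#'
#' @inheritParams find_detour_paths
#' @return A tibble with one row per group: `group`, `n_members`,
#'   `members` (list column of detour row indices into
#'   [find_detour_paths()] output), `shared_upstream` (list column) and
#'   `wp_identifiable`.
#' @export
detour_groups <- function(net, observed) {
  net <- as_network(net)
  obs <- as_strategy(net, observed)
  st <- wp_status(net, obs)
  ids <- unique(st$group[!is.na(st$group)])
  if (!length(ids)) {
    return(tibble::tibble(group = integer(0), n_members = integer(0),
                          members = list(), shared_upstream = list(),
                          wp_identifiable = logical(0)))
  }
  tibble::tibble(
    group = ids,
    n_members = vapply(ids, function(g) sum(!is.na(st$group) & st$group == g),
                       integer(1)),
    members = lapply(ids, function(g) which(!is.na(st$group) & st$group == g)),
    shared_upstream = lapply(ids, function(g) {
      net$nodes[st$group_sun[[as.character(g)]]]
    }),
    wp_identifiable = vapply(ids, function(g) {
      length(st$group_sun[[as.character(g)]]) >=
        sum(!is.na(st$group) & st$group == g)
    }, logical(1))
  )
}

#' Classify upstream nodes of detected detour-paths
#'
#' An upstream node is *shared* when it is an upstream node of two or more
#' detour-paths with the same downstream node, *exclusive* otherwise.
#'
#' @inheritParams find_detour_paths
#' @return A tibble with columns `detour` (row index into
#'   [find_detour_paths()] output), `collider`, `downstream`, `upstream`
#'   and `role` (`"exclusive"` or `"shared"`).
#' @export
classify_upstream <- function(net, observed) {
  net <- as_network(net)
  obs <- as_strategy(net, observed)
  st <- wp_status(net, obs)
  rows <- purrr::map_dfr(seq_along(st$detours), function(i) {
    d <- st$detours[[i]]
    tibble::tibble(
      detour = i,
      collider = net$nodes[d$collider],
      downstream = net$nodes[d$downstream],
      upstream = net$nodes[d$upstream],
      role = ifelse(d$upstream %in% st$shared[[i]], "shared", "exclusive")
    )
  })
  if (!nrow(rows)) {
    rows <- tibble::tibble(detour = integer(0), collider = character(0),
                           downstream = character(0), upstream = character(0),
                           role = character(0))
  }
  rows
}

#' Must-be-observed nodes
#'
#' Degree rules give nodes whose observation is necessary for all edge
#' coefficients to be (at least locally) identifiable: nodes with
#' out-degree 0, nodes with out-degree 1, and source nodes (in-degree 0)
#' with out-degree below 3. The dynamic program always starts from a
#' strategy observing all of them.
#'
#' @param net A network (anything accepted by [as_network()]).
#' @return A tibble with columns `node`, `in_degree`, `out_degree`,
#'   `reason`; one row per must-be-observed node in canonical order.
#' @examples
#' must_be_observed(network_fixture("star4"))
#' @export
must_be_observed <- function(net) {
  net <- as_network(net)
  outd <- lengths(net$adj_out)
  ind <- lengths(net$adj_in)
  reason <- character(net$n)
  reason[outd == 0] <- "out-degree 0"
  reason[outd == 1] <- "out-degree 1"
  src <- ind == 0 & outd < 3 & reason == ""
  reason[src] <- "source with out-degree < 3"
  keep <- reason != ""
  tibble::tibble(
    node = net$nodes[keep],
    in_degree = as.integer(ind[keep]),
    out_degree = as.integer(outd[keep]),
    reason = reason[keep]
  )
}

mbo_indicator <- function(net) {
  outd <- lengths(net$adj_out)
  ind <- lengths(net$adj_in)
  res <- outd == 0 | outd == 1 | (ind == 0 & outd < 3)
  names(res) <- net$nodes
  res
}
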
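#' Build a directed acyclic network from an edge table
#'
#' Constructs the package's network object from a data frame of directed
#' edges. Each edge `source -> target` carries one unknown structural
#' coefficient (the coefficient on the edge into `target`), so the number of
#' unknown parameters of the corresponding linear structural equation model
#' equals the number of edges.
#'
#' Node order matters: it is the canonical order used for deterministic
#' tie-breaking, dynamic-programming stage indexing and all printed output.
#' By default it is the order of first appearance in `x` (sources before
#' targets, row by row); supply `nodes` to fix it explicitly (required when
#' the network has isolated nodes).
#'
#' @param x A data frame whose first two columns are edge source and target
#'   node identifiers (coerced to character), or an existing
#'   `obsremedy_network`.
#' @param nodes Optional character vector of node identifiers fixing the
#'   canonical node order. Must contain every node referenced by `x`.
#' @param ... Unused.
#' @return An object of class `obsremedy_network`.
#' @examples
#' net <- as_network(data.frame(from = c("1", "2"), to = c("2", "3")))
#' net
#' @export
as_network <- function(x, nodes = NULL, ...) {
  UseMethod("as_network")
}

#' @export
as_network.obsremedy_network <- function(x, nodes = NULL, ...) x

#' @export
as_network.data.frame <- function(x, nodes = NULL, ...) {
  if (ncol(x) < 2) {
    rlang::abort("edge table needs at least two columns (source, target)",
                 class = "obsremedy_parse_error")
  }
  from <- as.character(x[[1]])
  to <- as.character(x[[2]])
  if (anyNA(from) || anyNA(to)) {
    rlang::abort("edge table contains missing node identifiers",
                 class = "obsremedy_parse_error")
  }
  if (is.null(nodes)) {
    nodes <- unique(as.character(t(cbind(from, to))))
  } else {
    nodes <- as.character(nodes)
    if (anyDuplicated(nodes)) {
      rlang::abort("`nodes` contains duplicated identifiers",
                   class = "obsremedy_parse_error")
    }
    missing <- setdiff(unique(c(from, to)), nodes)
    if (length(missing)) {
      rlang::abort(paste0("edges reference nodes absent from `nodes`: ",
                          paste(missing, collapse = ", ")),
                   class = "obsremedy_parse_error")
    }
  }
  new_network(nodes, match(from, nodes), match(to, nodes))
}

# Internal constructor working on integer node indices. Validates the DAG
# invariants (no self loops, duplicates, bidirectional pairs, cycles) and
# precomputes adjacency and reachability used by every algorithm.
new_network <- function(nodes, from_idx, to_idx) {
  n <- length(nodes)
  m <- length(from_idx)
  if (m != length(to_idx)) stop("internal: edge index length mismatch")

  loops <- which(from_idx == to_idx)
  if (length(loops)) {
    rlang::abort(paste0("self-loop on node '", nodes[from_idx[loops[1]]],
                        "' (edge ", loops[1], ")"),
                 class = "obsremedy_invalid_edge")
  }
  key <- from_idx * (n + 1L) + to_idx
  dup <- which(duplicated(key))
  if (length(dup)) {
    rlang::abort(paste0("duplicate edge '", nodes[from_idx[dup[1]]], "' -> '",
                        nodes[to_idx[dup[1]]], "' (edge ", dup[1], ")"),
                 class = "obsremedy_invalid_edge")
  }
  rev_key <- to_idx * (n + 1L) + from_idx
  bidir <- which(rev_key %in% key)
  if (length(bidir)) {
    rlang::abort(paste0("bidirectional edge between '",
                        nodes[from_idx[bidir[1]]], "' and '",
                        nodes[to_idx[bidir[1]]], "' (edge ", bidir[1], ")"),
                 class = "obsremedy_invalid_edge")
  }

  g <- igraph::make_empty_graph(n, directed = TRUE)
  if (m > 0) g <- igraph::add_edges(g, rbind(from_idx, to_idx))
  if (!igraph::is_dag(g)) {
    rlang::abort("cycle detected: the network must be a directed acyclic graph",
                 class = "obsremedy_cycle_error")
  }
  topo <- as.integer(igraph::topo_sort(g, mode = "out"))

  adj_out <- rep(list(integer(0)), n)
  adj_in <- rep(list(integer(0)), n)
  if (m > 0) {
    adj_out[seq_len(n)] <- unname(split(to_idx, factor(from_idx, levels = seq_len(n))))
    adj_in[seq_len(n)] <- unname(split(from_idx, factor(to_idx, levels = seq_len(n))))
    # keep deterministic canonical order within adjacency lists
    adj_out <- lapply(adj_out, sort)
    adj_in <- lapply(adj_in, sort)
  }

  # strict reachability (reach[i, j] <=> directed path i -> j, i != j)
  reach <- matrix(FALSE, n, n)
  if (m > 0) {
    for (v in rev(topo)) {
      kids <- adj_out[[v]]
      if (length(kids)) {
        reach[v, kids] <- TRUE
        if (length(kids) == 1L) {
          reach[v, ] <- reach[v, ] | reach[kids, ]
        } else {
          reach[v, ] <- reach[v, ] | (colSums(reach[kids, , drop = FALSE]) > 0)
        }
      }
    }
  }
  reach_s <- reach
  diag(reach_s) <- TRUE

  eid <- matrix(0L, n, n)
  if (m > 0) eid[cbind(from_idx, to_idx)] <- seq_len(m)

  structure(
    list(
      nodes = nodes,
      n = n,
      from = as.integer(from_idx),
      to = as.integer(to_idx),
      n_edges = m,
      adj_out = adj_out,
      adj_in = adj_in,
      topo = topo,
      reach = reach,
      reach_s = reach_s,
      eid = eid,
      cache = new.env(parent = emptyenv())
    ),
    class = "obsremedy_network"
  )
}

# Subnetwork on the same node set with a subset of edges (used by the
# edge-removal construction). Invariants already hold; skip revalidation.
subnetwork <- function(net, keep_edges) {
  new_network(net$nodes, net$from[keep_edges], net$to[keep_edges])
}

#' @export
print.obsremedy_network <- function(x, ...) {
  cat("<obsremedy_network> ", x$n, " nodes, ", x$n_edges,
      " edges (", x$n_edges, " unknown coefficients)\n", sep = "")
  cat("nodes: ", paste(utils::head(x$nodes, 10), collapse = ", "),
      if (x$n > 10) ", ..." else "", "\n", sep = "")
  if (x$n_edges > 0) {
    shown <- min(x$n_edges, 10)
    cat("edges: ",
        paste(paste0(x$nodes[x$from[seq_len(shown)]], " -> ",
                     x$nodes[x$to[seq_len(shown)]]), collapse = ", "),
        if (x$n_edges > 10) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Network accessors
#'
#' `network_nodes()` returns the node identifiers in canonical order;
#' `network_edges()` returns the edge table (one row per unknown
#' coefficient) as a tibble.
#'
#' @param net A network (anything accepted by [as_network()]).
#' @return A character vector of nodes, or a tibble with columns `from`,
#'   `to` and `coef` (the display label of the edge coefficient).
#' @export
network_nodes <- function(net) {
  net <- as_network(net)
  net$nodes
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  net <- as_network(net)
  tibble::tibble(
    from = net$nodes[net$from],
    to = net$nodes[net$to],
    coef = coef_names(net)
  )
}

# Display labels for edge coefficients. The coefficient on edge V_j -> V_i
# is written c_{i,j} (target first). Short single-character node names get
# the compact "c42" form used in printed equations.
coef_names <- function(net, edge_ids = seq_len(net$n_edges)) {
  if (!length(edge_ids)) return(character(0))
  to <- net$nodes[net$to[edge_ids]]
  from <- net$nodes[net$from[edge_ids]]
  if (all(nchar(net$nodes) == 1L)) {
    paste0("c", to, from)
  } else {
    paste0("c[", to, ",", from, "]")
  }
}

#' Topological order of a network
#'
#' @param net A network (anything accepted by [as_network()]).
#' @return Character vector of node identifiers in a topological order
#'   (every edge points forward).
#' @export
topological_order <- function(net) {
  net <- as_network(net)
  net$nodes[net$topo]
}

node_index <- function(net, node) {
  idx <- match(as.character(node), net$nodes)
  if (anyNA(idx)) {
    rlang::abort(paste0("unknown node id: ",
                        paste(node[is.na(idx)], collapse = ", ")),
                 class = "obsremedy_unknown_node")
  }
  idx
}

#' Ancestor/descendant/relative partition around a focal node
#'
#' Splits all other nodes into ancestors (`anc`), descendants (`des`) and
#' relatives (`rel`, neither) of the focal node, and flags boundary
#' ancestors: ancestors with at least one outgoing edge into the relative
#' set. These sets drive the edge-removal construction of the
#' identifiability gain.
#'
#' @param net A network (anything accepted by [as_network()]).
#' @param node Focal node identifier.
#' @return A tibble with columns `node`, `relation`
#'   (`"ancestor"`/`"descendant"`/`"relative"`) and `boundary` (logical,
#'   only ever `TRUE` for ancestors).
#' @examples
#' node_neighborhoods(network_fixture("collider5"), "K")
#' @export
node_neighborhoods <- function(net, node) {
  net <- as_network(net)
  i <- node_index(net, node)
  parts <- neighborhood_sets(net, i)
  all_idx <- c(parts$anc, parts$des, parts$rel)
  relation <- c(rep("ancestor", length(parts$anc)),
                rep("descendant", length(parts$des)),
                rep("relative", length(parts$rel)))
  ord <- order(all_idx)
  tibble::tibble(
    node = net$nodes[all_idx[ord]],
    relation = relation[ord],
    boundary = all_idx[ord] %in% parts$bound
  )
}

# Integer-index version used internally.
neighborhood_sets <- function(net, i) {
  anc <- which(net$reach[, i])
  des <- which(net$reach[i, ])
  rel <- setdiff(seq_len(net$n), c(anc, des, i))
  bound <- anc[vapply(anc, function(a) any(net$adj_out[[a]] %in% rel), logical(1))]
  list(anc = anc, des = des, rel = rel, bound = bound)
}
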
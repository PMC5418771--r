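# Wright's path (trek) enumeration and symbolic identifiability equations.
#
# A trek between a and b is a collider-free walk formed by two directed
# paths descending from a common top node, one to a and one to b, sharing
# no node but the top. Degenerate cases (top = a or top = b) are plain
# directed paths. The product of the edge coefficients along a trek is its
# Wright monomial; the covariance of a d-connected pair equals the sum of
# its trek monomials when error variances are standardized to one.

# All directed simple paths from a to b as integer node vectors (including
# both endpoints); cached per network.
paths_between <- function(net, a, b) {
  key <- paste0("p", a, "_", b)
  if (!is.null(net$cache[[key]])) return(net$cache[[key]])
  res <- if (a == b) {
    list(a)
  } else if (!net$reach[a, b]) {
    list()
  } else {
    acc <- list()
    walk <- function(cur, path) {
      for (w in net$adj_out[[cur]]) {
        if (w == b) {
          acc[[length(acc) + 1L]] <<- c(path, b)
        } else if (net$reach[w, b]) {
          walk(w, c(path, w))
        }
      }
    }
    walk(a, c(a))
    acc
  }
  net$cache[[key]] <- res
  res
}

edge_ids_of_path <- function(net, path) {
  if (length(path) < 2) return(integer(0))
  net$eid[cbind(path[-length(path)], path[-1])]
}

# All simple treks between distinct nodes a and b. Each trek is a list with
# `nodes` (sequence a .. top .. b), `top`, `top_pos`, and `edges` (edge ids;
# the Wright monomial is the multiset of these). Deterministic order:
# lexicographic on the node sequence.
treks_between <- function(net, a, b) {
  key <- paste0("t", a, "_", b)
  if (!is.null(net$cache[[key]])) return(net$cache[[key]])
  cap <- getOption("obsremedy.trek_node_cap", 100L)
  if (net$n > cap) {
    rlang::abort(paste0("trek enumeration capped at ", cap, " nodes ",
                        "(set options(obsremedy.trek_node_cap=) to raise)"),
                 class = "obsremedy_cap_error")
  }
  tops <- which(net$reach_s[, a] & net$reach_s[, b])
  res <- list()
  for (t in tops) {
    pa <- paths_between(net, t, a)
    pb <- paths_between(net, t, b)
    for (qa in pa) {
      for (qb in pb) {
        # node-disjoint except at the top
        if (length(qa) > 1 && length(qb) > 1 && any(qa[-1] %in% qb[-1])) next
        nodes <- c(rev(qa), qb[-1])
        res[[length(res) + 1L]] <- list(
          nodes = nodes,
          top = t,
          top_pos = length(qa),
          edges = c(edge_ids_of_path(net, qa), edge_ids_of_path(net, qb))
        )
      }
    }
  }
  if (length(res) > 1) {
    keys <- vapply(res, function(tr) paste(sprintf("%06d", tr$nodes), collapse = ""),
                   character(1))
    res <- res[order(keys)]
  }
  net$cache[[key]] <- res
  res
}

trek_interior <- function(trek) {
  nd <- trek$nodes
  if (length(nd) <= 2) integer(0) else nd[-c(1L, length(nd))]
}

#' Enumerate Wright's paths (treks) between two nodes
#'
#' @param net A network (anything accepted by [as_network()]).
#' @param a,b Distinct node identifiers.
#' @return A tibble with one row per trek: `trek` (index in deterministic
#'   lexicographic order), `top` (the trek's top node), `nodes` (list
#'   column: the node sequence from `a` over the top to `b`) and `monomial`
#'   (the Wright coefficient product as a display string).
#' @examples
#' enumerate_treks(network_fixture("diamond4"), "1", "4")
#' @export
enumerate_treks <- function(net, a, b) {
  net <- as_network(net)
  ia <- node_index(net, a)
  ib <- node_index(net, b)
  if (ia == ib) {
    rlang::abort("trek endpoints must be distinct (variance paths are out of scope)",
                 class = "obsremedy_invalid_pair")
  }
  trks <- treks_between(net, ia, ib)
  tibble::tibble(
    trek = seq_along(trks),
    top = vapply(trks, function(t) net$nodes[t$top], character(1)),
    nodes = lapply(trks, function(t) net$nodes[t$nodes]),
    monomial = vapply(trks, function(t) monomial_label(net, t$edges), character(1))
  )
}

# Coefficient product label with factors ordered target-major (descending),
# e.g. "c42*c21".
monomial_label <- function(net, edge_ids) {
  if (!length(edge_ids)) return("1")
  ord <- order(-net$to[edge_ids], -net$from[edge_ids])
  paste(coef_names(net, edge_ids[ord]), collapse = "*")
}

#' Marginal d-connection of a node pair
#'
#' Two distinct nodes are marginally d-connected (empty conditioning set,
#' independent errors) exactly when a trek joins them, i.e. when they share
#' a common ancestor (possibly one of the pair itself). d-separated pairs
#' have zero covariance and yield no identifiability equation.
#'
#' @inheritParams enumerate_treks
#' @return Logical scalar.
#' @export
d_connected <- function(net, a, b) {
  net <- as_network(net)
  ia <- node_index(net, a)
  ib <- node_index(net, b)
  if (ia == ib) {
    rlang::abort("d-connection is defined for distinct nodes",
                 class = "obsremedy_invalid_pair")
  }
  any(net$reach_s[, ia] & net$reach_s[, ib])
}

# Logical vector: which nodes are d-connected to focal.
d_connected_vec <- function(net, focal) {
  out <- as.vector(crossprod(net$reach_s, net$reach_s[, focal]) > 0)
  out[focal] <- FALSE
  out
}

#' Build the symbolic identifiability equation of a node pair
#'
#' The identifiability equation of a d-connected pair equates their
#' observable covariance with the sum of Wright trek monomials. Monomials
#' are represented as canonical sorted edge sets with an integer
#' multiplicity (distinct treks sharing one edge set are counted, not
#' merged away), so no symbolic algebra is ever needed.
#'
#' @inheritParams enumerate_treks
#' @return An object of class `obsremedy_equation` with fields `a`, `b`,
#'   `monomials` (list of sorted edge-id vectors), `multiplicity`, and a
#'   `tidy()`/`print()` rendering like `Cov(1,4) = c42*c21 + c43*c31`. The
#'   equation is empty iff the pair is d-separated.
#' @examples
#' build_equation(network_fixture("diamond4"), "1", "4")
#' @export
build_equation <- function(net, a, b) {
  net <- as_network(net)
  ia <- node_index(net, a)
  ib <- node_index(net, b)
  if (ia == ib) {
    rlang::abort("identifiability equations are defined for distinct nodes",
                 class = "obsremedy_invalid_pair")
  }
  trks <- treks_between(net, ia, ib)
  mono <- lapply(trks, function(t) sort(t$edges))
  keys <- vapply(mono, paste, character(1), collapse = ",")
  uk <- unique(keys)
  monomials <- mono[match(uk, keys)]
  multiplicity <- as.integer(table(factor(keys, levels = uk)))
  structure(
    list(a = net$nodes[ia], b = net$nodes[ib], monomials = monomials,
         multiplicity = multiplicity,
         labels = vapply(monomials, function(m) monomial_label(net, m), character(1))),
    class = "obsremedy_equation"
  )
}

#' @export
print.obsremedy_equation <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.obsremedy_equation <- function(x, ...) {
  lhs <- paste0("Cov(", x$a, ",", x$b, ")")
  if (!length(x$monomials)) return(paste0(lhs, " = 0  (d-separated)"))
  terms <- ifelse(x$multiplicity > 1,
                  paste0(x$multiplicity, "*", x$labels), x$labels)
  paste0(lhs, " = ", paste(terms, collapse = " + "))
}

#' @method tidy obsremedy_equation
#' @export
tidy.obsremedy_equation <- function(x, ...) {
  tibble::tibble(
    a = x$a, b = x$b,
    monomial = x$labels,
    multiplicity = x$multiplicity,
    edges = x$monomials
  )
}
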
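#' Normalize an observation strategy
#'
#' An observation strategy marks every network node as observed or
#' unobserved; only covariances between observed node pairs are available
#' to identify edge coefficients. Accepted inputs:
#' * `NULL` — all nodes unobserved;
#' * a character vector of observed node identifiers;
#' * a logical (or 0/1 numeric) vector of length `n`, optionally named by
#'   node;
#' * a data frame with columns `node` and `observed` covering every node
#'   exactly once (the format returned by [read_strategy()]).
#'
#' @param net A network (anything accepted by [as_network()]).
#' @param observed The strategy in any accepted form.
#' @return A logical vector of length `n` named by node, in canonical node
#'   order.
#' @export
as_strategy <- function(net, observed = NULL) {
  net <- as_network(net)
  n <- net$n
  if (is.null(observed)) {
    obs <- rep(FALSE, n)
  } else if (is.data.frame(observed)) {
    if (!all(c("node", "observed") %in% names(observed))) {
      rlang::abort("strategy data frame needs columns `node` and `observed`",
                   class = "obsremedy_strategy_error")
    }
    nd <- as.character(observed$node)
    if (anyDuplicated(nd) || length(setdiff(net$nodes, nd)) ||
        length(setdiff(nd, net$nodes))) {
      rlang::abort("strategy domain must equal the network's node set exactly",
                   class = "obsremedy_strategy_error")
    }
    obs <- rep(FALSE, n)
    obs[match(nd, net$nodes)] <- as.logical(as.numeric(observed$observed))
  } else if (is.character(observed)) {
    idx <- node_index(net, unique(observed))
    obs <- rep(FALSE, n)
    obs[idx] <- TRUE
  } else if (is.logical(observed) || is.numeric(observed)) {
    if (!is.null(names(observed))) {
      idx <- node_index(net, names(observed))
      obs <- rep(FALSE, n)
      obs[idx] <- as.logical(as.numeric(observed))
    } else {
      if (length(observed) != n) {
        rlang::abort("unnamed strategy vector must have one entry per node",
                     class = "obsremedy_strategy_error")
      }
      obs <- as.logical(as.numeric(observed))
    }
  } else {
    rlang::abort("cannot interpret `observed` as an observation strategy",
                 class = "obsremedy_strategy_error")
  }
  if (anyNA(obs)) {
    rlang::abort("observation strategy contains missing flags",
                 class = "obsremedy_strategy_error")
  }
  names(obs) <- net$nodes
  obs
}

strategy_key <- function(obs) paste(as.integer(obs), collapse = "")

#' Initial strategy: element-wise OR with the must-be-observed nodes
#'
#' The dynamic program never questions nodes that have to be observed for
#' identifiability to be achievable at all (see [must_be_observed()]); its
#' initial strategy is the element-wise OR of the user-supplied strategy
#' with the must-be-observed indicator.
#'
#' @param net A network (anything accepted by [as_network()]).
#' @param observed A strategy in any form accepted by [as_strategy()].
#' @return A tibble with columns `node`, `given`, `mbo`, `observed`
#'   (`observed = given | mbo`).
#' @examples
#' initial_strategy(network_fixture("star4"), NULL)
#' @export
initial_strategy <- function(net, observed = NULL) {
  net <- as_network(net)
  given <- as_strategy(net, observed)
  mbo <- mbo_indicator(net)
  tibble::tibble(
    node = net$nodes,
    given = unname(given),
    mbo = unname(mbo),
    observed = unname(given | mbo)
  )
}
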
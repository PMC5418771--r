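#' Read a directed network from a file
#'
#' Supported dialects:
#' * **tsv** — two tab-separated columns `source<TAB>target`; lines starting
#'   with `#` are comments.
#' * **sif** — `source<TAB>relation<TAB>target`; the relation token is
#'   ignored (any interaction type is accepted).
#' * **graphml** — read through igraph; node identifiers are taken from the
#'   `id`/`name` vertex attribute.
#'
#' The canonical node order of the returned network is the order of first
#' appearance in the file; it drives all deterministic tie-breaking.
#'
#' @param path Path to the network file.
#' @param format One of `"auto"`, `"tsv"`, `"sif"`, `"graphml"`. `"auto"`
#'   picks by file extension (`.sif`, `.graphml`/`.xml`, anything else is
#'   read as TSV).
#' @return An `obsremedy_network`.
#' @export
read_network <- function(path, format = c("auto", "tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "obsremedy_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sif = "sif", graphml = "graphml", xml = "graphml", "tsv")
  }
  switch(format,
    tsv = read_network_tsv(path, n_cols = 2L),
    sif = read_network_tsv(path, n_cols = 3L),
    graphml = read_network_graphml(path)
  )
}

read_network_tsv <- function(path, n_cols) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    rlang::abort(paste0("no edges found in ", path), class = "obsremedy_parse_error")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < n_cols)
  if (length(bad)) {
    rlang::abort(paste0("parse failure at line ", lineno[bad[1]], " of ", path,
                        ": expected ", n_cols, " tab-separated fields"),
                 class = "obsremedy_parse_error")
  }
  from <- trimws(vapply(parts, `[[`, "", 1L))
  to <- trimws(vapply(parts, `[[`, "", n_cols))
  as_network(data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

read_network_graphml <- function(path) {
  g <- tryCatch(
    igraph::read_graph(path, format = "graphml"),
    error = function(e) {
      rlang::abort(paste0("GraphML parse failure in ", path, ": ",
                          conditionMessage(e)),
                   class = "obsremedy_parse_error")
    }
  )
  if (!igraph::is_directed(g)) {
    rlang::abort("GraphML network must be directed", class = "obsremedy_parse_error")
  }
  attrs <- igraph::vertex_attr_names(g)
  name_attr <- if ("id" %in% attrs) "id" else if ("name" %in% attrs) "name" else NULL
  nodes <- if (is.null(name_attr)) {
    as.character(seq_len(igraph::vcount(g)))
  } else {
    as.character(igraph::vertex_attr(g, name_attr))
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0) return(new_network(nodes, integer(0), integer(0)))
  as_network(data.frame(from = nodes[el[, 1]], to = nodes[el[, 2]],
                        stringsAsFactors = FALSE),
             nodes = nodes)
}

#' Write a network to a file
#'
#' Inverse of [read_network()]: `load -> write -> load` is the identity on
#' nodes and edges for each supported format.
#'
#' @param net A network (anything accepted by [as_network()]).
#' @param path Output path.
#' @param format One of `"auto"`, `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("auto", "tsv", "sif", "graphml")) {
  net <- as_network(net)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sif = "sif", graphml = "graphml", xml = "graphml", "tsv")
  }
  if (format == "tsv") {
    writeLines(paste(net$nodes[net$from], net$nodes[net$to], sep = "\t"), path)
  } else if (format == "sif") {
    writeLines(paste(net$nodes[net$from], "directed", net$nodes[net$to], sep = "\t"), path)
  } else {
    esc <- function(x) {
      x <- gsub("&", "&amp;", x, fixed = TRUE)
      x <- gsub("<", "&lt;", x, fixed = TRUE)
      x <- gsub(">", "&gt;", x, fixed = TRUE)
      gsub("\"", "&quot;", x, fixed = TRUE)
    }
    # written by hand so that the XML node ids carry the node identifiers
    # (igraph reserves the id attribute when writing)
    writeLines(c(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">",
      "  <graph id=\"G\" edgedefault=\"directed\">",
      paste0("    <node id=\"", esc(net$nodes), "\"/>"),
      if (net$n_edges > 0) {
        paste0("    <edge source=\"", esc(net$nodes[net$from]),
               "\" target=\"", esc(net$nodes[net$to]), "\"/>")
      },
      "  </graph>",
      "</graphml>"
    ), path)
  }
  invisible(path)
}

#' Read an observation strategy file
#'
#' The file has two tab-separated columns `node<TAB>flag` with flag `0`
#' (unobserved) or `1` (observed); `#` comments are allowed. Every network
#' node must be listed unless `default_unobserved = TRUE`, in which case
#' missing nodes default to unobserved.
#'
#' @param path Path to the strategy file.
#' @param net The network the strategy refers to.
#' @param default_unobserved If `TRUE`, nodes absent from the file are
#'   treated as unobserved instead of raising an error.
#' @return A tibble with columns `node` and `observed` (logical), one row
#'   per network node in canonical order.
#' @export
read_strategy <- function(path, net, default_unobserved = FALSE) {
  net <- as_network(net)
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "obsremedy_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    rlang::abort(paste0("strategy parse failure: expected node<TAB>0|1 on line ",
                        bad[1]),
                 class = "obsremedy_parse_error")
  }
  node <- trimws(vapply(parts, `[[`, "", 1L))
  flag <- trimws(vapply(parts, `[[`, "", 2L))
  if (!all(flag %in% c("0", "1"))) {
    rlang::abort("strategy flags must be 0 or 1", class = "obsremedy_parse_error")
  }
  unknown <- setdiff(node, net$nodes)
  if (length(unknown)) {
    rlang::abort(paste0("strategy lists nodes not in the network: ",
                        paste(unknown, collapse = ", ")),
                 class = "obsremedy_parse_error")
  }
  if (anyDuplicated(node)) {
    rlang::abort("strategy lists a node twice", class = "obsremedy_parse_error")
  }
  missing <- setdiff(net$nodes, node)
  if (length(missing) && !default_unobserved) {
    rlang::abort(paste0("strategy is missing nodes (use default_unobserved ",
                        "to treat them as unobserved): ",
                        paste(missing, collapse = ", ")),
                 class = "obsremedy_parse_error")
  }
  obs <- rep(FALSE, net$n)
  obs[match(node, net$nodes)] <- flag == "1"
  tibble::tibble(node = net$nodes, observed = obs)
}

#' Write an observation strategy file
#'
#' @param strategy Anything accepted as an observation strategy (see
#'   [as_strategy()]).
#' @param net The network the strategy refers to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strategy <- function(strategy, net, path) {
  net <- as_network(net)
  obs <- as_strategy(net, strategy)
  writeLines(paste(net$nodes, as.integer(obs), sep = "\t"), path)
  invisible(path)
}
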
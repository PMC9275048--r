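#' Curated gene-gene interaction network
#'
#' Lightweight container for an undirected simple graph over gene symbols,
#' with per-edge provenance (the repositories each interaction came from).
#' Edges are stored in canonical lexicographic order (\code{from < to});
#' self-loops are forbidden and parallel edges are merged with provenance
#' unioned.
#'
#' @param edges data.frame with character columns \code{from}, \code{to}
#'   (gene symbols, uppercased on construction)
#' @param nodes optional character vector of node symbols; defaults to the
#'   edge endpoints. Extra isolated nodes are allowed.
#' @param provenance optional list (one character vector per edge row) of
#'   repository tags; defaults to empty tags
#' @return object of class \code{interaction_network}: a list with elements
#'   \code{nodes} (character), \code{edges} (data.frame \code{from},
#'   \code{to}) and \code{provenance} (list of character vectors, aligned
#'   with edge rows and sorted)
#' @export
interaction_network <- function(edges = NULL, nodes = NULL, provenance = NULL) {
  if (is.null(edges)) edges <- data.frame(from = character(), to = character())
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  from <- toupper(as.character(edges$from))
  to <- toupper(as.character(edges$to))
  if (any(from == to))
    stop_deggnet("self-loops are not allowed in an interaction_network")
  swap <- from > to
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  if (is.null(provenance)) provenance <- rep(list(character()), length(from))
  stopifnot(length(provenance) == length(from))
  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key)) {
    prov_by_key <- split(provenance, key)
    keep <- !duplicated(key)
    merged <- lapply(prov_by_key, function(ps) sort(unique(unlist(ps))))
    from <- from[keep]; to <- to[keep]; key <- key[keep]
    provenance <- merged[key]
  } else {
    provenance <- lapply(provenance, function(p) sort(unique(as.character(p))))
  }
  ord <- order(from, to)
  nodes <- sort(unique(c(toupper(as.character(nodes)), from, to)))
  structure(list(
    nodes = nodes,
    edges = data.frame(from = from[ord], to = to[ord],
                       stringsAsFactors = FALSE, row.names = NULL),
    provenance = unname(provenance[ord])
  ), class = "interaction_network")
}

edge_keys <- function(net) {
  paste(net$edges$from, net$edges$to, sep = "\r")
}

n_edges <- function(net) nrow(net$edges)

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              length(x$nodes), n_edges(x)))
  invisible(x)
}

#' @export
format.interaction_network <- function(x, ...) {
  sprintf("<interaction_network: %d nodes, %d edges>",
          length(x$nodes), n_edges(x))
}

#' Convert an interaction network to an igraph graph
#'
#' Provenance tags are collapsed with \code{";"} into an edge attribute so
#' GraphML export is lossless.
#'
#' @param net interaction_network
#' @return undirected simple \code{igraph} graph with vertex attribute
#'   \code{name} and edge attribute \code{provenance}
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (n_edges(net) > 0) {
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to))
    igraph::E(g)$provenance <-
      vapply(net$provenance, paste, "", collapse = ";")
  }
  g
}

#' Build an interaction network from an igraph graph
#'
#' @param g undirected igraph graph with vertex names; an optional
#'   \code{provenance} edge attribute (\code{";"}-separated tags) is split
#'   back into tag sets
#' @return interaction_network
#' @export
from_igraph <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  prov <- igraph::edge_attr(g, "provenance")
  if (is.null(prov)) {
    prov <- rep(list(character()), nrow(el))
  } else {
    prov <- lapply(strsplit(as.character(prov), ";", fixed = TRUE),
                   function(p) p[nzchar(p)])
  }
  interaction_network(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    nodes = igraph::V(g)$name, provenance = prov
  )
}

#' Merge curated interaction networks
#'
#' Node and edge sets are unioned; provenance tags of shared edges are
#' merged. Merging a network with itself returns an equal network.
#'
#' @param networks list of \code{interaction_network} objects (length >= 1)
#' @return merged \code{interaction_network}
#' @export
merge_networks <- function(networks) {
  if (inherits(networks, "interaction_network")) networks <- list(networks)
  if (!is.list(networks) || length(networks) < 1)
    stop_deggnet("merge_networks needs a non-empty list of networks",
                 "deggnet_argument")
  lapply(networks, function(n)
    stopifnot(inherits(n, "interaction_network")))
  edges <- do.call(rbind, lapply(networks, `[[`, "edges"))
  prov <- do.call(c, lapply(networks, `[[`, "provenance"))
  nodes <- sort(unique(unlist(lapply(networks, `[[`, "nodes"))))
  interaction_network(edges, nodes = nodes, provenance = prov)
}

#' Restrict a network to genes present in an expression matrix
#'
#' Nodes without measurements (and their incident edges) are removed; the
#' dropped counts are logged. An empty result is permitted with a warning.
#'
#' @param network interaction_network
#' @param expr numeric gene x sample matrix with gene rownames
#' @return restricted interaction_network
#' @export
restrict_to_measured <- function(network, expr) {
  stopifnot(inherits(network, "interaction_network"))
  validate_expr(expr)
  measured <- rownames(expr)
  keep_node <- network$nodes %in% measured
  keep_edge <- network$edges$from %in% measured &
    network$edges$to %in% measured
  dropped_nodes <- sum(!keep_node)
  dropped_edges <- sum(!keep_edge)
  if (dropped_nodes > 0 || dropped_edges > 0)
    deggnet_log("restrict_to_measured: dropped %d unmeasured nodes and %d incident edges",
                dropped_nodes, dropped_edges)
  out <- interaction_network(network$edges[keep_edge, , drop = FALSE],
                             nodes = network$nodes[keep_node],
                             provenance = network$provenance[keep_edge])
  if (length(out$nodes) == 0)
    warning("no network genes are measured; result is empty")
  out
}

# induced subgraph on a node subset, preserving provenance
induce_network <- function(network, keep_nodes) {
  keep_edge <- network$edges$from %in% keep_nodes &
    network$edges$to %in% keep_nodes
  interaction_network(network$edges[keep_edge, , drop = FALSE],
                      nodes = intersect(network$nodes, keep_nodes),
                      provenance = network$provenance[keep_edge])
}
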
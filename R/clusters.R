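# Community detection on subgroup-specific networks and gene-set
# enrichment with the percentage statistic and hypergeometric tail test.

#' Detect network clusters by greedy modularity maximization
#'
#' Communities are found with fast-greedy modularity optimization on the
#' undirected graph; vertices are iterated in canonical lexicographic
#' order so the partition is deterministic. Clusters smaller than
#' \code{min_size} are pooled into an \code{"unassigned"} bucket.
#'
#' @param network interaction_network (typically a specific_network)
#' @param min_size minimum cluster size (default 3)
#' @return named list of gene vectors (\code{C1}, \code{C2}, ... ordered
#'   by decreasing size), with attribute \code{unassigned} holding the
#'   pooled small-cluster genes
#' @export
detect_clusters <- function(network, min_size = 3) {
  stopifnot(inherits(network, "interaction_network"))
  if (length(network$nodes) == 0)
    stop_deggnet("detect_clusters on an empty network", "deggnet_argument")
  g <- as_igraph(network)
  g <- igraph::permute(g, match(igraph::V(g)$name, sort(igraph::V(g)$name)))
  comm <- igraph::cluster_fast_greedy(g)
  # cut the merge dendrogram at maximum modularity ourselves, breaking
  # near-ties (within 1e-12) toward fewer communities: the agglomerative
  # membership igraph reports can stop one merge short when the final
  # merge changes modularity by ~0 (e.g. complete graphs)
  q <- comm$modularity
  best <- max(which(q >= max(q) - 1e-12))
  n_comm <- igraph::vcount(g) - (best - 1L)
  membership <- if (n_comm >= length(comm))
    igraph::membership(comm) else igraph::cut_at(comm, no = n_comm)
  names(membership) <- igraph::V(g)$name
  groups <- split(names(membership), as.integer(membership))
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups),
               vapply(groups, `[[`, "", 1))
  groups <- groups[ord]
  big <- lengths(groups) >= min_size
  clusters <- groups[big]
  names(clusters) <- if (length(clusters))
    paste0("C", seq_along(clusters)) else NULL
  attr(clusters, "unassigned") <- sort(unlist(groups[!big], use.names = FALSE))
  clusters
}

#' Gene-set enrichment of one cluster
#'
#' For every term the overlap with the cluster is counted, the percentage
#' statistic \code{100 * n_in_term / cluster_size} is rounded to one
#' decimal (half to even), and the upper-tail hypergeometric probability
#' of observing at least that overlap when drawing \code{cluster_size}
#' genes from the universe is computed. P-values are
#' Benjamini-Hochberg-adjusted across terms; rows are sorted by raw p.
#'
#' @param cluster_genes character vector (must be a subset of the
#'   universe)
#' @param sets gene_set_collection from [read_gmt()] (or a named list of
#'   gene vectors)
#' @param universe background gene list; each set is intersected with it
#'   before testing
#' @return data.frame of class \code{cluster_enrichment} with columns
#'   term, n_in_term, cluster_size, percentage, p_hyper, p_adj
#' @export
enrich <- function(cluster_genes, sets, universe) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0)
    stop_deggnet("empty universe", "deggnet_argument")
  cluster_genes <- unique(toupper(cluster_genes))
  outside <- setdiff(cluster_genes, universe)
  if (length(outside) > 0)
    stop_deggnet(sprintf("cluster genes outside the universe: %s",
                         paste(utils::head(outside, 5), collapse = ", ")),
                 "deggnet_validation")
  set_genes <- if (inherits(sets, "gene_set_collection"))
    lapply(sets, `[[`, "genes") else sets
  stopifnot(is.list(set_genes), !is.null(names(set_genes)))
  N <- length(universe)
  n <- length(cluster_genes)
  rows <- lapply(names(set_genes), function(term) {
    term_genes <- intersect(toupper(set_genes[[term]]), universe)
    K <- length(term_genes)
    k <- length(intersect(cluster_genes, term_genes))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, n_in_term = k, cluster_size = n,
               percentage = enrichment_percentage(k, n),
               p_hyper = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_bh(out$p_hyper)
  out <- out[order(out$p_hyper, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cluster_enrichment", "data.frame")
  out
}

#' Cluster and enrich a specific network
#'
#' Convenience wrapper: [detect_clusters()] then [enrich()] per cluster;
#' the top term of each cluster serves as its label.
#'
#' @param network interaction_network / specific_network
#' @param sets gene_set_collection
#' @param universe background genes (default: the network's node set)
#' @param min_size minimum cluster size
#' @return data.frame with cluster_id, genes (comma-joined), and the
#'   [enrich()] columns for every cluster x term combination; per-cluster
#'   top labels in attribute \code{labels}
#' @export
enrich_clusters <- function(network, sets, universe = NULL, min_size = 3) {
  clusters <- detect_clusters(network, min_size = min_size)
  if (is.null(universe)) universe <- network$nodes
  rows <- lapply(names(clusters), function(cid) {
    e <- enrich(clusters[[cid]], sets, universe)
    cbind(data.frame(cluster_id = cid,
                     genes = paste(clusters[[cid]], collapse = ","),
                     stringsAsFactors = FALSE), e)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(cluster_id = character(), genes = character(),
               term = character(), n_in_term = integer(),
               cluster_size = integer(), percentage = numeric(),
               p_hyper = numeric(), p_adj = numeric())
  labels <- vapply(names(clusters), function(cid) {
    sub <- out[out$cluster_id == cid, , drop = FALSE]
    if (nrow(sub) == 0) NA_character_ else sub$term[1]
  }, "")
  attr(out, "labels") <- labels
  attr(out, "clusters") <- clusters
  rownames(out) <- NULL
  out
}
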
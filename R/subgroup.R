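# Subgroup-specific network construction: node weighting by mean
# subgroup expression, percolation-guided weight thresholding, and
# extraction of edges unique to one subgroup.

#' Weight network nodes by mean subgroup expression
#'
#' The curated network is replicated once per subgroup and every node is
#' weighted with the arithmetic mean of its log-expression across that
#' subgroup's samples.
#'
#' @param expr numeric gene x sample matrix
#' @param annot annotation data.frame with \code{sample_id} and
#'   \code{subgroup}; every subgroup needs at least 2 samples
#' @param network interaction_network; genes not measured are dropped
#'   first via [restrict_to_measured()]
#' @return named list (one element per subgroup level) of
#'   \code{weighted_network} objects: \code{list(subgroup, network,
#'   weight)} with \code{weight} a named numeric vector over nodes
#' @export
compute_weights <- function(expr, annot, network) {
  validate_expr(expr)
  validate_annotation(annot)
  stopifnot(inherits(network, "interaction_network"))
  missing_samples <- setdiff(annot$sample_id, colnames(expr))
  if (length(missing_samples) > 0)
    stop_deggnet(sprintf("annotated samples not in expression matrix: %s",
                         paste(utils::head(missing_samples, 5), collapse = ", ")),
                 "deggnet_validation")
  net <- restrict_to_measured(network, expr)
  groups <- levels(droplevels(factor(annot$subgroup)))
  sizes <- table(factor(annot$subgroup, levels = groups))
  if (any(sizes < 2))
    stop_deggnet(sprintf("subgroup(s) with < 2 samples: %s",
                         paste(names(sizes)[sizes < 2], collapse = ", ")),
                 "deggnet_validation")
  out <- lapply(groups, function(g) {
    ids <- annot$sample_id[annot$subgroup == g]
    w <- rowMeans(expr[net$nodes, ids, drop = FALSE])
    structure(list(subgroup = g, network = net, weight = w),
              class = "weighted_network")
  })
  names(out) <- groups
  out
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("weighted_network '%s': %d nodes, %d edges, weight range [%.3g, %.3g]\n",
              x$subgroup, length(x$network$nodes), n_edges(x$network),
              min(x$weight), max(x$weight)))
  invisible(x)
}

#' Percolation scan over weight-percentile thresholds
#'
#' For each percentile \code{p} of the grid the threshold is the p-th
#' percentile of the node weights (linear interpolation between order
#' statistics); nodes with weight strictly below the threshold are
#' removed and the component structure of the induced subgraph is
#' profiled. The giant-connected-component (GCC) fraction is the
#' percolation order parameter; the percentile maximising the size of the
#' second-largest component is reported as the percolation-transition
#' diagnostic.
#'
#' @param wnet weighted_network from [compute_weights()]
#' @param percentile_grid strictly increasing values in \[0, 100)
#' @param gcc_min_fraction select the largest grid percentile whose GCC
#'   fraction is still at least this value (default 0.5)
#' @return \code{percolation_profile}: a list with a \code{profile}
#'   data.frame (percentile, threshold, nodes_retained, gcc_size,
#'   gcc_fraction, second_component_size), \code{selected_percentile}
#'   (gcc-fraction rule) and \code{transition_percentile} (argmax of the
#'   second component size)
#' @export
percolation_scan <- function(wnet, percentile_grid = seq(0, 95, by = 5),
                             gcc_min_fraction = 0.5) {
  stopifnot(inherits(wnet, "weighted_network"))
  if (length(wnet$network$nodes) == 0)
    stop_deggnet("percolation_scan on an empty network", "deggnet_argument")
  p <- as.numeric(percentile_grid)
  if (length(p) == 0 || any(diff(p) <= 0) || any(p < 0) || any(p >= 100))
    stop_deggnet("percentile_grid must be strictly increasing in [0, 100)",
                 "deggnet_argument")
  g <- as_igraph(wnet$network)
  w <- wnet$weight[igraph::V(g)$name]
  rows <- lapply(p, function(pi) {
    thr <- weight_percentile(w, pi)
    keep <- which(w >= thr)
    sub <- igraph::induced_subgraph(g, keep)
    comp <- igraph::components(sub)$csize
    comp <- sort(comp, decreasing = TRUE)
    gcc <- if (length(comp)) comp[1] else 0L
    second <- if (length(comp) > 1) comp[2] else 0L
    data.frame(percentile = pi, threshold = thr,
               nodes_retained = length(keep), gcc_size = gcc,
               gcc_fraction = if (length(keep)) gcc / length(keep) else NA_real_,
               second_component_size = second)
  })
  profile <- do.call(rbind, rows)
  ok <- which(profile$gcc_fraction >= gcc_min_fraction)
  selected <- if (length(ok)) profile$percentile[max(ok)] else profile$percentile[1]
  structure(list(
    subgroup = wnet$subgroup,
    profile = profile,
    selected_percentile = selected,
    transition_percentile = profile$percentile[which.max(profile$second_component_size)]
  ), class = "percolation_profile")
}

#' @export
print.percolation_profile <- function(x, ...) {
  cat(sprintf("percolation_profile ('%s'): %d grid points; selected percentile %g (gcc rule); transition diagnostic at %g\n",
              x$subgroup %||% "?", nrow(x$profile), x$selected_percentile,
              x$transition_percentile))
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' @export
plot.percolation_profile <- function(x, ...) {
  pr <- x$profile
  plot(pr$percentile, pr$gcc_fraction, type = "b", ylim = c(0, 1),
       xlab = "weight percentile threshold", ylab = "GCC fraction",
       main = sprintf("Percolation profile (%s)", x$subgroup %||% ""), ...)
  graphics::abline(v = x$selected_percentile, lty = 2)
  invisible(x)
}

#' Filter a weighted network at a weight percentile
#'
#' Nodes with weight strictly below the percentile threshold are removed
#' (ties at the threshold are kept); the induced subgraph is returned
#' with nodes left isolated by the filtering dropped. The full set of
#' weight-passing genes (before isolate pruning) is attached as attribute
#' \code{kept_genes}.
#'
#' @param wnet weighted_network
#' @param percentile value in \[0, 100)
#' @return interaction_network with attribute \code{kept_genes}
#' @export
filter_by_weight <- function(wnet, percentile = 75) {
  stopifnot(inherits(wnet, "weighted_network"),
            percentile >= 0, percentile < 100)
  thr <- weight_percentile(wnet$weight, percentile)
  kept <- names(wnet$weight)[wnet$weight >= thr]
  out <- induce_network(wnet$network, kept)
  connected <- unique(c(out$edges$from, out$edges$to))
  out <- interaction_network(out$edges, nodes = connected,
                             provenance = out$provenance)
  attr(out, "kept_genes") <- sort(kept)
  attr(out, "threshold") <- thr
  attr(out, "subgroup") <- wnet$subgroup
  out
}

#' Extract subgroup-specific edge sets
#'
#' An edge belongs to subgroup k's specific network iff it occurs in k's
#' filtered network and in no other subgroup's; edges present in two or
#' more filtered networks are discarded from all (returned in attribute
#' \code{discarded}).
#'
#' @param filtered named list (>= 2 subgroups) of interaction_network
#' @return named list of \code{specific_network} objects (an
#'   interaction_network subclass whose nodes are the edge endpoints),
#'   with attribute \code{discarded}: the overlap edge set
#' @export
extract_specific <- function(filtered) {
  if (!is.list(filtered) || length(filtered) < 2)
    stop_deggnet("extract_specific needs filtered networks for >= 2 subgroups",
                 "deggnet_argument")
  if (is.null(names(filtered)) || any(!nzchar(names(filtered))))
    stop_deggnet("filtered networks must be named by subgroup",
                 "deggnet_argument")
  keys <- lapply(filtered, edge_keys)
  counts <- table(unlist(keys))
  out <- lapply(names(filtered), function(g) {
    net <- filtered[[g]]
    unique_edge <- counts[edge_keys(net)] == 1
    endpoints <- unique(c(net$edges$from[unique_edge],
                          net$edges$to[unique_edge]))
    sn <- interaction_network(net$edges[unique_edge, , drop = FALSE],
                              nodes = endpoints,
                              provenance = net$provenance[unique_edge])
    sn$subgroup <- g
    class(sn) <- c("specific_network", class(sn))
    sn
  })
  names(out) <- names(filtered)
  shared <- names(counts)[counts >= 2]
  discarded <- do.call(rbind, strsplit(shared, "\r", fixed = TRUE))
  attr(out, "discarded") <- if (is.null(discarded))
    data.frame(from = character(), to = character())
  else data.frame(from = discarded[, 1], to = discarded[, 2],
                  stringsAsFactors = FALSE)
  out
}

#' @export
print.specific_network <- function(x, ...) {
  cat(sprintf("specific_network '%s': %d nodes, %d subgroup-unique edges\n",
              x$subgroup %||% "?", length(x$nodes), n_edges(x)))
  invisible(x)
}
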
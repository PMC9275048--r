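# Readers and writers for the external formats the pipeline touches:
# TSV expression, CSV/TSV annotation, SIF-like interactions, GMT gene
# sets, GraphML/JSON networks and the edge-result table.

#' Read a log-scale expression matrix
#'
#' Expects genes in rows: first column gene symbols, header row sample
#' identifiers, remaining cells numeric log-scale expression. Symbols are
#' uppercased. Duplicate gene rows are collapsed by keeping the row with
#' the highest mean (logged); a non-numeric cell is a parse error naming
#' its row and column.
#'
#' @param path file path
#' @param delimiter field separator, default tab
#' @return numeric matrix, gene rownames x sample colnames
#' @export
read_expression <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop_deggnet(sprintf("file not found: %s", path))
  if (file.size(path) == 0)
    stop_deggnet(sprintf("empty expression file: %s", path), "deggnet_format")
  raw <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(raw) == 0 || ncol(raw) < 2)
    stop_deggnet(sprintf("expression file has no data cells: %s", path),
                 "deggnet_format")
  genes <- toupper(trimws(raw[[1]]))
  samples <- colnames(raw)[-1]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop_deggnet(sprintf(
      "non-numeric expression value '%s' for gene '%s' (row %d), sample '%s'",
      vals[i, j], genes[i], i, samples[j]), "deggnet_parse")
  }
  dimnames(num) <- list(genes, samples)
  if (anyDuplicated(samples))
    stop_deggnet("duplicated sample ids in expression header")
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    deggnet_log("collapsing %d duplicated gene symbol(s) by max mean: %s",
                length(dup), paste(utils::head(dup, 5), collapse = ", "))
    means <- rowMeans(num)
    keep <- unlist(lapply(split(seq_along(genes), genes),
                          function(idx) idx[which.max(means[idx])]))
    num <- num[sort(keep), , drop = FALSE]
  }
  validate_expr(num)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; values are written with full double
#' precision so a read-back reproduces the matrix exactly.
#'
#' @param expr numeric gene x sample matrix
#' @param path output path
#' @export
write_expression <- function(expr, path) {
  validate_expr(expr)
  df <- data.frame(gene = rownames(expr),
                   format(expr, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation table
#'
#' Requires columns \code{sample_id} and \code{subgroup}; an optional
#' \code{response} column is validated against the three-level EULAR set
#' (Good / Moderate / None, case-insensitive; empty or NA cells become
#' missing). Any further columns are kept as covariates.
#'
#' @param path file path (CSV or TSV; the delimiter is sniffed from the
#'   header line unless given)
#' @param delimiter optional field separator
#' @return data.frame with factor \code{subgroup} and factor
#'   \code{response} (levels Good, Moderate, None)
#' @export
read_annotation <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop_deggnet(sprintf("file not found: %s", path))
  if (is.null(delimiter)) {
    header <- readLines(path, n = 1)
    delimiter <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_annotation(df)
  df$sample_id <- as.character(df$sample_id)
  df$subgroup <- factor(as.character(df$subgroup))
  if ("response" %in% names(df)) {
    r <- trimws(as.character(df$response))
    r[r == "" | toupper(r) == "NA"] <- NA
    matched <- response_levels[match(tolower(r), tolower(response_levels))]
    bad <- !is.na(r) & is.na(matched)
    if (any(bad))
      stop_deggnet(sprintf("unknown response label(s): %s",
                           paste(unique(r[bad]), collapse = ", ")),
                   "deggnet_validation")
    df$response <- factor(matched, levels = response_levels)
  } else {
    df$response <- factor(rep(NA_character_, nrow(df)),
                          levels = response_levels)
  }
  df
}

#' Read a SIF-like curated interaction table
#'
#' Each row is \code{geneA <tab> relation <tab> geneB}. The graph is made
#' undirected and simple: self-loops are dropped (count logged), parallel
#' and reversed duplicates merged with the relation/provenance strings
#' unioned.
#'
#' @param path file path
#' @return interaction_network
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop_deggnet(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(interaction_network())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # fall back to whitespace splitting for space-separated SIF
  fields <- lapply(fields, function(f)
    if (length(f) == 1) strsplit(trimws(f[1]), "[ \t]+")[[1]] else f)
  nf <- lengths(fields)
  if (any(nf != 3))
    stop_deggnet(sprintf("interaction row with %d fields (expected 3) at line %d",
                         nf[which(nf != 3)[1]], which(nf != 3)[1]),
                 "deggnet_parse")
  m <- do.call(rbind, fields)
  from <- toupper(m[, 1]); rel <- m[, 2]; to <- toupper(m[, 3])
  loops <- from == to
  if (any(loops))
    deggnet_log("dropped %d self-loop(s)", sum(loops))
  interaction_network(
    data.frame(from = from[!loops], to = to[!loops],
               stringsAsFactors = FALSE),
    provenance = as.list(rel[!loops])
  )
}

#' Read a GMT gene-set collection
#'
#' GMT: one set per line, tab-separated \code{term, description,
#' gene...}. Symbols are uppercased; a line with fewer than three fields
#' is a parse error.
#'
#' @param path file path
#' @return object of class \code{gene_set_collection}: a named list of
#'   \code{list(description, genes)}
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_deggnet(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop_deggnet(sprintf("GMT line %d has %d fields (need >= 3)",
                         which(nf < 3)[1], nf[which(nf < 3)[1]]),
                 "deggnet_parse")
  terms <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(terms))
    stop_deggnet("duplicated term names in GMT", "deggnet_validation")
  sets <- lapply(fields, function(f)
    list(description = f[2], genes = unique(toupper(f[-(1:2)]))))
  names(sets) <- terms
  structure(sets, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (median size %g)\n", length(x),
              stats::median(vapply(x, function(s) length(s$genes), 0L))))
  invisible(x)
}

#' Write a differential-edge result table
#'
#' Fixed, documented TSV: one row per tested edge, header always written
#' (an empty result yields a header-only file).
#'
#' @param results data.frame as returned by [scan_network()]
#' @param path output path
#' @export
write_edge_table <- function(results, path) {
  stopifnot(is.data.frame(results))
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a network to GraphML or JSON
#'
#' Both formats round-trip losslessly through [read_network()]: node set,
#' edge set and provenance are preserved exactly.
#'
#' @param network interaction_network
#' @param path output path
#' @param format "graphml" or "json"
#' @export
export_network <- function(network, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "interaction_network"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(network), path, format = "graphml")
  } else {
    obj <- list(
      nodes = lapply(network$nodes, function(n) list(id = n)),
      edges = mapply(function(f, t, p)
        list(from = f, to = t, provenance = as.list(p)),
        network$edges$from, network$edges$to, network$provenance,
        SIMPLIFY = FALSE, USE.NAMES = FALSE)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read a network written by [export_network()]
#'
#' @param path file path
#' @param format "graphml" or "json"; guessed from the extension when
#'   missing
#' @return interaction_network
#' @export
read_network <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "graphml"
  format <- match.arg(format, c("graphml", "json"))
  if (format == "graphml") {
    from_igraph(igraph::read_graph(path, format = "graphml"))
  } else {
    obj <- jsonlite::read_json(path)
    edges <- data.frame(
      from = vapply(obj$edges, `[[`, "", "from"),
      to = vapply(obj$edges, `[[`, "", "to"),
      stringsAsFactors = FALSE)
    interaction_network(
      edges,
      nodes = vapply(obj$nodes, `[[`, "", "id"),
      provenance = lapply(obj$edges, function(e)
        unlist(e$provenance) %||% character()))
  }
}
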
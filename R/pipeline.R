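# End-to-end orchestration of the two workflows: subgroup (pathotype)
# networks and responder/non-responder prediction.

#' Pipeline configuration
#'
#' Validated bundle of input paths and tuning parameters shared by
#' [run_pathotype()] and [run_response()]. Validation is fail-fast:
#' paths and annotation columns are checked before the expression
#' matrix is parsed.
#'
#' @param expr path to the expression TSV
#' @param annot path to the annotation CSV/TSV
#' @param interactions path to the SIF-like interaction table
#' @param gmt optional path to a GMT gene-set file
#' @param group_col annotation column holding the subgroup label
#' @param response_col annotation column holding the response label
#' @param percentile weight-filter percentile (default 75)
#' @param percentile_grid grid for the percolation scan
#' @param alpha raw-p cutoff for carrying edges into response models
#' @param covariates additive covariate column names
#' @param term interaction-term mode for the logistic models
#' @param seed integer seed recorded in outputs
#' @param out_dir output directory
#' @return list of class \code{pipeline_config}
#' @export
pipeline_config <- function(expr, annot, interactions, gmt = NULL,
                            group_col = "subgroup",
                            response_col = "response",
                            percentile = 75,
                            percentile_grid = seq(0, 95, by = 5),
                            alpha = 0.05,
                            covariates = character(),
                            term = c("product", "ratio"),
                            seed = 1L,
                            out_dir = ".") {
  term <- match.arg(term)
  for (p in c(expr, annot, interactions, gmt))
    if (!file.exists(p))
      stop_deggnet(sprintf("input file not found: %s", p), "deggnet_config")
  if (percentile < 0 || percentile >= 100)
    stop_deggnet("percentile must lie in [0, 100)", "deggnet_config")
  header <- names(utils::read.delim(
    annot, nrows = 1, sep = if (grepl("\\.csv$", annot)) "," else "\t",
    check.names = FALSE))
  for (col in c(group_col, covariates))
    if (!col %in% header)
      stop_deggnet(sprintf("annotation lacks column '%s'", col),
                   "deggnet_config")
  structure(list(expr = expr, annot = annot, interactions = interactions,
                 gmt = gmt, group_col = group_col,
                 response_col = response_col, percentile = percentile,
                 percentile_grid = percentile_grid, alpha = alpha,
                 covariates = covariates, term = term,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  # hash the scientific configuration only: the output location must not
  # change the recorded identity of a run
  x <- unclass(config)
  x$out_dir <- NULL
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

output_header <- function(config) {
  sprintf("# deggnet %s | config %s | seed %d",
          as.character(utils::packageVersion("deggnet")),
          config_hash(config), config$seed)
}

write_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

load_inputs <- function(config, group_col) {
  annot <- read_annotation(config$annot)
  if (group_col != "subgroup") {
    if (!group_col %in% names(annot))
      stop_deggnet(sprintf("annotation lacks column '%s'", group_col),
                   "deggnet_config")
    annot$subgroup <- factor(annot[[group_col]])
  }
  expr <- read_expression(config$expr)
  network <- restrict_to_measured(read_interactions(config$interactions),
                                  expr)
  list(expr = expr, annot = annot, network = network)
}

run_network_stages <- function(expr, annot, network, config) {
  weighted <- compute_weights(expr, annot, network)
  profiles <- lapply(weighted, percolation_scan,
                     percentile_grid = config$percentile_grid)
  filtered <- lapply(weighted, filter_by_weight,
                     percentile = config$percentile)
  specific <- extract_specific(filtered)
  scans <- lapply(specific, function(sn)
    scan_network(sn, expr, annot, covariates = config$covariates))
  list(weighted = weighted, profiles = profiles, filtered = filtered,
       specific = specific, scans = scans)
}

#' Run the subgroup-network (pathotype) workflow
#'
#' Node weighting, percolation profiling, weight filtering, overlap
#' removal, differential-interaction scanning, cluster detection and
#' enrichment, executed per subgroup. Writes per-subgroup GraphML,
#' edge and cluster TSVs, a percolation-profile TSV, and a markdown
#' summary into the configured output directory; every tabular output
#' starts with a header comment carrying package version, config hash
#' and seed.
#'
#' @param config pipeline_config
#' @return report list (profiles, specific networks, edge scans,
#'   cluster enrichments, written paths), invisibly
#' @export
run_pathotype <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  inputs <- load_inputs(config, config$group_col)
  stages <- run_network_stages(inputs$expr, inputs$annot, inputs$network,
                               config)
  sets <- if (!is.null(config$gmt)) read_gmt(config$gmt)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- output_header(config)
  paths <- character()
  enrichments <- list()
  for (g in names(stages$specific)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", g)
    gml <- file.path(config$out_dir, sprintf("specific_%s.graphml", safe))
    export_network(stages$specific[[g]], gml, "graphml")
    etsv <- file.path(config$out_dir, sprintf("edges_%s.tsv", safe))
    write_with_header(stages$scans[[g]], etsv, hdr)
    ptsv <- file.path(config$out_dir, sprintf("percolation_%s.tsv", safe))
    write_with_header(stages$profiles[[g]]$profile, ptsv, hdr)
    paths <- c(paths, gml, etsv, ptsv)
    if (!is.null(sets) && n_edges(stages$specific[[g]]) > 0) {
      enr <- enrich_clusters(stages$specific[[g]], sets)
      enrichments[[g]] <- enr
      ctsv <- file.path(config$out_dir, sprintf("clusters_%s.tsv", safe))
      write_with_header(enr, ctsv, hdr)
      paths <- c(paths, ctsv)
    }
  }
  summary_md <- file.path(config$out_dir, "summary_pathotype.md")
  lines <- c(hdr, "", "# Subgroup-specific network summary", "")
  for (g in names(stages$specific)) {
    sc <- stages$scans[[g]]
    lines <- c(lines, sprintf(
      "- **%s**: %d specific edges, %d tested, %d with adjusted p < 0.05 (selected percentile %g)",
      g, n_edges(stages$specific[[g]]), nrow(sc),
      sum(sc$p_adj < 0.05), stages$profiles[[g]]$selected_percentile))
  }
  writeLines(lines, summary_md)
  invisible(list(profiles = stages$profiles, specific = stages$specific,
                 scans = stages$scans, enrichments = enrichments,
                 paths = c(paths, summary_md)))
}

#' Run the responder-prediction workflow
#'
#' Reduces samples to Good vs None responders, runs the same network
#' stages with response as the grouping, carries significant edges into
#' ratio-logistic models, and writes a models TSV plus per-pair ROC
#' coordinate TSVs.
#'
#' @param config pipeline_config
#' @return report list (edge scans, model table, written paths),
#'   invisibly
#' @export
run_response <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  inputs <- load_inputs(config, config$group_col)
  annot <- select_response_samples(inputs$annot)
  annot$subgroup <- droplevels(annot$response)
  expr <- inputs$expr[, annot$sample_id, drop = FALSE]
  stages <- run_network_stages(expr, annot, inputs$network, config)
  nonempty <- stages$scans[vapply(stages$scans, nrow, 0L) > 0]
  all_scans <- if (length(nonempty)) do.call(rbind, unname(nonempty))
    else data.frame(gene_a = character(), gene_b = character(),
                    p_raw = numeric())
  models <- evaluate_pairs(all_scans, expr, annot,
                           covariates = config$covariates,
                           alpha = config$alpha, term = config$term)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- output_header(config)
  mtsv <- file.path(config$out_dir, "models.tsv")
  write_with_header(models, mtsv, hdr)
  paths <- mtsv
  fits <- attr(models, "models")
  for (m in fits) {
    roc <- roc_auc(m$fitted, m$model$y)
    rtsv <- file.path(config$out_dir,
                      sprintf("roc_%s_%s.tsv", m$gene_1, m$gene_2))
    write_with_header(
      data.frame(threshold = roc$thresholds, fpr = roc$fpr, tpr = roc$tpr),
      rtsv, hdr)
    paths <- c(paths, rtsv)
  }
  invisible(list(scans = stages$scans, models = models, paths = paths))
}
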
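# Synthetic-study generator: log-scale expression with planted
# subgroup-specific gene-gene relations, a binary response driven by a
# planted two-gene interaction, an age-like covariate, and a curated
# network scaffold, so every pipeline stage is testable without
# external data.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline targets: three
#' histology subgroups of sizes 49/18/16, log-scale expression with
#' gene-specific baselines, subgroup-specific linear relations on
#' planted edges (slope difference 1, unit noise), a binary response
#' with a planted two-gene interaction effect, and an age covariate
#' (mean 52, sd 16 years).
#'
#' @param n_genes number of genes
#' @param group_sizes named integer vector of subgroup sample counts
#' @param n_planted_edges number of planted differential edges
#' @param slope_per_group named numeric: per-subgroup slope of each
#'   planted relation (names must match \code{group_sizes})
#' @param noise_sd residual sd of the planted relations
#' @param group_shift_sd sd of the per-gene, per-subgroup baseline
#'   shift (log units); this is what makes subgroup mean expression --
#'   and hence the weight-filtered networks -- differ between subgroups
#' @param response_effect log-odds coefficient on the planted pair's
#'   standardized product interaction term
#' @param age_mean,age_sd age covariate distribution (years)
#' @param age_effect log-odds coefficient on standardized age
#' @param moderate_frac fraction of samples relabelled Moderate
#' @param n_background_edges Erdos-Renyi background edges in the
#'   scaffold network
#' @param n_random_sets,random_set_size random gene sets accompanying
#'   the planted-module set
#' @param seed integer seed; one global stream drives the whole study
#' @return validated list of class \code{sim_config}
#' @export
sim_config <- function(n_genes = 120,
                       group_sizes = c(LM = 49, DM = 18, PF = 16),
                       n_planted_edges = 5,
                       slope_per_group = NULL,
                       noise_sd = 1,
                       group_shift_sd = 1,
                       response_effect = 2,
                       age_mean = 52, age_sd = 16,
                       age_effect = 0.5,
                       moderate_frac = 0,
                       n_background_edges = 150,
                       n_random_sets = 5, random_set_size = 10,
                       seed = 1L) {
  if (is.null(slope_per_group)) {
    slope_per_group <- setNames(rep(0, length(group_sizes)),
                                names(group_sizes))
    slope_per_group[1] <- 1
  }
  cfg <- list(n_genes = as.integer(n_genes),
              group_sizes = group_sizes,
              n_planted_edges = as.integer(n_planted_edges),
              slope_per_group = slope_per_group,
              noise_sd = noise_sd, group_shift_sd = group_shift_sd,
              response_effect = response_effect,
              age_mean = age_mean, age_sd = age_sd,
              age_effect = age_effect, moderate_frac = moderate_frac,
              n_background_edges = as.integer(n_background_edges),
              n_random_sets = as.integer(n_random_sets),
              random_set_size = as.integer(random_set_size),
              seed = as.integer(seed))
  if (cfg$n_genes < 2 * cfg$n_planted_edges + 2)
    stop_deggnet("n_genes too small for the requested planted edges",
                 "deggnet_config")
  if (is.null(names(cfg$group_sizes)) ||
      !identical(sort(names(cfg$group_sizes)),
                 sort(names(cfg$slope_per_group))))
    stop_deggnet("group_sizes and slope_per_group must share names",
                 "deggnet_config")
  if (any(cfg$group_sizes < 3))
    stop_deggnet("every subgroup needs >= 3 samples", "deggnet_config")
  if (cfg$noise_sd <= 0)
    stop_deggnet("noise_sd must be positive", "deggnet_config")
  if (cfg$moderate_frac < 0 || cfg$moderate_frac >= 1)
    stop_deggnet("moderate_frac must lie in [0, 1)", "deggnet_config")
  structure(cfg, class = "sim_config")
}

#' Simulate a complete synthetic study
#'
#' Baseline log-expression of gene g in subgroup k is
#' Normal(mu_g + s_gk, 1) with mu_g ~ Uniform(2, 10) and a per-subgroup
#' baseline shift s_gk ~ Normal(0, group_shift_sd) that differentiates
#' the subgroups' mean expression. For each planted edge (x, y) the response gene
#' follows \code{y = mu_y + b_k (x - mu_x) + Normal(0, noise_sd)} within
#' subgroup k. The scaffold network is the planted edges plus uniform
#' random background edges over independent genes. The binary response
#' is Bernoulli(plogis(beta * z1 * z2 + gamma * age_std)) where z1, z2
#' are the standardized expressions of the planted response pair (the
#' first planted edge) and beta is \code{response_effect}. Gene sets:
#' one module covering the planted-edge genes plus random sets.
#' Everything is reproducible from the single seed.
#'
#' @param config sim_config
#' @return list of class \code{sim_study}: \code{expr} (matrix),
#'   \code{annot} (data.frame), \code{network} (interaction_network),
#'   \code{gene_sets} (gene_set_collection), \code{truth} (planted
#'   edges with per-group slopes, planted response pair, seed)
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_genes <- config$n_genes
  genes <- sprintf("G%04d", seq_len(n_genes))
  groups <- names(config$group_sizes)
  n_samples <- sum(config$group_sizes)
  samples <- sprintf("S%03d", seq_len(n_samples))
  subgroup <- factor(rep(groups, times = config$group_sizes),
                     levels = groups)

  mu <- stats::runif(n_genes, 2, 10)
  # per-gene, per-subgroup baseline shift: what distinguishes the
  # subgroups' mean expression (and therefore their filtered networks)
  shift <- matrix(stats::rnorm(n_genes * length(groups),
                               sd = config$group_shift_sd),
                  nrow = n_genes, dimnames = list(genes, groups))
  mu_gk <- mu + shift  # genes x groups
  expr <- matrix(NA_real_, nrow = n_genes, ncol = n_samples,
                 dimnames = list(genes, samples))
  for (k in groups) {
    in_k <- subgroup == k
    expr[, in_k] <- matrix(
      stats::rnorm(n_genes * sum(in_k), mean = mu_gk[, k], sd = 1),
      nrow = n_genes)
  }

  planted_idx <- matrix(seq_len(2 * config$n_planted_edges), ncol = 2,
                        byrow = TRUE)
  planted <- data.frame(
    predictor = genes[planted_idx[, 1]],
    response = genes[planted_idx[, 2]],
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(planted))) {
    xg <- planted$predictor[i]; yg <- planted$response[i]
    for (k in groups) {
      in_k <- subgroup == k
      b <- config$slope_per_group[[k]]
      expr[yg, in_k] <- mu_gk[yg, k] +
        b * (expr[xg, in_k] - mu_gk[xg, k]) +
        stats::rnorm(sum(in_k), sd = config$noise_sd)
    }
  }

  # scaffold: planted edges + background edges over all remaining pairs
  all_pairs <- t(utils::combn(n_genes, 2))
  pair_key <- paste(all_pairs[, 1], all_pairs[, 2])
  planted_key <- paste(pmin(planted_idx[, 1], planted_idx[, 2]),
                       pmax(planted_idx[, 1], planted_idx[, 2]))
  candidates <- which(!(pair_key %in% planted_key))
  bg <- sample(candidates, min(config$n_background_edges,
                               length(candidates)))
  edges <- rbind(
    data.frame(from = planted$predictor, to = planted$response,
               stringsAsFactors = FALSE),
    data.frame(from = genes[all_pairs[bg, 1]], to = genes[all_pairs[bg, 2]],
               stringsAsFactors = FALSE))
  network <- interaction_network(
    edges, provenance = c(rep(list("planted"), nrow(planted)),
                          rep(list("background"), length(bg))))

  age <- stats::rnorm(n_samples, config$age_mean, config$age_sd)
  pair <- c(planted$predictor[1], planted$response[1])
  z1 <- as.numeric(scale(expr[pair[1], ]))
  z2 <- as.numeric(scale(expr[pair[2], ]))
  eta <- config$response_effect * z1 * z2 +
    config$age_effect * as.numeric(scale(age))
  good <- stats::rbinom(n_samples, 1, stats::plogis(eta))
  response <- ifelse(good == 1, "Good", "None")
  if (config$moderate_frac > 0) {
    n_mod <- round(config$moderate_frac * n_samples)
    response[sample(n_samples, n_mod)] <- "Moderate"
  }
  annot <- data.frame(sample_id = samples,
                      subgroup = subgroup,
                      response = factor(response, levels = response_levels),
                      age = age,
                      stringsAsFactors = FALSE)

  sets <- list(PLANTED_MODULE = list(
    description = "genes of the planted differential edges",
    genes = sort(unique(c(planted$predictor, planted$response)))))
  for (i in seq_len(config$n_random_sets)) {
    sets[[sprintf("RANDOM_SET_%02d", i)]] <- list(
      description = "random background gene set",
      genes = sort(sample(genes, config$random_set_size)))
  }
  gene_sets <- structure(sets, class = "gene_set_collection")

  truth <- list(
    planted_edges = cbind(planted,
                          as.data.frame(as.list(config$slope_per_group))),
    planted_response_pair = pair,
    response_effect = config$response_effect,
    seed = config$seed)

  structure(list(expr = expr, annot = annot, network = network,
                 gene_sets = gene_sets, truth = truth, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("sim_study: %d genes x %d samples, %d subgroups, %d planted edges (seed %d)\n",
              nrow(x$expr), ncol(x$expr),
              length(x$config$group_sizes),
              x$config$n_planted_edges, x$config$seed))
  invisible(x)
}

#' Write a simulated study to pipeline input files
#'
#' Emits the four standard inputs (expression TSV, annotation CSV,
#' interaction SIF, gene-set GMT) plus a JSON record of the planted
#' truth.
#'
#' @param study sim_study
#' @param dir output directory (created if needed)
#' @return named vector of written paths, invisibly
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expr = file.path(dir, "expression.tsv"),
    annot = file.path(dir, "annotation.csv"),
    interactions = file.path(dir, "interactions.sif"),
    gmt = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json"))
  write_expression(study$expr, paths["expr"])
  utils::write.table(study$annot, paths["annot"], sep = ",",
                     quote = FALSE, row.names = FALSE)
  sif <- data.frame(
    from = study$network$edges$from,
    rel = vapply(study$network$provenance, function(p)
      paste(p, collapse = "|") , ""),
    to = study$network$edges$to)
  sif$rel[!nzchar(sif$rel)] <- "pp"
  utils::write.table(sif, paths["interactions"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  gmt_lines <- vapply(names(study$gene_sets), function(term) {
    s <- study$gene_sets[[term]]
    paste(c(term, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(gmt_lines, paths["gmt"])
  jsonlite::write_json(study$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Bundled toy study
#'
#' A small fixed study (40 genes x 30 samples, two subgroups of 16 and
#' 14, three planted edges) shipped as plain-text files under
#' \code{inst/extdata} (filenames prefixed \code{synthetic_}) for
#' documentation examples and fast end-to-end checks. The files are the
#' deterministic output of [simulate_study()] at the configuration
#' returned by \code{fixture_config()}.
#'
#' @return list with \code{expr}, \code{annot}, \code{network},
#'   \code{gene_sets}, \code{truth}
#' @export
fixture_small <- function() {
  dir <- system.file("extdata", package = "deggnet")
  expr <- read_expression(file.path(dir, "synthetic_expression.tsv"))
  annot <- read_annotation(file.path(dir, "synthetic_annotation.csv"))
  network <- read_interactions(file.path(dir, "synthetic_interactions.sif"))
  gene_sets <- read_gmt(file.path(dir, "synthetic_gene_sets.gmt"))
  truth <- jsonlite::read_json(file.path(dir, "synthetic_truth.json"),
                               simplifyVector = TRUE)
  list(expr = expr, annot = annot, network = network,
       gene_sets = gene_sets, truth = truth)
}

#' Configuration that generated the bundled toy study
#' @return sim_config
#' @export
fixture_config <- function() {
  sim_config(n_genes = 40, group_sizes = c(A = 16, B = 14),
             n_planted_edges = 3,
             slope_per_group = c(A = 1.5, B = 0),
             noise_sd = 0.5, response_effect = 2,
             n_background_edges = 40, n_random_sets = 3,
             random_set_size = 8, seed = 101L)
}
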
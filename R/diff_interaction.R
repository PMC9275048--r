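# Differential gene-gene interaction testing: per-edge robust linear
# regression with a subgroup-by-gene interaction term.

# relevel a factor so the largest class is the reference
# (ties broken alphabetically)
relevel_largest <- function(f) {
  f <- droplevels(factor(f))
  sizes <- table(f)
  stats::relevel(f, ref = names(sizes)[which.max(sizes)])
}

# covariate columns as a model-ready data.frame: numerics kept,
# categoricals releveled so the most frequent level is the reference
prepare_covariates <- function(annot, covariates) {
  if (length(covariates) == 0) return(NULL)
  missing_cov <- setdiff(covariates, names(annot))
  if (length(missing_cov) > 0)
    stop_deggnet(sprintf("covariate(s) not in annotation: %s",
                         paste(missing_cov, collapse = ", ")),
                 "deggnet_validation")
  out <- annot[covariates]
  for (nm in covariates) {
    if (!is.numeric(out[[nm]])) out[[nm]] <- relevel_largest(out[[nm]])
  }
  out
}

#' Test one network edge for subgroup-differential interaction
#'
#' For an undirected gene pair the lexicographically later gene is
#' regressed on the earlier one (orientation recorded in the result):
#' \deqn{y = \beta_0 + \beta_1 x + \gamma_k + \delta_k x + covariates}
#' with treatment coding, the largest subgroup as reference, fitted by
#' Huber robust regression ([huber_fit()]). The differential-interaction
#' statistic is the joint Wald statistic on all subgroup-by-gene
#' interaction coefficients (\code{df = #groups - 1}); for two groups
#' this is the squared z of the single interaction coefficient. Its
#' p-value is taken from the F distribution with \code{(df, n - p)}
#' degrees of freedom, which is calibrated at realistic cohort sizes
#' where the asymptotic chi-square reference is anti-conservative.
#'
#' @param expr numeric gene x sample matrix
#' @param annot annotation data.frame (\code{sample_id}, \code{subgroup});
#'   every subgroup needs >= 3 samples
#' @param edge character vector of two gene symbols
#' @param covariates names of additive covariate columns in \code{annot}
#' @param orientation \code{"canonical"} (later-on-earlier, default) or
#'   \code{"symmetric"}: run both orientations and take the smaller p
#'   with a 2x Bonferroni factor
#' @param ... passed to [huber_fit()]
#' @return object of class \code{edge_test}: gene pair, orientation,
#'   per-group slopes, group sizes, Wald statistic, df, raw p
#' @export
test_edge <- function(expr, annot, edge, covariates = character(),
                      orientation = c("canonical", "symmetric"), ...) {
  orientation <- match.arg(orientation)
  validate_expr(expr)
  validate_annotation(annot)
  edge <- toupper(as.character(edge))
  stopifnot(length(edge) == 2)
  absent <- setdiff(edge, rownames(expr))
  if (length(absent) > 0)
    stop_deggnet(sprintf("gene(s) not measured: %s",
                         paste(absent, collapse = ", ")), "deggnet_lookup")
  gene_a <- min(edge); gene_b <- max(edge)
  if (orientation == "symmetric") {
    f1 <- test_edge(expr, annot, edge, covariates, "canonical", ...)
    # swap roles by renaming rows so the canonical rule picks the other gene
    expr2 <- expr
    rn <- rownames(expr2)
    rn[rn == gene_a] <- ".TMPA"; rownames(expr2) <- rn
    f2 <- test_edge(expr2, annot, c(".TMPA", gene_b), covariates,
                    "canonical", ...)
    best <- if (f1$p_raw <= f2$p_raw) f1 else f2
    best$gene_a <- gene_a; best$gene_b <- gene_b
    best$response_gene <- sub("^\\.TMPA$", gene_a, best$response_gene)
    best$predictor_gene <- sub("^\\.TMPA$", gene_a, best$predictor_gene)
    best$p_raw <- min(1, 2 * best$p_raw)  # Bonferroni over orientations
    best$orientation <- "symmetric"
    return(best)
  }
  response_gene <- gene_b; predictor_gene <- gene_a
  ids <- annot$sample_id
  group <- relevel_largest(annot$subgroup)
  sizes <- table(group)
  if (any(sizes < 3))
    stop_deggnet(sprintf("subgroup(s) with < 3 samples: %s",
                         paste(names(sizes)[sizes < 3], collapse = ", ")),
                 "deggnet_validation")
  d <- data.frame(.y = expr[response_gene, ids],
                  .x = expr[predictor_gene, ids],
                  .group = group)
  for (g in levels(group)) {
    in_g <- group == g
    if (stats::sd(d$.x[in_g]) == 0 || stats::sd(d$.y[in_g]) == 0)
      stop_deggnet(sprintf("zero-variance expression for edge %s-%s within subgroup '%s'",
                           gene_a, gene_b, g), "deggnet_degenerate")
  }
  covs <- prepare_covariates(annot, covariates)
  if (!is.null(covs)) d <- cbind(d, covs)
  fml <- stats::reformulate(c(".x * .group", covariates), response = ".y")
  X <- stats::model.matrix(fml, d)
  fit <- huber_fit(d$.y, X, ...)
  int_idx <- grep("^\\.x:\\.group", colnames(X))
  b_int <- fit$coefficients[int_idx]
  V_int <- fit$vcov[int_idx, int_idx, drop = FALSE]
  wald <- drop(t(b_int) %*% solve(V_int) %*% b_int)
  df <- length(int_idx)
  # F reference (denominator df = residual df) rather than the
  # asymptotic chi-square: at cohort-sized n the chi-square reference
  # is visibly anti-conservative for the joint interaction test
  p_raw <- stats::pf(wald / df, df1 = df, df2 = fit$df.residual,
                     lower.tail = FALSE)
  ref_slope <- fit$coefficients[".x"]
  slopes <- c(ref_slope, ref_slope + b_int)
  names(slopes) <- c(levels(group)[1],
                     sub("^\\.x:\\.group", "", colnames(X)[int_idx]))
  slopes <- slopes[sort(names(slopes))]
  structure(list(
    gene_a = gene_a, gene_b = gene_b,
    response_gene = response_gene, predictor_gene = predictor_gene,
    orientation = "canonical",
    per_group_slope = slopes,
    n_per_group = setNames(as.integer(sizes), names(sizes))[sort(names(sizes))],
    interaction_stat = wald, df = df, p_raw = p_raw,
    fit = fit
  ), class = "edge_test")
}

#' @export
print.edge_test <- function(x, ...) {
  cat(sprintf("edge_test %s ~ %s (%s): Wald = %.3f, df = %d, p = %.4g\n",
              x$response_gene, x$predictor_gene, x$orientation,
              x$interaction_stat, x$df, x$p_raw))
  cat("  per-group slopes:\n")
  print(round(x$per_group_slope, 4))
  invisible(x)
}

#' Scan a network for differential interactions
#'
#' Runs [test_edge()] over every edge; edges failing preconditions
#' (unmeasured gene, zero within-group variance, rank deficiency) are
#' skipped with a logged reason, and Benjamini-Hochberg adjustment is
#' applied across the edges actually tested.
#'
#' @param network interaction_network or specific_network
#' @param expr numeric gene x sample matrix
#' @param annot annotation data.frame
#' @param covariates additive covariate column names
#' @param ... passed to [test_edge()]
#' @return data.frame (one row per tested edge) with columns gene_a,
#'   gene_b, response_gene, n_<group>..., slope_<group>..., wald, df,
#'   p_raw, p_adj; skipped edges in attribute \code{skipped}
#' @export
scan_network <- function(network, expr, annot, covariates = character(),
                         ...) {
  stopifnot(inherits(network, "interaction_network"))
  results <- list()
  skipped <- list()
  for (i in seq_len(n_edges(network))) {
    e <- c(network$edges$from[i], network$edges$to[i])
    res <- tryCatch(test_edge(expr, annot, e, covariates, ...),
                    deggnet_error = function(cond) cond)
    if (inherits(res, "edge_test")) {
      results[[length(results) + 1L]] <- res
    } else {
      deggnet_log("skipping edge %s-%s: %s", e[1], e[2],
                  conditionMessage(res))
      skipped[[length(skipped) + 1L]] <-
        data.frame(gene_a = min(e), gene_b = max(e),
                   reason = conditionMessage(res))
    }
  }
  if (length(results) == 0) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      response_gene = character(), wald = numeric(),
                      df = integer(), p_raw = numeric(), p_adj = numeric())
  } else {
    groups <- sort(names(results[[1]]$n_per_group))
    out <- do.call(rbind, lapply(results, function(r) {
      row <- data.frame(gene_a = r$gene_a, gene_b = r$gene_b,
                        response_gene = r$response_gene,
                        stringsAsFactors = FALSE)
      for (g in groups) row[[paste0("n_", g)]] <- r$n_per_group[[g]]
      for (g in groups) row[[paste0("slope_", g)]] <- r$per_group_slope[[g]]
      row$wald <- r$interaction_stat
      row$df <- r$df
      row$p_raw <- r$p_raw
      row
    }))
    out$p_adj <- adjust_bh(out$p_raw)
    out <- out[order(out$p_raw), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
    else data.frame(gene_a = character(), gene_b = character(),
                    reason = character())
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' order-preserving with respect to the input indexing (a thin, validated
#' wrapper over \code{p.adjust(method = "BH")}).
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted p-values, same order as the input
#' @export
adjust_bh <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1))
    stop_deggnet("p-values must lie in [0, 1]", "deggnet_argument")
  stats::p.adjust(p, method = "BH")
}
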
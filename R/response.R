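# Ratio-based logistic response models and ROC/AUC evaluation.

#' Restrict an annotation to Good vs None responders
#'
#' Moderate responders and samples without a response label are removed;
#' the binary outcome is Good = 1, None = 0 (column \code{outcome}).
#'
#' @param annot annotation data.frame with a \code{response} column
#' @return filtered annotation with an added integer \code{outcome}
#'   column; errors if either class has fewer than 3 samples
#' @export
select_response_samples <- function(annot) {
  validate_annotation(annot, require_subgroup = FALSE)
  if (!"response" %in% names(annot))
    stop_deggnet("annotation lacks a 'response' column", "deggnet_validation")
  keep <- annot$response %in% c("Good", "None")
  out <- annot[keep, , drop = FALSE]
  out$outcome <- as.integer(out$response == "Good")
  n_good <- sum(out$outcome == 1); n_none <- sum(out$outcome == 0)
  if (n_good < 3 || n_none < 3)
    stop_deggnet(sprintf(
      "need >= 3 samples per response class after exclusions (Good: %d, None: %d)",
      n_good, n_none), "deggnet_validation")
  out$response <- droplevels(out$response)
  rownames(out) <- NULL
  out
}

# logistic regression by Newton / iteratively reweighted least squares
logistic_irls <- function(y, X, tol = 1e-8, max_iter = 100L) {
  n <- length(y); p <- ncol(X)
  const_col <- apply(X[, -1, drop = FALSE], 2, function(col)
    stats::sd(col) == 0)
  if (any(const_col))
    stop_deggnet(sprintf("constant (rank-deficient) column(s): %s",
                         paste(colnames(X)[-1][const_col], collapse = ", ")),
                 "deggnet_rank")
  qrX <- qr(X)
  if (qrX$rank < p)
    stop_deggnet(sprintf("design is rank deficient; collinear column(s): %s",
                         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):p]],
                               collapse = ", ")), "deggnet_rank")
  beta <- rep(0, p)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    beta_new <- qr.coef(qr(X * sw), z * sw)
    rel <- max(abs(beta_new - beta) / pmax(abs(beta_new), 1e-10))
    beta <- beta_new
    if (rel < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(info), error = function(e) {
    diag(Inf, p)
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))
  loglik <- sum(y * log(pmax(mu, 1e-300)) +
                (1 - y) * log(pmax(1 - mu, 1e-300)))
  list(coefficients = setNames(as.numeric(beta), colnames(X)),
       se = sqrt(diag(vcov)), vcov = vcov,
       fitted = mu, linear_predictors = eta,
       loglik = loglik, gradient = drop(crossprod(X, y - mu)),
       iterations = iter, converged = converged)
}

#' Ratio-based logistic response model for a gene pair
#'
#' Fits \code{outcome ~ gene_1 + gene_2 + interaction + covariates} by
#' iteratively reweighted maximum likelihood. The gene-ratio interaction
#' term is, by default, the centered product of the two log-scale
#' expressions (a literal log-ratio is exactly collinear with the two
#' additive terms); \code{term = "ratio"} instead uses the raw-scale
#' ratio \code{2^g1 / 2^g2}. In-sample AUC is reported for the model
#' with and without the interaction term.
#'
#' Suspected perfect separation (any coefficient exceeding 50 on
#' standardized inputs, or non-convergence) yields a flagged result with
#' \code{interaction_p = NA}; the AUCs are still reported.
#'
#' @param expr numeric gene x sample matrix (log scale)
#' @param annot_binary annotation with an \code{outcome} column (see
#'   [select_response_samples()]); an annotation still carrying
#'   Good/Moderate/None labels is reduced internally
#' @param gene_1,gene_2 gene symbols
#' @param covariates additive covariate column names in the annotation
#' @param term \code{"product"} (default) or \code{"ratio"}
#' @return object of class \code{ratio_glm}: coefficients, standard
#'   errors, \code{interaction_p}, \code{auc_with}, \code{auc_without},
#'   class counts, log-likelihoods, separation flag
#' @export
fit_ratio_logistic <- function(expr, annot_binary, gene_1, gene_2,
                               covariates = character(),
                               term = c("product", "ratio")) {
  term <- match.arg(term)
  validate_expr(expr)
  if (!"outcome" %in% names(annot_binary))
    annot_binary <- select_response_samples(annot_binary)
  gene_1 <- toupper(gene_1); gene_2 <- toupper(gene_2)
  absent <- setdiff(c(gene_1, gene_2), rownames(expr))
  if (length(absent) > 0)
    stop_deggnet(sprintf("gene(s) not measured: %s",
                         paste(absent, collapse = ", ")), "deggnet_lookup")
  y <- annot_binary$outcome
  if (length(unique(y)) < 2)
    stop_deggnet("both response classes must be present", "deggnet_validation")
  ids <- annot_binary$sample_id
  x1 <- expr[gene_1, ids]; x2 <- expr[gene_2, ids]
  inter <- if (term == "product") {
    (x1 - mean(x1)) * (x2 - mean(x2))
  } else {
    2^x1 / 2^x2
  }
  inter_name <- if (term == "product") paste0(gene_1, ":", gene_2)
                else paste0("ratio_", gene_1, "_", gene_2)
  d <- data.frame(x1 = x1, x2 = x2, inter = inter)
  covs <- prepare_covariates(annot_binary, covariates)
  if (!is.null(covs)) d <- cbind(d, covs)
  fml <- stats::reformulate(c("x1", "x2", "inter", covariates))
  X <- stats::model.matrix(fml, d)
  colnames(X)[colnames(X) == "x1"] <- gene_1
  colnames(X)[colnames(X) == "x2"] <- gene_2
  colnames(X)[colnames(X) == "inter"] <- inter_name
  full <- logistic_irls(y, X)
  reduced <- logistic_irls(y, X[, colnames(X) != inter_name, drop = FALSE])
  # separation check on standardized inputs
  sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  beta_std <- full$coefficients[-1] * sds
  separation <- !full$converged || any(abs(beta_std) > 50) ||
    any(!is.finite(full$se))
  z <- full$coefficients[inter_name] / full$se[inter_name]
  interaction_p <- if (separation) NA_real_ else 2 * stats::pnorm(-abs(z))
  structure(list(
    gene_1 = gene_1, gene_2 = gene_2, term = term,
    coefficients = full$coefficients,
    standard_errors = full$se,
    vcov = full$vcov,
    interaction_term = inter_name,
    interaction_p = interaction_p,
    auc_with = roc_auc(full$fitted, y)$auc,
    auc_without = roc_auc(reduced$fitted, y)$auc,
    loglik_with = full$loglik,
    loglik_without = reduced$loglik,
    gradient = full$gradient,
    fitted = full$fitted,
    n_good = sum(y == 1), n_none = sum(y == 0),
    separation = separation,
    iterations = full$iterations,
    model = list(y = y, X = X)
  ), class = "ratio_glm")
}

#' @export
print.ratio_glm <- function(x, ...) {
  cat(sprintf("ratio_glm %s / %s (%s interaction term)%s\n",
              x$gene_1, x$gene_2, x$term,
              if (x$separation) " [separation flagged]" else ""))
  cat(sprintf("  interaction p = %.4g | AUC with = %.3f, without = %.3f | n = %d Good / %d None\n",
              x$interaction_p, x$auc_with, x$auc_without,
              x$n_good, x$n_none))
  invisible(x)
}

#' @export
coef.ratio_glm <- function(object, ...) object$coefficients

#' @export
summary.ratio_glm <- function(object, ...) {
  z <- object$coefficients / object$standard_errors
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$standard_errors,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(pair = c(object$gene_1, object$gene_2),
              coefficients = tab,
              interaction_p = object$interaction_p,
              auc_with = object$auc_with, auc_without = object$auc_without,
              n_good = object$n_good, n_none = object$n_none,
              separation = object$separation)
  class(out) <- "summary.ratio_glm"
  out
}

#' @export
print.summary.ratio_glm <- function(x, ...) {
  cat(sprintf("Logistic response model for pair %s / %s\n",
              x$pair[1], x$pair[2]))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("AUC with interaction term: %.3f; without: %.3f (n = %d Good, %d None)\n",
              x$auc_with, x$auc_without, x$n_good, x$n_none))
  if (x$separation) cat("warning: perfect separation suspected\n")
  invisible(x)
}

#' @export
predict.ratio_glm <- function(object, ...) object$fitted

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formula with ties counted one half;
#' the curve is a threshold sweep over the unique scores, for which the
#' trapezoidal integral equals the rank AUC exactly.
#'
#' @param scores numeric prediction scores (higher = more positive)
#' @param labels binary labels (0/1 or logical); both classes required
#' @return object of class \code{roc_curve}: decreasing
#'   \code{thresholds}, \code{tpr}, \code{fpr} (each starting at 0 and
#'   ending at 1) and \code{auc}
#' @examples
#' roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc  # 1
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.integer(as.logical(as.numeric(labels)))
  if (length(scores) != length(labels))
    stop_deggnet("scores and labels must have equal length")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_deggnet("both classes must be present", "deggnet_validation")
  r <- rank(scores)  # average ranks handle ties as 1/2
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  pos_at <- vapply(thr, function(t) sum(labels == 1 & scores == t), 0)
  neg_at <- vapply(thr, function(t) sum(labels == 0 & scores == t), 0)
  tpr <- c(0, cumsum(pos_at) / n1)
  fpr <- c(0, cumsum(neg_at) / n0)
  structure(list(thresholds = c(Inf, thr), tpr = tpr, fpr = fpr,
                 auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.4f (%d operating points)\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Fit ratio-logistic models for all significant edges
#'
#' Edges with raw interaction p below \code{alpha} in the
#' responder/non-responder differential scan are passed to
#' [fit_ratio_logistic()]; results are sorted by \code{auc_with}
#' descending. Pairs that fail to fit are skipped with a logged reason.
#'
#' @param edge_results data.frame from [scan_network()]
#' @param expr numeric gene x sample matrix
#' @param annot annotation (reduced internally to Good vs None)
#' @param covariates additive covariate column names
#' @param alpha raw-p significance cutoff (default 0.05)
#' @param term interaction-term mode, see [fit_ratio_logistic()]
#' @return data.frame with one row per fitted pair (gene_1, gene_2,
#'   interaction_p, auc_with, auc_without, n_good, n_none,
#'   separation_flag), sorted by auc_with; fitted models in attribute
#'   \code{models}
#' @export
evaluate_pairs <- function(edge_results, expr, annot,
                           covariates = character(), alpha = 0.05,
                           term = c("product", "ratio")) {
  term <- match.arg(term)
  stopifnot(is.data.frame(edge_results))
  empty <- data.frame(gene_1 = character(), gene_2 = character(),
                      interaction_p = numeric(), auc_with = numeric(),
                      auc_without = numeric(), n_good = integer(),
                      n_none = integer(), separation_flag = logical())
  sig <- edge_results[!is.na(edge_results$p_raw) &
                      edge_results$p_raw < alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    attr(empty, "models") <- list()
    return(empty)
  }
  if (!"outcome" %in% names(annot)) annot <- select_response_samples(annot)
  models <- list()
  rows <- list()
  for (i in seq_len(nrow(sig))) {
    g1 <- sig$gene_a[i]; g2 <- sig$gene_b[i]
    m <- tryCatch(
      fit_ratio_logistic(expr, annot, g1, g2, covariates, term),
      deggnet_error = function(cond) cond)
    if (!inherits(m, "ratio_glm")) {
      deggnet_log("skipping pair %s-%s: %s", g1, g2, conditionMessage(m))
      next
    }
    models[[length(models) + 1L]] <- m
    rows[[length(rows) + 1L]] <- data.frame(
      gene_1 = m$gene_1, gene_2 = m$gene_2,
      interaction_p = m$interaction_p,
      auc_with = m$auc_with, auc_without = m$auc_without,
      n_good = m$n_good, n_none = m$n_none,
      separation_flag = m$separation, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    attr(empty, "models") <- list()
    return(empty)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$auc_with)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "models") <- models[ord]
  out
}
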
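#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef complete.cases mad median model.matrix pchisq
#'   pnorm qnorm quantile rbinom rnorm runif sd setNames p.adjust phyper
#'   plogis
#' @importFrom utils read.delim write.table head combn packageVersion
NULL

# condition helpers: classed errors so callers (scan_network, pipelines)
# can distinguish skippable per-edge problems from fatal ones
stop_deggnet <- function(msg, class = "deggnet_error", ...) {
  stop(structure(
    class = c(class, "deggnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

deggnet_log <- function(fmt, ...) {
  message(sprintf(paste0("[deggnet] ", fmt), ...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round to one decimal, half to even
#'
#' Percentage statistic used in cluster enrichment tables:
#' \code{100 * n_in_term / cluster_size} rounded to one decimal place with
#' ties rounded half to even (the convention of base \code{round}).
#'
#' @param n_in_term number of cluster genes inside the gene-set term
#' @param cluster_size number of genes in the cluster
#' @return numeric percentage in \[0, 100\], one decimal
#' @examples
#' enrichment_percentage(29, 31) # 93.5
#' enrichment_percentage(13, 16) # 81.2 (81.25 rounds half to even)
#' @export
enrichment_percentage <- function(n_in_term, cluster_size) {
  stopifnot(all(cluster_size > 0), all(n_in_term >= 0),
            all(n_in_term <= cluster_size))
  round(100 * n_in_term / cluster_size, 1)
}

# percentile with linear interpolation between order statistics
# (quantile type 7); the convention is fixed because it changes node sets
weight_percentile <- function(w, p) {
  stats::quantile(w, probs = p / 100, type = 7, names = FALSE)
}

validate_expr <- function(expr, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop_deggnet(sprintf("%s must be a numeric matrix (genes x samples)", arg))
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop_deggnet(sprintf("%s must have gene rownames and sample colnames", arg))
  if (anyDuplicated(rownames(expr)))
    stop_deggnet(sprintf("%s has duplicated gene ids", arg))
  if (anyDuplicated(colnames(expr)))
    stop_deggnet(sprintf("%s has duplicated sample ids", arg))
  if (!all(is.finite(expr)))
    stop_deggnet(sprintf("%s contains non-finite values", arg))
  invisible(expr)
}

validate_annotation <- function(annot, require_subgroup = TRUE) {
  if (!is.data.frame(annot))
    stop_deggnet("annotation must be a data.frame")
  if (!"sample_id" %in% names(annot))
    stop_deggnet("annotation lacks a 'sample_id' column", "deggnet_validation")
  if (anyDuplicated(annot$sample_id))
    stop_deggnet("duplicated sample_id in annotation", "deggnet_validation")
  if (require_subgroup && !"subgroup" %in% names(annot))
    stop_deggnet("annotation lacks a 'subgroup' column", "deggnet_validation")
  invisible(annot)
}

response_levels <- c("Good", "Moderate", "None")
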
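# Shared fixtures and independent oracles.

# tiny expression matrix builder
make_expr <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), ncol = length(samples),
         dimnames = list(genes, samples), byrow = TRUE)
}

make_annot <- function(samples, subgroup, response = NULL, ...) {
  df <- data.frame(sample_id = samples, subgroup = subgroup,
                   stringsAsFactors = FALSE, ...)
  if (!is.null(response))
    df$response <- factor(response, levels = c("Good", "Moderate", "None"))
  df
}

# two triangles (A-B-C, D-E-F) joined by the bridge edge C-D
two_triangles <- function() {
  interaction_network(data.frame(
    from = c("A", "A", "B", "D", "D", "E", "C"),
    to   = c("B", "C", "C", "E", "F", "F", "D")))
}

# oracle: ordinary least squares through the normal equations
ols_solve <- function(y, X) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# oracle: AUC by brute-force count over all positive-negative pairs
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# oracle: upper-tail hypergeometric by exhaustive enumeration of all
# draws of `n` from the universe (feasible for |universe| <= 15)
hyper_enum <- function(N, K, n, k_min) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # treat 1..K as the successes
  mean(hits >= k_min)
}

# oracle: Benjamini-Hochberg step-up computed literally
bh_hand <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# oracle: trapezoidal integral of an ROC curve
trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

# write lines to a temp file, return path
tmpfile_with <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
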
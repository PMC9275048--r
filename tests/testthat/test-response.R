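# simulate a binary-response study for a gene pair; the planted signal
# is the product interaction (an additive z1 - z2 signal would be fully
# absorbed by the two additive gene terms and cannot raise the AUC of
# the full model over the reduced one)
response_study <- function(n, effect = 0, seed = NULL, age_effect = 0) {
  if (!is.null(seed)) set.seed(seed)
  z1 <- rnorm(n); z2 <- rnorm(n)
  age <- rnorm(n, 52, 16)
  eta <- effect * z1 * z2 + age_effect * scale(age)[, 1]
  y <- rbinom(n, 1, plogis(eta))
  samples <- sprintf("s%03d", seq_len(n))
  expr <- rbind(P1 = 5 + z1, P2 = 6 + z2)
  colnames(expr) <- samples
  annot <- make_annot(samples, rep("g1", n),
                      response = ifelse(y == 1, "Good", "None"),
                      age = age)
  annot$outcome <- y
  list(expr = expr, annot = annot, y = y)
}

test_that("select_response_samples drops Moderate/missing and needs 3 per class", {
  annot <- make_annot(sprintf("s%d", 1:9), rep("g1", 9),
                      response = c("Good", "Moderate", "None", "Good",
                                   "Moderate", NA, "Good", "None", "None"))
  out <- select_response_samples(annot)
  expect_equal(nrow(out), 6L)
  expect_equal(out$outcome, c(1L, 0L, 1L, 1L, 0L, 0L))

  few <- make_annot(sprintf("s%d", 1:5), rep("g1", 5),
                    response = c("Good", "Moderate", "None", "Good",
                                 "Moderate"))
  expect_error(select_response_samples(few), ">= 3 samples per response")
  all_mod <- make_annot(sprintf("s%d", 1:4), rep("g1", 4),
                        response = rep("Moderate", 4))
  expect_error(select_response_samples(all_mod), ">= 3 samples per response")
})

test_that("roc_auc matches brute-force pair counting", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  # 7 of the 9 positive-negative pairs are correctly ordered
  expect_equal(roc_auc(c(3, 1, 2, 5, 4, 0), c(1, 0, 1, 1, 0, 0))$auc, 7 / 9)
  expect_equal(7 / 9, auc_brute(c(3, 1, 2, 5, 4, 0), c(1, 0, 1, 1, 0, 0)))
  set.seed(91)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, auc_brute(scores, labels))
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(90)
  for (rep in 1:5) {
    scores <- round(rnorm(40), 1)
    labels <- rbinom(40, 1, 0.5)
    ref <- suppressMessages(pROC::auc(labels, scores,
                                      direction = "<", quiet = TRUE))
    expect_equal(roc_auc(scores, labels)$auc, as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("the ROC curve is a valid staircase whose trapezoid equals rank AUC", {
  set.seed(92)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    scores <- round(rnorm(n), 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    roc <- roc_auc(scores, labels)
    expect_equal(c(roc$tpr[1], roc$fpr[1]), c(0, 0))
    expect_equal(c(roc$tpr[length(roc$tpr)], roc$fpr[length(roc$fpr)]),
                 c(1, 1))
    expect_true(all(diff(roc$tpr) >= 0) && all(diff(roc$fpr) >= 0))
    expect_equal(trapezoid_auc(roc), roc$auc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and flips with labels", {
  set.seed(93)
  scores <- rnorm(40)
  labels <- rbinom(40, 1, 0.5)
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(plogis(3 * scores - 1), labels)$auc, a)
  expect_equal(roc_auc(exp(scores), labels)$auc, a)
  expect_equal(roc_auc(scores, 1 - labels)$auc, 1 - a)
})

test_that("fit_ratio_logistic matches glm and reports a near-zero gradient", {
  st <- response_study(120, effect = 2, seed = 94, age_effect = 0.5)
  m <- fit_ratio_logistic(st$expr, st$annot, "P1", "P2",
                          covariates = "age")
  x1 <- st$expr["P1", ]; x2 <- st$expr["P2", ]
  inter <- (x1 - mean(x1)) * (x2 - mean(x2))
  ref <- glm(st$y ~ x1 + x2 + inter + st$annot$age, family = binomial())
  expect_equal(unname(coef(m)), unname(coef(ref)), tolerance = 1e-6)
  expect_lt(max(abs(m$gradient)), 1e-6)
  expect_equal(m$n_good, sum(st$y), tolerance = 0)
})

test_that("removing the interaction term never increases the log-likelihood", {
  set.seed(95)
  for (rep in 1:10) {
    st <- response_study(80, effect = runif(1, 0, 2))
    m <- fit_ratio_logistic(st$expr, st$annot, "P1", "P2")
    expect_lte(m$loglik_without, m$loglik_with + 1e-8)
  }
})

test_that("null outcomes give calibrated interaction p and chance-level AUC", {
  reps <- 80
  p_vals <- numeric(reps); aucs <- numeric(reps)
  for (i in seq_len(reps)) {
    st <- response_study(200, effect = 0, seed = 2000 + i)
    m <- fit_ratio_logistic(st$expr, st$annot, "P1", "P2")
    p_vals[i] <- m$interaction_p
    aucs[i] <- m$auc_with
  }
  expect_gte(mean(p_vals > 0.05, na.rm = TRUE), 0.9)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("a planted difference signal raises AUC over the reduced model", {
  gains <- vapply(1:60, function(i) {
    st <- response_study(150, effect = 2, seed = 3000 + i)
    m <- fit_ratio_logistic(st$expr, st$annot, "P1", "P2")
    m$auc_with - m$auc_without
  }, 0)
  expect_gte(mean(gains >= 0.05), 0.9)
})

test_that("degenerate and separable inputs are handled explicitly", {
  st <- response_study(40, seed = 96)
  st$expr["P1", ] <- 4
  expect_error(fit_ratio_logistic(st$expr, st$annot, "P1", "P2"),
               "rank|constant")

  # perfectly separable outcome: flagged, p missing, AUCs still reported
  st2 <- response_study(40, seed = 97)
  st2$annot$outcome <- as.integer(st2$expr["P1", ] > 5)
  m2 <- fit_ratio_logistic(st2$expr, st2$annot, "P1", "P2")
  expect_true(m2$separation)
  expect_true(is.na(m2$interaction_p))
  expect_equal(m2$auc_with, 1)
})

test_that("evaluate_pairs filters by alpha, sorts by AUC and recovers the signal", {
  empty <- data.frame(gene_a = "P1", gene_b = "P2", p_raw = 0.5)
  st <- response_study(60, effect = 2, seed = 98)
  out0 <- evaluate_pairs(empty, st$expr, st$annot)
  expect_equal(nrow(out0), 0L)

  set.seed(99)
  n <- 100
  samples <- sprintf("s%03d", 1:n)
  genes <- sprintf("N%02d", 1:8)
  expr <- matrix(rnorm(8 * n, 5), nrow = 8,
                 dimnames = list(genes, samples))
  z1 <- expr["N01", ] - 5; z2 <- expr["N02", ] - 5
  y <- rbinom(n, 1, plogis(3 * z1 * z2))
  annot <- make_annot(samples, rep("g1", n),
                      response = ifelse(y == 1, "Good", "None"))
  edges <- data.frame(gene_a = c("N01", "N03", "N05"),
                      gene_b = c("N02", "N04", "N06"),
                      p_raw = c(0.001, 0.01, 0.5))
  out <- evaluate_pairs(edges, expr, annot)
  expect_equal(nrow(out), 2L)  # the 0.5 edge is below alpha
  expect_true(all(diff(out$auc_with) <= 0))
  expect_equal(out$gene_1[1], "N01")
  expect_length(attr(out, "models"), 2L)
})
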
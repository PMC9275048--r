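# build a two-gene study with given per-group slopes
edge_study <- function(slopes, n_per_group, noise_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- names(slopes)
  subgroup <- rep(groups, times = n_per_group)
  n <- length(subgroup)
  x <- rnorm(n, mean = 5)
  y <- numeric(n)
  for (g in groups) {
    in_g <- subgroup == g
    y[in_g] <- 3 + slopes[[g]] * (x[in_g] - 5)
  }
  y <- y + rnorm(n, sd = noise_sd)
  samples <- sprintf("s%03d", seq_len(n))
  expr <- rbind(GA = x, GB = y)
  colnames(expr) <- samples
  annot <- make_annot(samples, subgroup, age = rnorm(n, 52, 16))
  list(expr = expr, annot = annot)
}

test_that("test_edge recovers per-group slopes and orientation", {
  st <- edge_study(c(g1 = 1, g2 = 0), c(g1 = 60, g2 = 40), 0.3, seed = 1)
  res <- test_edge(st$expr, st$annot, c("GB", "GA"))
  expect_equal(res$response_gene, "GB")   # lexicographically later
  expect_equal(res$predictor_gene, "GA")
  expect_equal(res$df, 1L)
  expect_equal(unname(res$per_group_slope["g1"]), 1, tolerance = 0.15)
  expect_equal(unname(res$per_group_slope["g2"]), 0, tolerance = 0.15)
  expect_lt(res$p_raw, 1e-6)
  expect_equal(res$n_per_group, c(g1 = 60L, g2 = 40L))
})

test_that("three equal-slope groups give df = 2 and compatible slopes", {
  st <- edge_study(c(g1 = 1, g2 = 1, g3 = 1), c(g1 = 49, g2 = 18, g3 = 16),
                   0.5, seed = 2)
  res <- test_edge(st$expr, st$annot, c("GA", "GB"))
  expect_equal(res$df, 2L)
  expect_gt(res$p_raw, 0.01)
  expect_lt(max(res$per_group_slope) - min(res$per_group_slope), 0.5)
})

test_that("interaction statistic is invariant to group label permutation", {
  st <- edge_study(c(g1 = 1.5, g2 = 0.5, g3 = 1), c(g1 = 30, g2 = 25, g3 = 20),
                   0.5, seed = 3)
  res1 <- test_edge(st$expr, st$annot, c("GA", "GB"))
  st2 <- st
  st2$annot$subgroup <- chartr("123", "312", st2$annot$subgroup)
  res2 <- test_edge(st2$expr, st2$annot, c("GA", "GB"))
  expect_equal(res2$interaction_stat, res1$interaction_stat,
               tolerance = 1e-6)
  expect_equal(res2$p_raw, res1$p_raw, tolerance = 1e-6)
  perm <- setNames(chartr("123", "312", names(res1$per_group_slope)),
                   names(res1$per_group_slope))
  expect_equal(unname(res2$per_group_slope[perm]),
               unname(res1$per_group_slope), tolerance = 1e-6)
})

test_that("translating the predictor leaves slopes and p unchanged", {
  st <- edge_study(c(g1 = 1, g2 = 0), c(g1 = 40, g2 = 40), 0.5, seed = 4)
  res1 <- test_edge(st$expr, st$annot, c("GA", "GB"))
  st$expr["GA", ] <- st$expr["GA", ] + 7
  res2 <- test_edge(st$expr, st$annot, c("GA", "GB"))
  expect_equal(res2$per_group_slope, res1$per_group_slope, tolerance = 1e-6)
  expect_equal(res2$p_raw, res1$p_raw, tolerance = 1e-6)
})

test_that("with downweighting disabled the fit matches closed-form OLS", {
  st <- edge_study(c(g1 = 1, g2 = 0.5), c(g1 = 12, g2 = 10), 0.4, seed = 5)
  res <- test_edge(st$expr, st$annot, c("GA", "GB"), k = Inf)
  grp <- relevel(factor(st$annot$subgroup), "g1")
  X <- model.matrix(~ x * g, data.frame(x = st$expr["GA", ], g = grp))
  b <- ols_solve(st$expr["GB", ], X)
  expect_equal(unname(res$per_group_slope["g1"]), unname(b[2]),
               tolerance = 1e-8)
  expect_equal(unname(res$per_group_slope["g2"]), unname(b[2] + b[4]),
               tolerance = 1e-8)
})

test_that("test_edge validates its preconditions", {
  st <- edge_study(c(g1 = 1, g2 = 0), c(g1 = 10, g2 = 10), 0.5, seed = 6)
  expect_error(test_edge(st$expr, st$annot, c("GA", "MISSING")),
               "not measured")
  st$annot$subgroup[st$annot$subgroup == "g2"] <- "g1"
  st$annot$subgroup[1:2] <- "g2"
  expect_error(test_edge(st$expr, st$annot, c("GA", "GB")), "< 3 samples")
  st2 <- edge_study(c(g1 = 1, g2 = 0), c(g1 = 10, g2 = 10), 0.5, seed = 7)
  st2$expr["GA", st2$annot$subgroup == "g1"] <- 4
  expect_error(test_edge(st2$expr, st2$annot, c("GA", "GB")),
               "zero-variance")
})

test_that("symmetric orientation applies a two-fold Bonferroni factor", {
  st <- edge_study(c(g1 = 1, g2 = 0), c(g1 = 40, g2 = 40), 0.5, seed = 8)
  can <- test_edge(st$expr, st$annot, c("GA", "GB"))
  sym <- test_edge(st$expr, st$annot, c("GA", "GB"),
                   orientation = "symmetric")
  expect_equal(sym$orientation, "symmetric")
  expect_lte(sym$p_raw, 1)
  expect_lte(sym$p_raw, 2 * can$p_raw + 1e-12)
})

test_that("interaction power at separated slopes is high and tracks OLS", {
  reps <- 100
  huber_hit <- logical(reps); ols_hit <- logical(reps)
  for (i in seq_len(reps)) {
    st <- edge_study(c(g1 = 0, g2 = 1), c(g1 = 50, g2 = 50), 1,
                     seed = 1000 + i)
    huber_hit[i] <- test_edge(st$expr, st$annot, c("GA", "GB"))$p_raw < 0.001
    # oracle: the identical test with downweighting disabled (pure OLS)
    ols_hit[i] <- test_edge(st$expr, st$annot, c("GA", "GB"),
                            k = Inf)$p_raw < 0.001
  }
  expect_gte(mean(huber_hit), 0.9)
  # on clean Gaussian data the robust test concedes little power to OLS
  expect_lt(abs(mean(huber_hit) - mean(ols_hit)), 0.07)
})

test_that("scan_network adjusts across tested edges and skips bad ones", {
  set.seed(71)
  genes <- c("GA", "GB", "GC", "GD", "GE")
  n <- 40
  expr <- matrix(rnorm(length(genes) * n, 5), nrow = length(genes),
                 dimnames = list(genes, sprintf("s%02d", 1:n)))
  annot <- make_annot(colnames(expr), rep(c("g1", "g2"), each = n / 2))
  net <- interaction_network(data.frame(
    from = c("GA", "GB", "GC", "GD"), to = c("GB", "GC", "GD", "GZ")))
  res <- suppressMessages(scan_network(net, expr, annot))
  expect_equal(nrow(res), 3L)              # GZ edge skipped
  expect_equal(nrow(attr(res, "skipped")), 1L)
  expect_equal(res$p_adj, adjust_bh(res$p_raw))
  expect_true(all(res$p_adj >= res$p_raw))
})

test_that("BH adjustment matches the literal step-up computation", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  set.seed(81)
  for (rep in 1:10) {
    p <- runif(sample(1:20, 1))
    expect_equal(adjust_bh(p), bh_hand(p), tolerance = 1e-12)
  }
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})
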
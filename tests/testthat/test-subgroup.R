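test_that("compute_weights averages expression per subgroup", {
  expr <- make_expr(c(1, 3, 2, 4,
                      5, 5, 8, 8), c("A", "B"),
                    c("s1", "s2", "s3", "s4"))
  annot <- make_annot(colnames(expr), c("g1", "g1", "g2", "g2"))
  net <- interaction_network(data.frame(from = "A", to = "B"))
  w <- suppressMessages(compute_weights(expr, annot, net))
  expect_named(w, c("g1", "g2"))
  expect_equal(w$g1$weight, c(A = 2, B = 5))
  expect_equal(w$g2$weight, c(A = 3, B = 8))

  # identical expression across subgroups gives identical weight maps
  expr2 <- make_expr(c(1, 2, 1, 2, 5, 6, 5, 6), c("A", "B"),
                     c("s1", "s2", "s3", "s4"))
  w2 <- suppressMessages(compute_weights(expr2, annot, net))
  expect_equal(w2$g1$weight, w2$g2$weight)

  # every subgroup needs at least two samples
  annot_bad <- make_annot(colnames(expr), c("g1", "g1", "g1", "g2"))
  expect_error(suppressMessages(compute_weights(expr, annot_bad, net)),
               "< 2 samples")
})

test_that("percolation_scan matches hand enumeration on the two-triangle toy", {
  net <- two_triangles()
  expr <- make_expr(rep(c(6, 5, 1, 2, 4, 3), each = 2),
                    c("A", "B", "C", "D", "E", "F"), c("s1", "s2"))
  annot <- make_annot(c("s1", "s2"), c("g1", "g1"))
  wnet <- suppressMessages(compute_weights(expr, annot, net))$g1
  prof <- percolation_scan(wnet, percentile_grid = c(0, 50, 75))$profile

  # p = 0: threshold 1, all six nodes, one component through the bridge
  expect_equal(prof$nodes_retained, c(6L, 3L, 2L))
  expect_equal(prof$threshold, c(1, 3.5, 4.75))
  # p = 50 keeps A(6), B(5), E(4): A-B edge survives, E is isolated
  expect_equal(prof$gcc_size, c(6L, 2L, 2L))
  expect_equal(prof$gcc_fraction, c(1, 2 / 3, 1))
  expect_equal(prof$second_component_size, c(0L, 1L, 0L))
})

test_that("percolation profile is monotone in retained nodes and valid", {
  set.seed(5)
  for (rep in 1:15) {
    genes <- sprintf("G%02d", 1:12)
    edges <- t(combn(genes, 2))
    pick <- sample(nrow(edges), 18)
    net <- interaction_network(data.frame(from = edges[pick, 1],
                                          to = edges[pick, 2]))
    expr <- make_expr(rep(runif(12, 2, 10), each = 3), genes,
                      c("s1", "s2", "s3"))
    annot <- make_annot(colnames(expr), rep("g1", 3))
    wnet <- suppressMessages(compute_weights(expr, annot, net))$g1
    prof <- percolation_scan(wnet)$profile
    expect_true(all(diff(prof$nodes_retained) <= 0))
    expect_true(all(prof$gcc_fraction >= 0 & prof$gcc_fraction <= 1))
    expect_true(all(prof$nodes_retained >= 1))
  }
})

test_that("percolation selection rules behave as documented", {
  net <- two_triangles()
  expr <- make_expr(rep(c(6, 5, 1, 2, 4, 3), each = 2),
                    c("A", "B", "C", "D", "E", "F"), c("s1", "s2"))
  annot <- make_annot(c("s1", "s2"), c("g1", "g1"))
  wnet <- suppressMessages(compute_weights(expr, annot, net))$g1
  pp <- percolation_scan(wnet, percentile_grid = c(0, 50, 75))
  # gcc-fraction rule: largest percentile with gcc_fraction >= 0.5
  expect_equal(pp$selected_percentile, 75)
  # transition diagnostic: argmax of the second component size
  expect_equal(pp$transition_percentile, 50)
  expect_error(percolation_scan(wnet, percentile_grid = c(10, 5)),
               "increasing")
})

test_that("filter_by_weight keeps ties and applies the interpolated percentile", {
  genes <- c("W1", "W2", "W3", "W4")
  net <- interaction_network(data.frame(
    from = c("W1", "W2", "W3"), to = c("W2", "W3", "W4")))

  # equal weights: no node is strictly below the threshold
  expr_eq <- make_expr(rep(2, 8), genes, c("s1", "s2"))
  annot <- make_annot(c("s1", "s2"), c("g1", "g1"))
  w_eq <- suppressMessages(compute_weights(expr_eq, annot, net))$g1
  f_eq <- filter_by_weight(w_eq, 75)
  expect_equal(attr(f_eq, "kept_genes"), genes)
  expect_equal(nrow(f_eq$edges), 3L)

  # weights 1..4 at percentile 75: interpolated threshold 3.25
  expr14 <- make_expr(rep(1:4, each = 2), genes, c("s1", "s2"))
  w14 <- suppressMessages(compute_weights(expr14, annot, net))$g1
  f14 <- filter_by_weight(w14, 75)
  expect_equal(attr(f14, "threshold"), 3.25)
  expect_equal(attr(f14, "kept_genes"), "W4")
  expect_equal(nrow(f14$edges), 0L)

  # percentile 0 returns the original network minus isolates
  net_iso <- interaction_network(data.frame(from = "W1", to = "W2"),
                                 nodes = genes)
  w_iso <- suppressMessages(compute_weights(expr14, annot, net_iso))$g1
  f0 <- filter_by_weight(w_iso, 0)
  expect_equal(f0$nodes, c("W1", "W2"))
})

test_that("extract_specific assigns only subgroup-unique edges", {
  e1 <- interaction_network(data.frame(from = c("A", "B"), to = c("B", "C")))
  e2 <- interaction_network(data.frame(from = c("B", "C"), to = c("C", "D")))
  e3 <- interaction_network(data.frame(from = "C", to = "D"))
  sp <- extract_specific(list(A = e1, B = e2, C = e3))
  expect_equal(sp$A$edges, data.frame(from = "A", to = "B"))
  expect_equal(nrow(sp$B$edges), 0L)
  expect_equal(nrow(sp$C$edges), 0L)
  expect_equal(attr(sp, "discarded"),
               data.frame(from = c("B", "C"), to = c("C", "D")))

  # identical networks leave nothing specific
  sp_same <- extract_specific(list(A = e1, B = e1, C = e1))
  expect_true(all(vapply(sp_same, function(s) nrow(s$edges), 0L) == 0L))

  # pairwise-disjoint networks pass through unchanged
  d1 <- interaction_network(data.frame(from = "A", to = "B"))
  d2 <- interaction_network(data.frame(from = "C", to = "D"))
  sp_dis <- extract_specific(list(A = d1, B = d2))
  expect_equal(sp_dis$A$edges, d1$edges)
  expect_equal(sp_dis$B$edges, d2$edges)

  expect_error(extract_specific(list(A = e1)), ">= 2")
})

test_that("specific edge sets are disjoint and conserve the filtered union", {
  set.seed(9)
  for (rep in 1:15) {
    genes <- sprintf("G%02d", 1:10)
    pairs <- t(combn(genes, 2))
    nets <- lapply(1:3, function(i) {
      pick <- sample(nrow(pairs), sample(5:15, 1))
      interaction_network(data.frame(from = pairs[pick, 1],
                                     to = pairs[pick, 2]))
    })
    names(nets) <- c("g1", "g2", "g3")
    sp <- extract_specific(nets)
    keys <- lapply(sp, deggnet:::edge_keys)
    expect_false(anyDuplicated(unlist(keys)) > 0)
    discarded <- attr(sp, "discarded")
    disc_keys <- paste(discarded$from, discarded$to, sep = "\r")
    all_keys <- unique(unlist(lapply(nets, deggnet:::edge_keys)))
    expect_setequal(c(unlist(keys), disc_keys), all_keys)
  }
})
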
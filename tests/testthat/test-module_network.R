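test_that("inter-module edge counting matches direct definitions", {
  e1 <- clique_edges(paste0("a", 1:5))
  e2 <- clique_edges(paste0("b", 1:5))
  bridges <- data.frame(from = paste0("a", 1:3), to = paste0("b", 1:3))
  g <- graph_from_edges(c(e1$from, e2$from, bridges$from),
                        c(e1$to, e2$to, bridges$to))
  A <- paste0("a", 1:5)
  B <- paste0("b", 1:5)
  expect_equal(inter_edge_count(g, A, B), 3)
  # A == B counts the edges internal to A, each once
  expect_equal(inter_edge_count(g, A, A), 10)
})

test_that("inter-module edge counting matches a double-loop oracle", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 30
    edf <- data.frame(from = sprintf("n%02d", sample(n, 60, TRUE)),
                      to = sprintf("n%02d", sample(n, 60, TRUE)),
                      stringsAsFactors = FALSE)
    edf <- edf[edf$from != edf$to, ]
    key <- paste(pmin(edf$from, edf$to), pmax(edf$from, edf$to))
    edf <- edf[!duplicated(key), ]
    g <- graph_from_edges(edf$from, edf$to)
    A <- sample(sprintf("n%02d", 1:n), 8)
    B <- sample(setdiff(sprintf("n%02d", 1:n), A), 8)
    expect_equal(inter_edge_count(g, A, B), bf_inter_count(edf, A, B))
  }
})

test_that("complete-graph symmetry and zero observations give p = 1", {
  vs <- sprintf("v%02d", 1:20)
  cl <- clique_edges(vs)
  k20 <- graph_from_edges(cl$from, cl$to)
  ct <- crosstalk_pvalue(k20, vs[1:5], vs[6:10], n_perm = 50, seed = 1)
  expect_equal(ct$p_value, 1)

  # two 5-cliques with no connection: observed 0, null always >= 0
  e1 <- clique_edges(paste0("a", 1:5))
  e2 <- clique_edges(paste0("b", 1:5))
  g <- graph_from_edges(c(e1$from, e2$from), c(e1$to, e2$to))
  ct0 <- crosstalk_pvalue(g, paste0("a", 1:5), paste0("b", 1:5),
                          n_perm = 50, seed = 1)
  expect_equal(ct0$observed, 0)
  expect_equal(ct0$p_value, 1)
})

test_that("the cross-talk p-value is symmetric and monotone", {
  sim <- simulate_ppi(n_modules = 4, module_size = 6,
                      n_crosstalk_pairs = 1, crosstalk_edge_prob = 0.3,
                      n_background_genes = 120,
                      background_edge_prob = 0.01, seed = 4)
  g <- sim$graph
  A <- sim$truth$modules$M01
  B <- c(sim$truth$modules$M02, sim$truth$modules$M03[1:3])  # unequal sizes
  pab <- crosstalk_pvalue(g, A, B, n_perm = 300, seed = 99)
  pba <- crosstalk_pvalue(g, B, A, n_perm = 300, seed = 99)
  expect_equal(pab$p_value, pba$p_value)
  expect_equal(pab$observed, pba$observed)

  # adding inter-module edges (same node universe, same seed) never
  # increases the p-value
  g2 <- igraph::add_edges(g, c("g0001", "g0009", "g0002", "g0010"))
  p_before <- crosstalk_pvalue(g, sim$truth$modules$M01,
                               sim$truth$modules$M02,
                               n_perm = 300, seed = 7)
  p_after <- crosstalk_pvalue(g2, sim$truth$modules$M01,
                              sim$truth$modules$M02,
                              n_perm = 300, seed = 7)
  expect_gte(p_after$observed, p_before$observed)
  expect_lte(p_after$p_value, p_before$p_value)
})

test_that("Monte-Carlo p agrees with exact enumeration on a 7-node universe", {
  # universe of 7 nodes, |A| = |B| = 2: the null has only
  # C(7,2) * C(5,2) = 210 equally likely disjoint set pairs
  edf <- data.frame(from = c("n1", "n2", "n3", "n5", "n1"),
                    to   = c("n2", "n3", "n4", "n6", "n4"),
                    stringsAsFactors = FALSE)
  g <- graph_from_edges(edf$from, edf$to)
  g <- igraph::add_vertices(g, 1, name = "n7")
  vs <- sprintf("n%d", 1:7)
  A <- c("n1", "n2")
  B <- c("n3", "n4")
  obs <- inter_edge_count(g, A, B)
  # exact tail probability by full enumeration
  tail_cnt <- 0L; tot <- 0L
  for (ia in utils::combn(7, 2, simplify = FALSE)) {
    rest <- setdiff(1:7, ia)
    for (ib in utils::combn(rest, 2, simplify = FALSE)) {
      tot <- tot + 1L
      if (bf_inter_count(edf, vs[ia], vs[ib]) >= obs)
        tail_cnt <- tail_cnt + 1L
    }
  }
  exact <- tail_cnt / tot
  ct <- crosstalk_pvalue(g, A, B, n_perm = 4000, seed = 12)
  se <- sqrt(exact * (1 - exact) / 4000)
  expect_lt(abs(ct$p_value - exact), 3 * se + 1 / 4001)
})

test_that("planted bipartite cross-talk is detected, random pairs are not", {
  sim <- simulate_ppi(n_modules = 6, module_size = 6,
                      n_crosstalk_pairs = 1, crosstalk_edge_prob = 1,
                      n_background_genes = 500,
                      background_edge_prob = 0.005, seed = 31)
  net <- build_module_network(sim$graph, sim$truth$modules,
                              alpha = 0.01, n_perm = 1000, seed = 31)
  expect_setequal(net$modules, names(sim$truth$modules))
  got <- paste(net$edges$module_a, net$edges$module_b)
  expect_true(paste("M01", "M02") %in% got)
  expect_true(all(net$edges$p_value < 0.01))
  expect_true(all(net$pairs$p_value > 0 & net$pairs$p_value <= 1))
})

test_that("module networks over structureless graphs have no edges", {
  # complete graph: every permuted count equals the observed count
  vs <- sprintf("v%02d", 1:20)
  cl <- clique_edges(vs)
  k20 <- graph_from_edges(cl$from, cl$to)
  mods <- list(A = vs[1:5], B = vs[6:10], C = vs[11:15])
  net <- build_module_network(k20, mods, n_perm = 100, seed = 2)
  expect_equal(nrow(net$edges), 0)
  expect_setequal(net$modules, c("A", "B", "C"))
})

test_that("per-pair seeding makes the network reproducible", {
  sim <- simulate_ppi(n_modules = 4, module_size = 6,
                      n_crosstalk_pairs = 2, crosstalk_edge_prob = 0.5,
                      n_background_genes = 100,
                      background_edge_prob = 0.01, seed = 6)
  n1 <- build_module_network(sim$graph, sim$truth$modules,
                             n_perm = 200, seed = 5)
  n2 <- build_module_network(sim$graph, rev(sim$truth$modules),
                             n_perm = 200, seed = 5)
  # same pairs, same p-values regardless of module order
  canon <- function(p) {
    a <- pmin(p$module_a, p$module_b)
    b <- pmax(p$module_a, p$module_b)
    out <- data.frame(module_a = a, module_b = b,
                      observed = p$observed, p_value = p$p_value)
    out <- out[order(out$module_a, out$module_b), ]
    rownames(out) <- NULL
    out
  }
  expect_equal(canon(n1$pairs), canon(n2$pairs))
})
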
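test_that("the generator is a pure function of its seed", {
  s1 <- simulate_ppi(n_modules = 4, module_size = 6, seed = 42,
                     n_background_genes = 100)
  s2 <- simulate_ppi(n_modules = 4, module_size = 6, seed = 42,
                     n_background_genes = 100)
  expect_equal(igraph::as_data_frame(s1$graph),
               igraph::as_data_frame(s2$graph))
  expect_equal(s1$truth$modules, s2$truth$modules)
  s3 <- simulate_ppi(n_modules = 4, module_size = 6, seed = 43,
                     n_background_genes = 100)
  expect_false(identical(igraph::as_data_frame(s1$graph),
                         igraph::as_data_frame(s3$graph)))
})

test_that("zero background and cross-talk yield exactly the disjoint cliques", {
  sim <- simulate_ppi(n_modules = 3, module_size = 5,
                      n_crosstalk_pairs = 0, crosstalk_edge_prob = 0,
                      n_background_genes = 20, background_edge_prob = 0,
                      seed = 1)
  expect_equal(igraph::ecount(sim$graph), 3 * choose(5, 2))
  for (m in sim$truth$modules) {
    sub <- igraph::induced_subgraph(sim$graph, m)
    expect_equal(igraph::ecount(sub), choose(5, 2))
  }
  comp <- igraph::components(sim$graph)
  expect_equal(sum(comp$csize >= 5), 3)
})

test_that("infeasible generator parameters are rejected", {
  expect_error(simulate_ppi(module_size = 4), "module_size")
  expect_error(simulate_ppi(n_modules = 3, n_crosstalk_pairs = 10),
               "pairs")
})

test_that("noiseless condition scores place drivers at exactly +/- delta", {
  sim <- simulate_ppi(n_modules = 4, module_size = 6, seed = 2,
                      n_background_genes = 50)
  sc <- simulate_condition_scores(sim$truth, c("M01", "M03"),
                                  effect_size = 3, noise_sd = 0,
                                  seed = 11)
  driver_genes <- unlist(sim$truth$modules[c("M01", "M03")])
  expect_setequal(unique(abs(sc[driver_genes])), 3)
  # balanced signs within each driver module
  for (m in c("M01", "M03"))
    expect_equal(sum(sign(sc[sim$truth$modules[[m]]])), 0)
  expect_true(all(sc[setdiff(names(sc), driver_genes)] == 0))
})

test_that("a zero effect size is exchangeable with background", {
  sim <- simulate_ppi(n_modules = 4, module_size = 6, seed = 2,
                      n_background_genes = 50)
  sc <- simulate_condition_scores(sim$truth, "M01", effect_size = 0,
                                  noise_sd = 1, seed = 12)
  imp <- module_importance(sc, sim$truth$modules)
  # driver module indistinguishable: not systematically the largest
  expect_lt(imp[["M01"]], max(imp) + 1e-9)
  expect_equal(length(sc), length(sim$truth$genes))
})

test_that("driver modules dominate the raw importance ranking", {
  hits <- 0L
  for (sd in 1:10) {
    sim <- simulate_ppi(seed = sd)
    drivers <- c("M03", "M04")
    sc <- simulate_condition_scores(sim$truth, drivers, seed = sd)
    top <- rank_modules(module_importance(sc, sim$truth$modules),
                        top_n = 2)$module
    if (setequal(top, drivers)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("benchmarks wire true drugs to their disease's driver modules", {
  sim <- simulate_ppi(seed = 3)
  bench <- simulate_benchmark(sim$truth, n_diseases = 4, n_drugs = 30,
                              n_true_per_disease = 5, seed = 3)
  expect_length(bench$disease_scores, 4)
  expect_length(bench$drug_scores, 30)
  expect_equal(nrow(bench$standard$pairs), 20)
  expect_true(all(bench$standard$pairs$drug_id %in%
                    bench$standard$drug_universe))
  # drivers are anchored on a planted cross-talk pair
  ct <- apply(sim$truth$crosstalk_pairs, 1, paste, collapse = "+")
  for (d in names(bench$drivers)) {
    pair_hits <- apply(sim$truth$crosstalk_pairs, 1, function(p)
      all(p %in% bench$drivers[[d]]))
    expect_true(any(pair_hits))
  }
  # a true drug's strongest modules are its disease's drivers
  d <- "DIS01"
  drug <- bench$true_drugs[[d]][1]
  imp <- module_importance(bench$drug_scores[[drug]], sim$truth$modules)
  expect_setequal(rank_modules(imp, top_n = 2)$module,
                  bench$drivers[[d]])
})

test_that("generated fixtures round-trip through the text formats", {
  sim <- simulate_ppi(n_modules = 4, module_size = 6, seed = 9,
                      n_background_genes = 80)
  d <- withr::local_tempdir()
  f <- file.path(d, "ppi.tsv")
  write_ppi(sim$graph, f)
  g2 <- read_ppi(f, min_confidence = 0)
  expect_equal(igraph::ecount(g2), igraph::ecount(sim$graph))
  expect_equal(inter_edge_count(g2, sim$truth$modules$M01,
                                sim$truth$modules$M02),
               inter_edge_count(sim$graph, sim$truth$modules$M01,
                                sim$truth$modules$M02))
  fm <- file.path(d, "modules.gmt")
  write_modules(sim$truth$modules, fm)
  expect_equal(read_modules(fm), sim$truth$modules)
  sc <- simulate_condition_scores(sim$truth, "M02", seed = 4)
  fs <- file.path(d, "scores.tsv")
  write_scores(sc, fs)
  expect_equal(read_scores(fs), sc, tolerance = 1e-12)
})

test_that("a benchmark where every drug is positive degenerates loudly", {
  sim <- simulate_ppi(n_modules = 4, module_size = 6, seed = 5,
                      n_background_genes = 60)
  bench <- simulate_benchmark(sim$truth, n_diseases = 1, n_drugs = 4,
                              n_true_per_disease = 4, seed = 5)
  rk <- screen_drugs(bench$disease_scores, bench$drug_scores,
                     modules = sim$truth$modules, method = "module",
                     top_n = 4)
  expect_warning(expect_error(evaluate(rk, bench$standard), "excluded"),
                 "no negatives")
})
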
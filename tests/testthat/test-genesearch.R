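test_that("prefilter keeps expressed, variable genes only", {
  mat <- rbind(kept = c(1.5, 2.0, 0.0),
               low = c(1.5, 0.0, 0.0),
               flat = c(2.0, 2.0, 2.0))
  colnames(mat) <- paste0("c", 1:3)
  expr <- expression_matrix(mat)
  expect_identical(prefilter_genes(expr), "kept")
  flat_only <- expression_matrix(mat["flat", , drop = FALSE])
  expect_error(prefilter_genes(flat_only), "no genes pass")
})

test_that("shadow-feature preselection separates markers from noise", {
  g <- path_graph(3)
  expr <- toy_marker_expression(g, cells_per_domain = 15, n_noise = 50,
                                noise_sd = 0.1, seed = 2)
  sel <- preselect_features(expr, max_runs = 20, num_trees = 200, seed = 5)
  markers <- grep("^mk_", expr$gene_ids, value = TRUE)
  noise <- grep("^nz_", expr$gene_ids, value = TRUE)
  expect_true(all(sel$status[markers] == "confirmed"))
  expect_gte(mean(sel$status[noise] == "rejected"), 0.9)
  expect_true(all(sel$pool %in% expr$gene_ids))
})

test_that("a constant gene is rejected by preselection", {
  g <- path_graph(2)
  expr <- toy_marker_expression(g, cells_per_domain = 10, seed = 3)
  flat <- matrix(1, 1, length(expr$cell_ids),
                 dimnames = list("flatgene", expr$cell_ids))
  expr2 <- expression_matrix(rbind(expr$values, flat),
                             domain_labels = expr$domain_labels)
  sel <- preselect_features(expr2, max_runs = 15, num_trees = 150, seed = 1)
  expect_equal(as.character(sel$status["flatgene"]), "rejected")
})

test_that("candidate proposals enumerate additions and removals", {
  pool <- c("g1", "g2", "g3")
  cands <- propose_candidates("g1", pool)
  keys <- sapply(cands, function(x) paste(sort(x), collapse = "+"))
  expect_setequal(keys, c("g1+g2", "g1+g3"))  # removal to empty set excluded

  cands <- propose_candidates(c("g1", "g2"), pool)
  expect_length(cands, 1 + 2)  # one addition, two removals

  pool10 <- paste0("g", 1:10)
  cands <- propose_candidates(paste0("g", 1:3), pool10)
  expect_length(cands, 7 + 3)
})

test_that("an exhausted neighborhood falls back to one swap replacement", {
  pool <- c("g1", "g2", "g3")
  current <- c("g1", "g2")
  neighbors <- c(propose_candidates(current, pool), list(current))
  registry <- vapply(neighbors, function(s) paste(sort(s), collapse = "\x1f"), "")
  set.seed(4)
  cands <- propose_candidates(current, pool, registry = registry)
  expect_length(cands, 1)
  expect_length(cands[[1]], 2)           # swap keeps the set size
  expect_true("g3" %in% cands[[1]])      # brings in the outside gene
})

test_that("candidate selection probabilities use the standardized softmax", {
  expect_equal(candidate_selection_probabilities(1.7), 1.0)
  expect_equal(candidate_selection_probabilities(rep(1.2, 5)), rep(0.2, 5))
  p <- candidate_selection_probabilities(c(1.0, 1.0, 1.8))
  expect_equal(p, c(0.0647, 0.0647, 0.8705), tolerance = 1e-3)
})

test_that("replica exchange probability matches the printed expression", {
  expect_equal(replica_exchange_probability(1.3, 1.3, 0.1, 0.4), 1.0)
  expect_equal(replica_exchange_probability(0.2, 0.9, 0.3, 0.3), 1.0)
  expect_equal(replica_exchange_probability(1, 2, 0.5, 1), exp(-1))
  expect_error(replica_exchange_probability(1, 2, 0, 1), "positive")
})

test_that("search on separable toy data finds the perfect-score subset", {
  g <- path_graph(3)
  expr <- toy_marker_expression(g, cells_per_domain = 5, n_noise = 7,
                                noise_sd = 0.05, seed = 6)
  pool <- expr$gene_ids  # 3 markers + 7 noise = 10 candidates
  rs <- mcmc_run(pool, expr, g, steps = 50, n_init = 3, som_steps = 30,
                 alloc_steps = 20, seed = 17)
  expect_equal(rs$best_score, 2.0)
  # best-score trace is monotone non-decreasing
  expect_true(all(diff(rs$trace$best_score) >= 0))
  # registry contract: every evaluation hit a fresh subset
  rep1 <- rs$replicas[[1]]
  expect_equal(rep1$n_evaluations, rep1$n_unique_sets)
})

test_that("a single replica reproduces the plain MCMC run", {
  g <- path_graph(3)
  expr <- toy_marker_expression(g, cells_per_domain = 4, n_noise = 5, seed = 8)
  a <- mcmc_run(expr$gene_ids, expr, g, steps = 15, n_init = 4,
                som_steps = 20, alloc_steps = 10, seed = 23)
  b <- replica_exchange_search(expr$gene_ids, expr, g, replicas = 1,
                               steps = 15, n_init = 4, som_steps = 20,
                               alloc_steps = 10, seed = 23)
  expect_identical(a$best_set, b$best_set)
  expect_identical(a$best_score, b$best_score)
  expect_identical(a$trace, b$trace)
})

test_that("the global best dominates every replica and reruns reproduce", {
  g <- path_graph(3)
  expr <- toy_marker_expression(g, cells_per_domain = 4, n_noise = 5, seed = 9)
  rs <- replica_exchange_search(expr$gene_ids, expr, g, replicas = 3,
                                steps = 12, n_init = 3, som_steps = 20,
                                alloc_steps = 10, seed = 31)
  for (rep in rs$replicas) expect_lte(rep$best_score, rs$best_score)
  rs2 <- replica_exchange_search(expr$gene_ids, expr, g, replicas = 3,
                                 steps = 12, n_init = 3, som_steps = 20,
                                 alloc_steps = 10, seed = 31)
  expect_identical(rs$best_set, rs2$best_set)
  expect_identical(rs$trace, rs2$trace)
})
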
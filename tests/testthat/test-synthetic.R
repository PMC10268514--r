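test_that("backbone graphs have the advertised shapes", {
  lin <- backbone_graph("linear")
  expect_true(lin$is_connected)
  expect_equal(sum(lin$adjacency) / 2, length(lin$vertex_names) - 1)
  cyc <- backbone_graph("cycle")
  expect_true(all(rowSums(cyc$adjacency) == 2))
  dis <- backbone_graph("disconnected")
  expect_false(dis$is_connected)
  bif <- backbone_graph("bifurcating")
  expect_equal(max(rowSums(bif$adjacency)), 3)  # the branch point
})

test_that("simulation is reproducible and labelled consistently", {
  s1 <- simulate_backbone_expression("linear", n_cells = 100, seed = 4)
  s2 <- simulate_backbone_expression("linear", n_cells = 100, seed = 4)
  expect_identical(s1$counts, s2$counts)
  s3 <- simulate_backbone_expression("linear", n_cells = 100, seed = 5)
  expect_false(identical(s1$counts, s3$counts))
  expect_setequal(unique(s1$expr$domain_labels), s1$graph$vertex_names)
  expect_equal(dim(s1$counts),
               c(5 * 3 + 40 + 40, 100))
})

test_that("noiseless markers classify modules perfectly by nearest centroid", {
  sim <- simulate_backbone_expression("linear", n_cells = 150,
                                      dispersion = 0, lib_jitter = 0,
                                      noise_sd = 0, seed = 9)
  v <- sim$expr$values[grep("^marker_", rownames(sim$counts)), ]
  labs <- sim$expr$domain_labels
  cents <- vapply(sim$graph$vertex_names,
                  function(m) rowMeans(v[, labs == m, drop = FALSE]),
                  numeric(nrow(v)))
  pred <- sim$graph$vertex_names[apply(v, 2, function(x) {
    which.min(colSums((cents - x)^2))
  })]
  expect_equal(mean(pred == labs), 1.0)
})

test_that("disconnected components are less correlated than neighbors", {
  seps <- vapply(1:10, function(s) {
    sim <- simulate_backbone_expression("disconnected", n_cells = 200, seed = s)
    labs <- sim$expr$domain_labels
    cents <- vapply(sim$graph$vertex_names,
                    function(m) rowMeans(sim$expr$values[, labs == m, drop = FALSE]),
                    numeric(nrow(sim$expr$values)))
    cors <- cor(cents)
    d <- sim$graph$distances
    ut <- upper.tri(d)
    k <- nrow(d)
    min(cors[ut][d[ut] == 1]) - max(cors[ut][d[ut] >= k])
  }, numeric(1))
  expect_gt(median(seps), 0)
  expect_true(all(seps > 0))
})

test_that("topology derivation recovers the linear and cycle module graphs", {
  for (kind in c("linear", "cycle")) {
    seed <- if (kind == "linear") 111 else 666
    sim <- simulate_backbone_expression(kind, n_cells = 500, seed = seed)
    nm <- length(sim$graph$vertex_names)
    res <- derive_topology_graph(sim$expr, cluster_range = c(nm, nm + 2),
                                 expect = "connected", seed = 7)
    ct <- table(sim$expr$domain_labels, res$labels)
    expect_equal(ncol(ct), nm)
    mapping <- rownames(ct)[apply(ct, 2, which.max)]
    expect_equal(length(unique(mapping)), nm)
    expect_equal(unname(sim$graph$adjacency[mapping, mapping]),
                 unname(res$graph$adjacency))
  }
})

test_that("derivation reports the correlation spectrum when no threshold works", {
  sim <- simulate_backbone_expression("disconnected", n_cells = 200, seed = 3)
  nm <- length(sim$graph$vertex_names)
  expect_error(
    derive_topology_graph(sim$expr, cluster_range = c(nm, nm + 2),
                          expect = "connected", seed = 7),
    "correlations")
})

test_that("derived topology has the right connectivity for every backbone", {
  for (kind in c("linear", "cycle", "bifurcating", "branching", "disconnected")) {
    sim <- simulate_backbone_expression(kind, n_cells = 400, seed = 21)
    nm <- length(sim$graph$vertex_names)
    expect <- if (kind == "disconnected") "disconnected" else "connected"
    res <- derive_topology_graph(sim$expr, cluster_range = c(nm, nm + 2),
                                 expect = expect, seed = 5)
    expect_equal(res$graph$is_connected, expect == "connected")
    expect_true(res$threshold >= 0.70 && res$threshold <= 0.85)
  }
})

test_that("misspecification experiment summarizes per-graph maxima", {
  sim <- simulate_backbone_expression("linear", n_cells = 200, seed = 31)
  nm <- length(sim$graph$vertex_names)
  der <- derive_topology_graph(sim$expr, cluster_range = c(nm, nm + 2),
                               expect = "connected", seed = 5)
  pool <- grep("^marker_|^grad_", sim$expr$gene_ids, value = TRUE)[1:12]
  mis <- misspecification_experiment(
    sim$expr, der$labels, der$graph, p = 0.1, constraint = "connected",
    pool = pool, n_graphs = 2, runs = 1, downsample = 6, seed = 1,
    replicas = 1, steps = 5, n_init = 4, som_steps = 15, alloc_steps = 10)
  expect_equal(nrow(mis$per_graph), 2)
  expect_true(all(c("max_score", "max_accuracy", "max_ari") %in%
                    colnames(mis$per_graph)))
  expect_equal(mis$summary$mean_max_score, mean(mis$per_graph$max_score))
  expect_true(is.finite(mis$summary$ci_score))
})
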
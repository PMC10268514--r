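test_that("centroid initialization is seeded, in range, and seed-sensitive", {
  g <- path_graph(4)
  expr <- toy_marker_expression(g, cells_per_domain = 3)
  s1 <- initialize_centroids(expr, g, seed = 1)
  s2 <- initialize_centroids(expr, g, seed = 1)
  s3 <- initialize_centroids(expr, g, seed = 2)
  expect_identical(s1$centroids, s2$centroids)
  expect_false(identical(s1$centroids, s3$centroids))
  rng <- apply(expr$values, 1, range)
  for (d in seq_len(ncol(s1$centroids))) {
    expect_true(all(s1$centroids[, d] >= rng[1, d] - 1e-12))
    expect_true(all(s1$centroids[, d] <= rng[2, d] + 1e-12))
  }
  expect_error(subset_expression(expr, genes = character(0)) |>
                 initialize_centroids(g), "empty gene subset")
})

test_that("find_bmu returns the nearest centroid with low-index tie-break", {
  g <- path_graph(5)
  expr <- toy_marker_expression(g, cells_per_domain = 2)
  state <- initialize_centroids(expr, g, seed = 3)
  expect_equal(find_bmu(state$centroids[3, ], state), 3)
  # equidistant centroids 1 and 4
  state$centroids[1, ] <- rep(0, ncol(state$centroids))
  state$centroids[4, ] <- rep(2, ncol(state$centroids))
  x <- rep(1, ncol(state$centroids))
  state$centroids[c(2, 3, 5), ] <- 100
  expect_equal(find_bmu(x, state), 1)
  # brute-force check on random states and cells
  set.seed(9)
  for (rep in 1:20) {
    st <- initialize_centroids(expr, g, seed = rep)
    x <- runif(ncol(st$centroids), 0, 2)
    d2 <- apply(st$centroids, 1, function(m) sum((x - m)^2))
    expect_equal(find_bmu(x, st), unname(which.min(d2)))
  }
})

test_that("neighborhood weight follows the stochastic kernel", {
  expect_equal(neighborhood_weight(0, 2, 0.7), 1.0)
  expect_equal(neighborhood_weight(1, 1, 0.5), exp(-0.25))
  # strictly decreasing in distance and in the stochastic factor
  w_d <- neighborhood_weight(0:4, 1.5, 0.6)
  expect_true(all(diff(w_d) < 0))
  w_u <- neighborhood_weight(2, 1.5, c(0.5, 0.7, 0.9))
  expect_true(all(diff(w_u) < 0))
  expect_true(all(w_d > 0 & w_d <= 1))
  expect_error(neighborhood_weight(1, 0, 0.5), "sigma")
  expect_error(neighborhood_weight(1, 1, 0.4), "u must")
})

test_that("one batch update reproduces the hand-computed weighted means", {
  g <- path_graph(2, c("A", "B"))
  mat <- matrix(c(0, 1, 9, 10), nrow = 1,
                dimnames = list("g1", paste0("c", 1:4)))
  labels <- c(c1 = "A", c2 = "A", c3 = "B", c4 = "B")
  expr <- expression_matrix(mat, domain_labels = labels)
  state <- initialize_centroids(expr, g, seed = 1, total_steps = 1, sigma0 = 1)
  state$centroids[] <- c(0, 10)
  upd <- batch_update(expr, state, g, u_pin = 0.75)
  w <- exp(-0.75 / 2)  # weight at distance 1
  m1 <- (0 + 1 + w * (9 + 10)) / (2 + 2 * w)
  m2 <- (w * (0 + 1) + 9 + 10) / (2 * w + 2)
  expect_equal(unname(upd$centroids[, 1]), c(m1, m2), tolerance = 1e-12)
})

test_that("huge sigma drives every centroid to the global mean", {
  g <- path_graph(3)
  expr <- toy_marker_expression(g, cells_per_domain = 3)
  state <- initialize_centroids(expr, g, seed = 2, total_steps = 1, sigma0 = 1e6)
  upd <- batch_update(expr, state, g, u_pin = 0.75)
  gm <- rowMeans(expr$values)
  for (i in 1:3) expect_equal(unname(upd$centroids[i, ]), unname(gm),
                              tolerance = 1e-6)
})

test_that("updated centroids stay inside the per-gene data range", {
  g <- cycle_graph(4)
  expr <- toy_marker_expression(g, cells_per_domain = 4, n_noise = 3)
  state <- initialize_centroids(expr, g, seed = 5, total_steps = 10, sigma0 = 2)
  set.seed(6)
  for (t in 1:5) {
    state <- batch_update(expr, state, g)
    rng <- apply(expr$values, 1, range)
    expect_true(all(t(state$centroids) >= rng[1, ] - 1e-12))
    expect_true(all(t(state$centroids) <= rng[2, ] + 1e-12))
  }
})

test_that("pinned near-indicator update equals a Lloyd k-means step", {
  g <- path_graph(3)
  expr <- toy_marker_expression(g, cells_per_domain = 5, seed = 4)
  # start from centroids close to the three true clusters
  init <- t(vapply(g$vertex_names, function(d) {
    rowMeans(expr$values[, expr$domain_labels == d, drop = FALSE]) + 0.01
  }, numeric(length(expr$gene_ids))))
  state <- initialize_centroids(expr, g, seed = 1, total_steps = 1, sigma0 = 0.05)
  state$centroids[] <- init
  upd <- batch_update(expr, state, g, u_pin = 0.75)
  km <- suppressWarnings(stats::kmeans(t(expr$values), centers = init,
                                       iter.max = 1, algorithm = "Lloyd"))
  expect_lt(max(abs(upd$centroids - km$centers)), 1e-10)
})

test_that("full fit on separable markers attains the perfect score", {
  g <- complete_graph(3)
  expr <- toy_marker_expression(g, cells_per_domain = 4, noise_sd = 0.01)
  fit <- gsom_fit(expr, g, som_steps = 50, alloc_steps = 30, seed = 11)
  expect_equal(fit$score, 2.0)
  expect_equal(fit$accuracy, 1.0)
  expect_equal(fit$ari, 1.0)
})

test_that("single-vertex mapping layer is trivially perfect", {
  g <- topology_graph(matrix(0, 1, 1), "only")
  mat <- matrix(runif(20), nrow = 2,
                dimnames = list(c("g1", "g2"), paste0("c", 1:10)))
  expr <- expression_matrix(mat, domain_labels = setNames(rep("only", 10),
                                                          colnames(mat)))
  fit <- gsom_fit(expr, g, som_steps = 5, alloc_steps = 0, seed = 1)
  expect_equal(fit$accuracy, 1.0)
  expect_equal(unname(fit$predicted), rep("only", 10))
})

test_that("fits are reproducible and invariant to cell order", {
  g <- path_graph(3)
  expr <- toy_marker_expression(g, cells_per_domain = 4, n_noise = 2)
  f1 <- gsom_fit(expr, g, som_steps = 30, alloc_steps = 20, seed = 7)
  f2 <- gsom_fit(expr, g, som_steps = 30, alloc_steps = 20, seed = 7)
  expect_identical(f1$predicted, f2$predicted)
  expect_identical(f1$score, f2$score)
  # batch learning: permuting cells does not change the learned assignment
  perm <- rev(expr$cell_ids)
  exprp <- subset_expression(expr, cells = perm)
  # same init (seeded independently of cell order), pinned stochastic factor
  init <- initialize_centroids(expr, g, seed = 3)$centroids
  f3 <- gsom_fit(expr, g, som_steps = 20, alloc_steps = 0, seed = 1,
                 u_pin = 0.8, init = init)
  f4 <- gsom_fit(exprp, g, som_steps = 20, alloc_steps = 0, seed = 1,
                 u_pin = 0.8, init = init)
  expect_identical(f3$predicted[expr$cell_ids], f4$predicted[expr$cell_ids])
})

test_that("compiled fit reproduces the in-R batch update sequence", {
  g <- cycle_graph(4)
  expr <- toy_marker_expression(g, cells_per_domain = 3, n_noise = 2, seed = 8)
  init <- initialize_centroids(expr, g, seed = 10)$centroids
  steps <- 5
  state <- initialize_centroids(expr, g, seed = 1, total_steps = steps,
                                sigma0 = 2, sigma_final = 0.3)
  state$centroids[] <- init
  for (t in seq_len(steps)) state <- batch_update(expr, state, g, u_pin = 0.75)
  fit <- gsom_fit(expr, g, som_steps = steps, sigma0 = 2, sigma_final = 0.3,
                  alloc_steps = 0, u_pin = 0.75, init = init, seed = 1)
  expect_equal(unname(fit$centroids), unname(state$centroids), tolerance = 1e-12)
})
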
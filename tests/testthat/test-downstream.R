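test_that("downsampling keeps small domains whole and samples large ones", {
  labels <- setNames(rep(c("A", "B"), times = c(7, 100)), paste0("c", 1:107))
  kept <- downsample_cells(labels, size = 10, seed = 1)
  expect_equal(sum(labels[kept] == "A"), 7)    # all of the small domain
  expect_equal(sum(labels[kept] == "B"), 10)   # exactly ten of the large one
  expect_identical(kept, downsample_cells(labels, size = 10, seed = 1))
  expect_false(identical(kept, downsample_cells(labels, size = 10, seed = 2)))
})

test_that("consensus genes require the minimum run frequency", {
  runs <- list(c("a", "b", "c"), c("a", "b"), c("a", "b"), c("a", "d"),
               c("a"), c("a"), c("a"), c("a"), c("a"), c("a"))
  cons <- consensus_genes(runs, min_count = 3)
  expect_identical(cons, c("a", "b"))   # a in 10/10 ranks first; c,d below cutoff
  expect_false("c" %in% cons)
  expect_identical(consensus_genes(list(c("x", "y")), min_count = 1), c("x", "y"))
})

test_that("knocking out a gene outside the consensus set is a no-op", {
  g <- path_graph(3)
  expr <- toy_marker_expression(g, cells_per_domain = 4, n_noise = 2, seed = 2)
  consensus <- grep("^mk_", expr$gene_ids, value = TRUE)
  expect_warning(
    vko <- virtual_knockout(expr, g, consensus,
                            knockouts = list(ghost = "not_a_gene"),
                            runs = 5, seed = 10, som_steps = 20,
                            alloc_steps = 10),
    "not in the consensus")
  base <- vko[vko$knockout == "noKO", -1]
  ghost <- vko[vko$knockout == "ghost", -1]
  expect_equal(unname(unlist(base)), unname(unlist(ghost)))
})

test_that("an essential marker costs more than a redundant one", {
  # domain D carries no marker: remove B's sole marker and B collapses onto
  # D's all-low profile, while A keeps its second, redundant marker
  g <- path_graph(4, c("A", "B", "C", "D"))
  set.seed(12)
  labels <- setNames(rep(c("A", "B", "C", "D"), each = 6), paste0("c", 1:24))
  base <- function(dom, high = 2, low = 0.1) {
    ifelse(labels == dom, high, low) + rnorm(24, 0, 0.05)
  }
  mat <- rbind(mkA_1 = base("A"), mkA_2 = base("A"),  # redundant pair for A
               mkB = base("B"),                       # sole marker for B
               mkC = base("C"))
  mat[mat < 0] <- 0
  colnames(mat) <- names(labels)
  expr <- expression_matrix(mat, domain_labels = labels)
  consensus <- rownames(mat)
  vko <- virtual_knockout(expr, g, consensus,
                          knockouts = list(redundant = "mkA_1",
                                           essential = "mkB"),
                          runs = 20, seed = 3, som_steps = 30, alloc_steps = 20)
  expect_lt(vko$mean_score[vko$knockout == "essential"],
            vko$mean_score[vko$knockout == "redundant"])
  # most influential knockout ranks first (ascending mean score)
  expect_equal(vko$knockout[1], "essential")
  expect_error(virtual_knockout(expr, g, consensus,
                                knockouts = list(all = consensus),
                                runs = 2, seed = 1),
               "removes all")
})

test_that("hypergeometric enrichment matches exact enumeration", {
  universe <- paste0("g", 1:10)
  annotation <- data.frame(gene = paste0("g", 1:5), term = "T1")
  res <- hypergeometric_enrichment(paste0("g", c(1:3, 5)), annotation, universe)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)  # C(5,4)/C(10,4)
  # zero overlap is certain at level 1
  res0 <- hypergeometric_enrichment(paste0("g", 6:9), annotation, universe)
  expect_equal(res0$p_value, 1.0)
  # a term annotating the whole universe is uninformative
  all_t <- data.frame(gene = universe, term = "ALL")
  resA <- hypergeometric_enrichment(paste0("g", 1:4), all_t, universe)
  expect_equal(resA$p_value, 1.0)
  expect_error(hypergeometric_enrichment("g99", annotation, universe),
               "universe")
})

test_that("enrichment conserves annotation overlap counts and p-value range", {
  set.seed(8)
  universe <- paste0("g", 1:40)
  annotation <- data.frame(
    gene = sample(universe, 60, replace = TRUE),
    term = sample(paste0("T", 1:6), 60, replace = TRUE))
  annotation <- unique(annotation)
  genes <- sample(universe, 12)
  res <- hypergeometric_enrichment(genes, annotation, universe)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  per_gene <- sum(table(annotation$term[annotation$gene %in% genes]))
  expect_equal(sum(res$overlap), per_gene)
})
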
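#' Pairwise adjacency accuracy of a topological clustering
#'
#' For every unordered pair of cells, the pair is counted as correct when the
#' adjacency-matrix state of the pair's predicted domains equals that of its
#' true domains. Same-domain pairs read the (zero) diagonal, so two cells of
#' one domain predicted into one domain always match. Accuracy is the fraction
#' of correct pairs over all C(n, 2) pairs.
#'
#' @param true_domains named character vector, cell id -> true domain
#'   (a vertex name of `graph`).
#' @param predicted named character vector, cell id -> predicted vertex name.
#' @param graph the [topology_graph] the clustering was run against.
#' @return Accuracy in \[0, 1\].
#' @export
pairwise_accuracy <- function(true_domains, predicted, graph) {
  stopifnot(inherits(graph, "topology_graph"))
  cells <- names(true_domains)
  if (is.null(cells) || is.null(names(predicted))) {
    stop("true_domains and predicted must be named by cell id")
  }
  if (!setequal(cells, names(predicted))) {
    stop("true and predicted assignments cover different cell sets")
  }
  predicted <- predicted[cells]
  n <- length(cells)
  if (n < 2L) stop("need at least two cells")
  bad <- setdiff(unique(c(true_domains, predicted)), graph$vertex_names)
  if (length(bad)) {
    stop("labels not in graph: ", paste(bad, collapse = ", "))
  }
  ct <- table(factor(true_domains, levels = graph$vertex_names),
              factor(predicted, levels = graph$vertex_names))
  accuracy_from_contingency(unclass(ct), graph$adjacency)
}

# Pair-counting accuracy from a (true domain x predicted vertex) contingency
# table; O((m*k)^2) in the nonzero groups rather than O(n^2) in cells.
accuracy_from_contingency <- function(ct, adjacency) {
  nz <- which(ct > 0, arr.ind = TRUE)
  N <- ct[nz]
  n <- sum(N)
  total_pairs <- n * (n - 1) / 2
  # within-group pairs always agree (both read the zero diagonal)
  correct <- sum(N * (N - 1) / 2)
  if (nrow(nz) > 1L) {
    a_true <- adjacency[nz[, 1], nz[, 1], drop = FALSE]
    a_pred <- adjacency[nz[, 2], nz[, 2], drop = FALSE]
    match <- (a_true == a_pred)
    cross <- outer(N, N)
    ut <- upper.tri(match)
    correct <- correct + sum(cross[ut][match[ut]])
  }
  correct / total_pairs
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement between two labelings of the same
#' items, computed from the contingency table. The topology graph plays no
#' role. In the degenerate case of a zero denominator (e.g. both partitions a
#' single cluster), the index is defined as 1 when the partitions are
#' identical up to label renaming and 0 otherwise.
#'
#' @param x,y vectors of cluster labels over the same items (if named, they
#'   are aligned by name).
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    if (!setequal(names(x), names(y))) stop("x and y cover different items")
    y <- y[names(x)]
  }
  if (length(x) != length(y)) stop("x and y differ in length")
  n <- length(x)
  if (n < 2L) stop("need at least two items")
  ct <- unclass(table(x, y))
  a <- rowSums(ct)
  b <- colSums(ct)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(a, 2))
  sum_b <- sum(choose(b, 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) {
    identical_partition <- all(rowSums(ct > 0) <= 1) && all(colSums(ct > 0) <= 1)
    return(if (identical_partition) 1.0 else 0.0)
  }
  (sum_ij - expected) / denom
}

#' Combined clustering score
#'
#' `Score = Accuracy + a * ARI`, the objective maximized by the gene-set
#' search. The default weight `a = 1.0` gives both criteria equal influence.
#'
#' @param accuracy pairwise adjacency accuracy.
#' @param ari adjusted Rand index.
#' @param weight_a non-negative weight on the ARI term.
#' @return The combined score.
#' @export
clustering_score <- function(accuracy, ari, weight_a = 1.0) {
  if (weight_a < 0) stop("weight_a must be non-negative")
  accuracy + weight_a * ari
}

#' Bundle a clustering evaluation
#'
#' @param predicted,true_domains named cell -> vertex/domain vectors.
#' @param graph the [topology_graph].
#' @param weight_a ARI weight in the combined score.
#' @return Object of class `clustering_result` with `accuracy`, `ari`,
#'   `score`, `weight_a` and the assignments.
#' @export
clustering_result <- function(predicted, true_domains, graph, weight_a = 1.0) {
  acc <- pairwise_accuracy(true_domains, predicted, graph)
  ari <- adjusted_rand_index(true_domains, predicted[names(true_domains)])
  structure(
    list(predicted = predicted, true_domains = true_domains,
         accuracy = acc, ari = ari,
         score = clustering_score(acc, ari, weight_a), weight_a = weight_a),
    class = "clustering_result"
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("clustering_result: score %.4f (accuracy %.4f + %.2g * ARI %.4f), %d cells\n",
              x$score, x$accuracy, x$weight_a, x$ari, length(x$predicted)))
  invisible(x)
}
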
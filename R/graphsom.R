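#' @useDynLib gsomata, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# evaluate fn under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

# sigma at step t (0-based) of an exponentially decaying schedule
sigma_at <- function(t, total_steps, sigma0, sigma_final) {
  frac <- if (total_steps > 1) t / (total_steps - 1) else 0
  sigma0 * (sigma_final / sigma0)^frac
}

# default initial neighborhood radius: largest finite graph distance
default_sigma0 <- function(graph) {
  k <- length(graph$vertex_names)
  finite <- graph$distances[graph$distances < k]
  max(1, max(finite))
}

#' Initialize SOM centroids on a topology graph
#'
#' One centroid per graph vertex, each coordinate drawn uniformly within the
#' observed per-gene \[min, max\] range of the data.
#'
#' @param expr an `expression_set` already restricted to the gene subset.
#' @param graph the [topology_graph] serving as mapping layer.
#' @param seed optional integer seed.
#' @param total_steps,sigma0,sigma_final learning schedule recorded on the
#'   state; `sigma0` defaults to the largest finite graph distance.
#' @return Object of class `som_state`: centroids (vertices x genes), step
#'   counter and schedule.
#' @export
initialize_centroids <- function(expr, graph, seed = NULL, total_steps = 200L,
                                 sigma0 = NULL, sigma_final = 0.3) {
  stopifnot(inherits(expr, "expression_set"), inherits(graph, "topology_graph"))
  if (length(expr$gene_ids) == 0L) stop("empty gene subset")
  if (length(expr$cell_ids) == 0L) stop("no cells")
  if (is.null(sigma0)) sigma0 <- default_sigma0(graph)
  k <- length(graph$vertex_names)
  v <- expr$values
  centroids <- with_seed(seed, function() {
    vapply(seq_len(nrow(v)), function(d) {
      rng <- range(v[d, ])
      stats::runif(k, rng[1], rng[2])
    }, numeric(k))
  })
  centroids <- matrix(centroids, nrow = k,
                      dimnames = list(graph$vertex_names, expr$gene_ids))
  structure(
    list(centroids = centroids, step = 0L, total_steps = as.integer(total_steps),
         sigma0 = sigma0, sigma_final = sigma_final),
    class = "som_state"
  )
}

#' Best matching unit of a cell vector
#'
#' @param x numeric vector over the state's genes.
#' @param state a `som_state`.
#' @return Index of the vertex whose centroid is nearest in Euclidean
#'   distance; ties break to the lowest vertex index.
#' @export
find_bmu <- function(x, state) {
  stopifnot(inherits(state, "som_state"))
  if (length(x) != ncol(state$centroids)) stop("dimension mismatch")
  d2 <- rowSums(sweep(state$centroids, 2, x)^2)
  unname(which.min(d2))
}

#' Stochastic neighborhood weight
#'
#' `h = exp(-u * d^2 / (2 * sigma^2))` with the stochastic factor
#' `u ~ Uniform[0.5, 1)` replacing a deterministic learning rate: even late
#' in learning (small sigma) the map keeps a randomized, Gibbs-like ability
#' to adjust, which delays freezing into local minima.
#'
#' @param d graph distance between the BMU's vertex and the updated vertex.
#' @param sigma current neighborhood radius, must be positive.
#' @param u stochastic factor in \[0.5, 1).
#' @return Weight in (0, 1\]; equals 1 iff `d == 0`.
#' @export
neighborhood_weight <- function(d, sigma, u) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(u < 0.5 | u >= 1)) stop("u must lie in [0.5, 1)")
  if (any(d < 0)) stop("d must be non-negative")
  exp(-u * d^2 / (2 * sigma^2))
}

#' One batch-learning update of all centroids
#'
#' Computes every cell's BMU with the current centroids, then replaces each
#' centroid by the neighborhood-weighted mean of all cells. One fresh
#' stochastic draw is made per (cell, vertex) weight evaluation.
#'
#' @param expr `expression_set` restricted to the state's genes.
#' @param state a `som_state`.
#' @param graph the mapping-layer [topology_graph].
#' @param u_pin optional constant replacing the stochastic factor (testing and
#'   degeneracy analysis).
#' @return The updated `som_state` with `step` advanced by one.
#' @export
batch_update <- function(expr, state, graph, u_pin = NULL) {
  stopifnot(inherits(expr, "expression_set"), inherits(state, "som_state"),
            inherits(graph, "topology_graph"))
  x <- t(expr$values)  # cells x genes
  if (ncol(x) != ncol(state$centroids)) stop("dimension mismatch")
  n <- nrow(x)
  k <- nrow(state$centroids)
  sigma <- sigma_at(state$step, state$total_steps, state$sigma0, state$sigma_final)
  # BMU per cell
  cross <- x %*% t(state$centroids)
  d2 <- outer(rowSums(x^2), rowSums(state$centroids^2), "+") - 2 * cross
  bmu <- max.col(-d2, ties.method = "first")
  # weights: k x n, draw order (cell-major) matches the compiled fit loop
  u <- if (is.null(u_pin)) {
    matrix(stats::runif(n * k, 0.5, 1), nrow = k)
  } else {
    matrix(u_pin, nrow = k, ncol = n)
  }
  dmat <- t(graph$distances[bmu, , drop = FALSE])  # k x n
  h <- neighborhood_weight(dmat, sigma, u)
  den <- rowSums(h)
  if (any(den <= 0)) stop("zero weight sum for a vertex")
  centroids <- (h %*% x) / den
  dimnames(centroids) <- dimnames(state$centroids)
  state$centroids <- centroids
  state$step <- state$step + 1L
  state
}

#' Fit a graph-based stochastic SOM and score the clustering
#'
#' Runs centroid initialization, `som_steps` batch updates with exponentially
#' decaying neighborhood radius, final BMU assignment, simulated-annealing
#' optimization of the cluster-to-vertex allocation, and evaluation (pairwise
#' adjacency accuracy, ARI against the true domain labels, combined score).
#' The whole procedure is reproducible for a fixed seed. The inner loops run
#' in compiled code.
#'
#' @param expr `expression_set` with `domain_labels` mapping every cell to a
#'   vertex of `graph`.
#' @param graph the [topology_graph] mapping layer.
#' @param genes optional gene subset to fit on (default: all genes in `expr`).
#' @param som_steps number of batch updates (default 200).
#' @param sigma0,sigma_final neighborhood radius schedule; `sigma0` defaults
#'   to the largest finite graph distance, decaying to 0.3.
#' @param alloc_steps annealing steps for the allocation optimization
#'   (default 100; 0 disables it).
#' @param weight_a ARI weight in the combined score.
#' @param seed optional integer seed (the caller's RNG stream is preserved).
#' @param u_pin optional constant stochastic factor (testing only).
#' @param init optional initial centroid matrix (vertices x genes).
#' @return Object of class `gsom_fit`: `predicted` (named cell -> vertex),
#'   `accuracy`, `ari`, `score`, `accuracy_raw` (before allocation
#'   optimization), `centroids`, `genes`, `seed`.
#' @export
gsom_fit <- function(expr, graph, genes = NULL, som_steps = 200L,
                     sigma0 = NULL, sigma_final = 0.3, alloc_steps = 100L,
                     weight_a = 1.0, seed = NULL, u_pin = NULL, init = NULL) {
  stopifnot(inherits(expr, "expression_set"), inherits(graph, "topology_graph"))
  if (is.null(expr$domain_labels)) stop("expression set has no domain labels")
  if (!is.null(genes)) expr <- subset_expression(expr, genes = genes)
  bad <- setdiff(unique(expr$domain_labels), graph$vertex_names)
  if (length(bad)) stop("domain labels not in graph: ", paste(bad, collapse = ", "))
  if (is.null(sigma0)) sigma0 <- default_sigma0(graph)
  xt <- t(expr$values)
  true_idx <- match(expr$domain_labels, graph$vertex_names) - 1L
  res <- with_seed(seed, function() {
    gsom_fit_cpp(xt, graph$distances, graph$adjacency, true_idx,
                 as.integer(som_steps), sigma0, sigma_final,
                 as.integer(alloc_steps), weight_a,
                 if (is.null(u_pin)) NA_real_ else u_pin,
                 init)
  })
  predicted <- stats::setNames(graph$vertex_names[res$assignment], expr$cell_ids)
  centroids <- res$centroids
  dimnames(centroids) <- list(graph$vertex_names, expr$gene_ids)
  structure(
    list(predicted = predicted, true_domains = expr$domain_labels,
         accuracy = res$accuracy, ari = res$ari, score = res$score,
         accuracy_raw = res$accuracy_raw, centroids = centroids,
         genes = expr$gene_ids, weight_a = weight_a, seed = seed),
    class = "gsom_fit"
  )
}

#' @export
print.gsom_fit <- function(x, ...) {
  cat(sprintf("gsom_fit: score %.4f (accuracy %.4f + %.2g * ARI %.4f), %d genes, %d cells\n",
              x$score, x$accuracy, x$weight_a, x$ari,
              length(x$genes), length(x$predicted)))
  invisible(x)
}
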
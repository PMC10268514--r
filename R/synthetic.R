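#' Module graph of a synthetic backbone
#'
#' Each backbone kind maps to a fixed small module network: `linear` (path of
#' 5), `cycle` (ring of 6), `bifurcating` (path splitting into two arms),
#' `branching` (two successive splits) and `disconnected` (a 3-module path
#' plus a separate 2-module component).
#'
#' @param kind backbone name.
#' @return A [topology_graph] over modules `M1`, `M2`, ...
#' @export
backbone_graph <- function(kind = c("linear", "cycle", "bifurcating",
                                    "branching", "disconnected")) {
  kind <- match.arg(kind)
  edges <- switch(kind,
    linear = cbind(1:4, 2:5),
    cycle = cbind(1:6, c(2:6, 1)),
    bifurcating = cbind(c(1, 2, 3, 3), c(2, 3, 4, 5)),
    branching = cbind(c(1, 2, 2, 4, 4), c(2, 3, 4, 5, 6)),
    disconnected = cbind(c(1, 2, 4), c(2, 3, 5)))
  k <- max(edges)
  adj <- matrix(0, k, k)
  adj[edges] <- 1
  adj <- adj + t(adj)
  adj[adj > 1] <- 1
  topology_graph(adj, paste0("M", seq_len(k)))
}

#' Simulate a synthetic single-cell dataset on a backbone
#'
#' Cells are spread evenly over the modules of the backbone's module graph.
#' Three gene classes are generated: per-module marker genes whose mean peaks
#' in their own module and decays geometrically with graph distance (the
#' spillover into neighboring modules emulates the smooth module-to-module
#' expression overlap of developmental trajectories), gradient genes whose
#' log-mean decreases
#' linearly with graph distance from a randomly chosen root module (so
#' expression changes monotonically along backbone paths, and stays flat at
#' baseline in unreachable components), and uninformative noise genes with a
#' module-independent mean. Counts are drawn from a negative-binomial
#' observation model with per-cell library-size jitter and optional
#' log-normal biological noise on the mean.
#'
#' @param kind backbone name, see [backbone_graph].
#' @param n_cells total number of cells (default 500).
#' @param markers_per_module marker genes per module (default 3).
#' @param n_gradient,n_noise numbers of gradient and noise genes
#'   (defaults 40 and 40).
#' @param mu_high,mu_low marker mean counts in the own module / baseline.
#' @param marker_decay geometric decay of the marker mean per edge of graph
#'   distance (default 0.4; unreachable modules stay at baseline).
#' @param dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson sampling.
#' @param lib_jitter half-width of the uniform library-size factor
#'   (default 0.2, i.e. factors in \[0.8, 1.2\]).
#' @param noise_sd SD of log-normal noise multiplied onto every mean
#'   (default 0.1; 0 disables it).
#' @param seed integer seed; the dataset is fully reproducible.
#' @return Object of class `backbone_sim`: `expr` (an `expression_set` of
#'   log10(count+1) values with module labels), `counts` (raw matrix),
#'   `graph` (the true module [topology_graph]) and `spec` (the parameters).
#' @export
simulate_backbone_expression <- function(kind = c("linear", "cycle", "bifurcating",
                                                  "branching", "disconnected"),
                                         n_cells = 500L, markers_per_module = 3L,
                                         n_gradient = 40L, n_noise = 40L,
                                         mu_high = 150, mu_low = 3,
                                         marker_decay = 0.4,
                                         dispersion = 0.2, lib_jitter = 0.2,
                                         noise_sd = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  graph <- backbone_graph(kind)
  k <- length(graph$vertex_names)
  d <- graph$distances
  maxd <- max(1, max(d[d < k]))
  out <- with_seed(seed, function() {
    modules <- sample(rep(graph$vertex_names, length.out = n_cells))
    midx <- match(modules, graph$vertex_names)
    mean_rows <- list()
    # markers: peak in the own module, geometric decay with graph distance
    for (m in seq_len(k)) {
      for (i in seq_len(markers_per_module)) {
        s <- marker_decay^d[m, ]
        s[d[m, ] >= k] <- 0
        mean_rows[[sprintf("marker_%s_%d", graph$vertex_names[m], i)]] <-
          mu_low + (mu_high - mu_low) * s
      }
    }
    # monotone gradients along graph paths; roots cycle over the modules so
    # every region of the graph is covered; flat at the baseline in
    # components unreachable from the root
    for (i in seq_len(n_gradient)) {
      root <- 1L + (i - 1L) %% k
      top <- stats::runif(1, 60, 200)
      slope <- stats::runif(1, 0.5, 1)  # log10 decades over the graph radius
      dr <- d[root, ]
      mu <- pmax(mu_low, top * 10^(-slope * dr / maxd))
      mu[dr >= k] <- mu_low
      mean_rows[[sprintf("grad_%02d", i)]] <- mu
    }
    for (i in seq_len(n_noise)) {
      mean_rows[[sprintf("noise_%02d", i)]] <- rep(stats::runif(1, 5, 50), k)
    }
    mu_mat <- do.call(rbind, mean_rows)   # genes x modules
    lib <- stats::runif(n_cells, 1 - lib_jitter, 1 + lib_jitter)
    mu_cells <- mu_mat[, midx, drop = FALSE] * rep(lib, each = nrow(mu_mat))
    if (noise_sd > 0) {
      mu_cells <- mu_cells * exp(matrix(stats::rnorm(length(mu_cells), 0, noise_sd),
                                        nrow = nrow(mu_cells)))
    }
    counts <- if (dispersion > 0) {
      matrix(stats::rnbinom(length(mu_cells), mu = mu_cells, size = 1 / dispersion),
             nrow = nrow(mu_cells))
    } else {
      matrix(stats::rpois(length(mu_cells), mu_cells), nrow = nrow(mu_cells))
    }
    dimnames(counts) <- list(rownames(mu_mat),
                             sprintf("cell_%04d", seq_len(n_cells)))
    list(counts = counts,
         labels = stats::setNames(modules, colnames(counts)))
  })
  expr <- expression_matrix(log10(out$counts + 1),
                            domain_labels = out$labels, scale = "log10p1")
  structure(
    list(expr = expr, counts = out$counts, graph = graph,
         spec = list(kind = kind, n_cells = n_cells,
                     markers_per_module = markers_per_module,
                     n_gradient = n_gradient, n_noise = n_noise,
                     mu_high = mu_high, mu_low = mu_low,
                     marker_decay = marker_decay,
                     dispersion = dispersion, lib_jitter = lib_jitter,
                     noise_sd = noise_sd, seed = seed)),
    class = "backbone_sim"
  )
}

#' @export
print.backbone_sim <- function(x, ...) {
  cat(sprintf("backbone_sim: %s backbone, %d modules, %d genes x %d cells (seed %d)\n",
              x$spec$kind, length(x$graph$vertex_names),
              nrow(x$counts), ncol(x$counts), x$spec$seed))
  invisible(x)
}

#' Derive a cell-domain topology graph from expression data
#'
#' Standard single-cell preprocessing (variable-gene selection, per-gene
#' scaling, PCA, nearest-neighbor graph) followed by Louvain community
#' detection, with the resolution tuned so the cluster count falls in
#' `cluster_range`. Cluster centroids are then computed over all genes in
#' (unscaled) log-expression space and an edge is drawn between clusters
#' whose centroid Pearson correlation
#' reaches `threshold`. The resulting graph must satisfy the expected
#' connectivity (`connected` for single-component backbones, `disconnected`
#' otherwise); if not at the requested threshold, the band
#' \[0.70, 0.85\] is scanned for a satisfying one.
#'
#' @param expr an `expression_set` on a log scale.
#' @param cluster_range admissible cluster counts, e.g. `c(5, 7)`.
#' @param threshold centroid-correlation cutoff for drawing an edge
#'   (default 0.75; must lie in \[0.70, 0.85\]).
#' @param expect `"connected"` or `"disconnected"` consistency requirement.
#' @param n_var_genes,n_pcs,knn preprocessing sizes.
#' @param seed seed for the (stochastic) community detection.
#' @return List with `graph` (a [topology_graph] with vertices `D1`, `D2`,
#'   ...), `labels` (named cell -> vertex), `centroid_cor`, `threshold` and
#'   `resolution` actually used.
#' @export
derive_topology_graph <- function(expr, cluster_range, threshold = 0.75,
                                  expect = c("connected", "disconnected"),
                                  n_var_genes = 50L, n_pcs = 10L, knn = 15L,
                                  seed = 1L) {
  stopifnot(inherits(expr, "expression_set"))
  expect <- match.arg(expect)
  if (threshold < 0.70 || threshold > 0.85) {
    stop("threshold must lie within [0.70, 0.85]")
  }
  v <- expr$values
  vars <- apply(v, 1, stats::var)
  top <- names(sort(vars, decreasing = TRUE))[seq_len(min(n_var_genes, nrow(v)))]
  vz <- v[top, , drop = FALSE]
  vz <- (vz - rowMeans(vz)) / apply(vz, 1, stats::sd)
  vz <- vz[apply(vz, 1, function(r) all(is.finite(r))), , drop = FALSE]
  pcs <- stats::prcomp(t(vz), center = FALSE, scale. = FALSE)$x
  pcs <- pcs[, seq_len(min(n_pcs, ncol(pcs))), drop = FALSE]
  n <- nrow(pcs)
  dd <- as.matrix(stats::dist(pcs))
  diag(dd) <- Inf
  knn <- min(knn, n - 1L)
  nbr <- t(apply(dd, 1, function(row) order(row)[seq_len(knn)]))
  el <- cbind(rep(seq_len(n), each = knn), as.vector(t(nbr)))
  g <- igraph::simplify(igraph::graph_from_edgelist(el, directed = FALSE))
  res_grid <- c(seq(0.1, 2, by = 0.1), seq(2.5, 5, by = 0.5))
  pick <- with_seed(seed, function() {
    best <- NULL
    for (r in res_grid) {
      cl <- igraph::cluster_louvain(g, resolution = r)
      nc <- length(unique(igraph::membership(cl)))
      if (nc >= cluster_range[1] && nc <= cluster_range[2]) {
        return(list(membership = as.integer(igraph::membership(cl)),
                    resolution = r, n_clusters = nc))
      }
      if (is.null(best) ||
          min(abs(nc - cluster_range)) < min(abs(best$n_clusters - cluster_range))) {
        best <- list(membership = as.integer(igraph::membership(cl)),
                     resolution = r, n_clusters = nc)
      }
    }
    best
  })
  membership <- pick$membership
  kc <- length(unique(membership))
  # order clusters by size for stable naming
  sizes <- table(membership)
  relabel <- match(membership, as.integer(names(sort(sizes, decreasing = TRUE))))
  labels <- stats::setNames(paste0("D", relabel), expr$cell_ids)
  centroids <- vapply(seq_len(kc), function(cl) {
    rowMeans(v[, relabel == cl, drop = FALSE])
  }, numeric(nrow(v)))
  colnames(centroids) <- paste0("D", seq_len(kc))
  cors <- stats::cor(centroids)
  build <- function(th) {
    adj <- (cors >= th) * 1
    diag(adj) <- 0
    topology_graph(adj, colnames(centroids))
  }
  satisfies <- function(gr) {
    if (expect == "connected") gr$is_connected else !gr$is_connected
  }
  graph <- build(threshold)
  used <- threshold
  if (!satisfies(graph)) {
    band <- seq(0.70, 0.85, by = 0.01)
    band <- band[order(abs(band - threshold))]
    found <- FALSE
    for (th in band) {
      cand <- build(th)
      if (satisfies(cand)) {
        graph <- cand
        used <- th
        found <- TRUE
        break
      }
    }
    if (!found) {
      off <- sort(cors[upper.tri(cors)], decreasing = TRUE)
      stop(sprintf(paste0("no threshold in [0.70, 0.85] yields a %s graph; ",
                          "off-diagonal centroid correlations: %s"),
                   expect, paste(sprintf("%.3f", off), collapse = ", ")))
    }
  }
  list(graph = graph, labels = labels, centroid_cor = cors,
       threshold = used, resolution = pick$resolution)
}

#' Topology-misspecification experiment
#'
#' Randomizes the input topology graph at flip probability `p` (respecting
#' the backbone's connectivity class), runs the gene-set search `runs` times
#' against each randomized graph, and summarizes the per-graph maxima of
#' score, accuracy and ARI with 95% confidence intervals.
#'
#' @param expr `expression_set` (full data).
#' @param labels named cell -> vertex labels for the graph's vertex set.
#' @param graph the unmodified input [topology_graph].
#' @param p flip probability (e.g. 0.1, 0.2, 0.5).
#' @param constraint connectivity constraint for [randomize_topology]
#'   (`"connected"` or `"disconnected"`).
#' @param pool candidate gene pool for the search (precomputed).
#' @param n_graphs randomized graphs (default 10).
#' @param runs search runs per graph (default 3).
#' @param downsample cells per domain per run.
#' @param seed base seed.
#' @param ... search parameters forwarded to [replica_exchange_search].
#' @return List with `per_graph` (one row per randomized graph: max score /
#'   accuracy / ARI over runs) and `summary` (means with 95% CI half-widths).
#' @export
misspecification_experiment <- function(expr, labels, graph, p, constraint,
                                        pool, n_graphs = 10L, runs = 3L,
                                        downsample = 10L, seed = 1L, ...) {
  rows <- lapply(seq_len(n_graphs), function(gidx) {
    gseed <- (seed * 131L + gidx * 17L) %% 2147480009L
    rg <- randomize_topology(graph, p, constraint = constraint, seed = gseed)
    best <- c(score = -Inf, accuracy = -Inf, ari = -Inf)
    for (r in seq_len(runs)) {
      rseed <- (gseed + r * 7919L) %% 2147480009L
      cells <- downsample_cells(labels, size = downsample, seed = rseed)
      sub <- subset_expression(expr, cells = cells)
      sub$domain_labels <- labels[cells]
      rs <- replica_exchange_search(pool, sub, rg, seed = rseed, ...)
      best["score"] <- max(best["score"], rs$best_score)
      best["accuracy"] <- max(best["accuracy"], rs$best_accuracy)
      best["ari"] <- max(best["ari"], rs$best_ari)
    }
    data.frame(graph = gidx, p = p, max_score = best["score"],
               max_accuracy = best["accuracy"], max_ari = best["ari"],
               row.names = NULL)
  })
  per_graph <- do.call(rbind, rows)
  ci <- function(x) {
    if (length(x) < 2L) return(NA_real_)
    stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x))
  }
  summary <- data.frame(
    p = p, n_graphs = n_graphs,
    mean_max_score = mean(per_graph$max_score), ci_score = ci(per_graph$max_score),
    mean_max_accuracy = mean(per_graph$max_accuracy), ci_accuracy = ci(per_graph$max_accuracy),
    mean_max_ari = mean(per_graph$max_ari), ci_ari = ci(per_graph$max_ari))
  list(per_graph = per_graph, summary = summary)
}
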
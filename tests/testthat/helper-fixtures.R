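# Shared fixtures built in code.

path_graph <- function(n = 3L, names = paste0("P", seq_len(n))) {
  adj <- matrix(0, n, n)
  if (n > 1) for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1
  topology_graph(adj, names)
}

cycle_graph <- function(n = 4L, names = paste0("C", seq_len(n))) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    adj[i, j] <- adj[j, i] <- 1
  }
  topology_graph(adj, names)
}

complete_graph <- function(n = 3L, names = paste0("K", seq_len(n))) {
  adj <- matrix(1, n, n) - diag(n)
  topology_graph(adj, names)
}

# toy expression with one clean high marker per domain plus optional noise
# genes; cells named c1, c2, ...; domains assigned round-robin
toy_marker_expression <- function(graph, cells_per_domain = 4L,
                                  n_noise = 0L, noise_sd = 0.05, seed = 1L,
                                  high = 2, low = 0.1) {
  set.seed(seed)
  doms <- graph$vertex_names
  labels <- rep(doms, each = cells_per_domain)
  n <- length(labels)
  cells <- paste0("c", seq_len(n))
  names(labels) <- cells
  marker <- vapply(labels, function(d) ifelse(doms == d, high, low),
                   numeric(length(doms)))
  rownames(marker) <- paste0("mk_", doms)
  mat <- marker + matrix(rnorm(length(marker), 0, noise_sd), nrow(marker))
  if (n_noise > 0) {
    noise <- matrix(runif(n_noise * n, 0, high), n_noise,
                    dimnames = list(paste0("nz_", seq_len(n_noise)), cells))
    mat <- rbind(mat, noise)
  }
  colnames(mat) <- cells
  mat[mat < 0] <- 0
  expression_matrix(mat, domain_labels = labels, scale = "log10p1")
}

# independent O(n^2) reference for the pairwise adjacency accuracy
brute_force_accuracy <- function(true_domains, predicted, graph) {
  cells <- names(true_domains)
  predicted <- predicted[cells]
  n <- length(cells)
  hits <- 0L
  total <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a_true <- graph$adjacency[true_domains[i], true_domains[j]]
      a_pred <- graph$adjacency[predicted[i], predicted[j]]
      total <- total + 1L
      if (a_true == a_pred) hits <- hits + 1L
    }
  }
  hits / total
}

# independent pair-counting ARI (explicit loop over item pairs)
brute_force_ari <- function(x, y) {
  n <- length(x)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sx <- x[i] == x[j]
      sy <- y[i] == y[j]
      if (sx && sy) n11 <- n11 + 1
      else if (!sx && !sy) n00 <- n00 + 1
      else if (sx) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  max_idx <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_idx == expected) {
    return(if (n10 + n01 == 0) 1.0 else 0.0)
  }
  (n11 - expected) / (max_idx - expected)
}

# Floyd-Warshall oracle for shortest-path distances (sentinel = n vertices)
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (via in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, via] + d[via, j] < d[i, j]) d[i, j] <- d[i, via] + d[via, j]
      }
    }
  }
  d[is.infinite(d)] <- n
  dimnames(d) <- dimnames(adj)
  d
}
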
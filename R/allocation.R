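#' Annealing temperature schedule
#'
#' Exponential decay from 1.0 to 0.001 over the schedule:
#' `T_t = (0.001)^(t / total)` for step `t` in `0..total-1`.
#'
#' @param t 0-based step index.
#' @param total number of annealing steps.
#' @return Temperature(s) in (0.001, 1\].
#' @export
anneal_temperature <- function(t, total) {
  if (any(t < 0) || total <= 0) stop("invalid schedule indices")
  1.0 * (0.001 / 1.0)^(t / total)
}

#' Swap-pair selection probabilities
#'
#' Cluster pairs are selected for swapping with probability proportional to
#' `exp(z)^c`, where `z` standardizes the post-swap accuracies (population
#' standard deviation) and `c = sqrt(m / 2)` sharpens the preference as the
#' number of clusters `m` grows. A flat accuracy profile (zero SD) falls back
#' to uniform selection.
#'
#' @param post_swap_accuracies numeric vector, one entry per unordered
#'   cluster pair.
#' @param m number of clusters.
#' @return Probabilities summing to 1, in the order of the input.
#' @export
swap_selection_probabilities <- function(post_swap_accuracies, m) {
  if (m < 2) stop("need at least two clusters")
  x <- post_swap_accuracies
  if (length(x) < 1L) stop("no candidate pairs")
  softmax_standardized(x, sqrt(m / 2))
}

# shared standardized softmax used for swap-pair and gene-candidate selection
softmax_standardized <- function(x, cexp) {
  n <- length(x)
  if (n == 1L) return(1.0)
  mu <- mean(x)
  sd_pop <- sqrt(sum((x - mu)^2) / n)
  if (sd_pop == 0) return(rep(1 / n, n))
  z <- cexp * (x - mu) / sd_pop
  w <- exp(z - max(z))
  w / sum(w)
}

#' Simulated-annealing adoption probability
#'
#' Improving moves (`delta_f <= 0`) are always adopted; worsening moves are
#' adopted with probability `exp(-delta_f / T_t)`.
#'
#' @param delta_f objective difference before minus after (so positive means
#'   the move worsens the objective).
#' @param T_t current temperature, positive.
#' @return Adoption probability in (0, 1\].
#' @export
sa_adoption_probability <- function(delta_f, T_t) {
  if (any(T_t <= 0)) stop("temperature must be positive")
  ifelse(delta_f <= 0, 1.0, exp(-delta_f / T_t))
}

#' Optimize the cluster-to-vertex allocation
#'
#' Clusterings on unstructured topologies often have a high ARI but a low
#' adjacency accuracy: the cluster memberships are right, but the clusters
#' sit on the wrong vertices. This pass swaps whole clusters between vertices
#' by simulated annealing, leaving memberships (and hence the ARI) untouched.
#' Per step, the post-swap accuracy of every vertex pair is computed, a pair
#' is sampled by [swap_selection_probabilities], and the swap is adopted per
#' [sa_adoption_probability]. The best allocation seen is returned.
#'
#' @param result a `clustering_result` (see [clustering_result]).
#' @param graph the [topology_graph].
#' @param steps annealing steps (default 100).
#' @param seed optional seed.
#' @param centroids optional vertices-x-genes matrix swapped alongside the
#'   assignments.
#' @return A list with the re-allocated `result` (class `clustering_result`)
#'   and, when supplied, the correspondingly swapped `centroids`.
#' @export
optimize_allocation <- function(result, graph, steps = 100L, seed = NULL,
                                centroids = NULL) {
  stopifnot(inherits(result, "clustering_result"),
            inherits(graph, "topology_graph"))
  k <- length(graph$vertex_names)
  verts <- graph$vertex_names
  ct <- unclass(table(factor(result$true_domains[names(result$predicted)], levels = verts),
                      factor(result$predicted, levels = verts)))
  pairs <- which(upper.tri(diag(k)), arr.ind = TRUE)
  perm <- seq_len(k)      # perm[i]: vertex now hosting the cluster born on vertex i
  acc_for <- function(pm) accuracy_from_contingency(ct[, order(pm), drop = FALSE],
                                                    graph$adjacency)
  out <- with_seed(seed, function() {
    acc_cur <- acc_for(perm)
    best <- list(acc = acc_cur, perm = perm)
    if (k >= 2 && steps > 0) {
      for (t in seq_len(steps) - 1L) {
        accs <- vapply(seq_len(nrow(pairs)), function(q) {
          pm <- perm
          pm[pairs[q, ]] <- pm[rev(pairs[q, ])]
          acc_for(pm)
        }, numeric(1))
        probs <- swap_selection_probabilities(accs, k)
        sel <- sample.int(nrow(pairs), 1L, prob = probs)
        p_sa <- sa_adoption_probability(acc_cur - accs[sel],
                                        anneal_temperature(t, steps))
        if (p_sa >= 1 || stats::runif(1) < p_sa) {
          perm[pairs[sel, ]] <- perm[rev(pairs[sel, ])]
          acc_cur <- accs[sel]
          if (acc_cur > best$acc) best <- list(acc = acc_cur, perm = perm)
        }
      }
    }
    best
  })
  relabel <- stats::setNames(verts[out$perm], verts)
  predicted <- stats::setNames(relabel[result$predicted], names(result$predicted))
  new_result <- clustering_result(predicted, result$true_domains, graph,
                                  result$weight_a)
  if (!is.null(centroids)) {
    centroids <- centroids[order(match(relabel[verts], verts)), , drop = FALSE]
    rownames(centroids) <- verts
  }
  list(result = new_result, centroids = centroids)
}
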
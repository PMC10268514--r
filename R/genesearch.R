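#' Boruta-style feature gene preselection
#'
#' Iteratively compares each gene's random-forest importance for classifying
#' the domain labels against "shadow" features (per-gene permutations of the
#' same data). A gene scoring above the best shadow counts a hit; after each
#' iteration a binomial test against chance (p = 0.5) confirms genes with
#' significantly many hits and rejects genes with significantly few. The
#' candidate pool for the gene-set search is the union of confirmed and
#' still-tentative genes.
#'
#' @param expr an `expression_set`; its `domain_labels` (or `domain_labels`
#'   argument) provide the response.
#' @param domain_labels optional named cell -> domain vector overriding the
#'   labels stored on `expr`.
#' @param genes genes to consider (default: all; normally the output of
#'   [prefilter_genes]).
#' @param max_runs maximum shadow iterations (default 30).
#' @param p_threshold significance level of the binomial decisions.
#' @param num_trees random-forest size per iteration.
#' @param seed optional seed (caller's stream preserved).
#' @return List with `pool` (confirmed + tentative gene ids) and `status`
#'   (named factor: confirmed / tentative / rejected).
#' @export
preselect_features <- function(expr, domain_labels = NULL, genes = NULL,
                               max_runs = 30L, p_threshold = 0.01,
                               num_trees = 300L, seed = NULL) {
  stopifnot(inherits(expr, "expression_set"))
  labels <- if (is.null(domain_labels)) expr$domain_labels else domain_labels
  if (is.null(labels)) stop("domain labels required for feature preselection")
  if (is.null(genes)) genes <- expr$gene_ids
  labels <- labels[expr$cell_ids]
  if (length(unique(labels)) < 2L) stop("need at least two domains")
  x <- t(expr$values[genes, , drop = FALSE])
  y <- factor(labels)
  status <- stats::setNames(rep("tentative", length(genes)), genes)
  hits <- stats::setNames(integer(length(genes)), genes)
  with_seed(seed, function() {
    for (run in seq_len(max_runs)) {
      active <- names(status)[status != "rejected"]
      if (!length(active)) break
      xa <- x[, active, drop = FALSE]
      shadows <- apply(xa, 2, sample)
      colnames(shadows) <- paste0(".shadow.", seq_len(ncol(shadows)))
      fit <- ranger::ranger(x = cbind(xa, shadows), y = y,
                            num.trees = num_trees, importance = "impurity",
                            num.threads = 1L,
                            seed = sample.int(.Machine$integer.max, 1L))
      imp <- fit$variable.importance
      shadow_max <- max(imp[colnames(shadows)])
      hits[active] <<- hits[active] + (imp[active] > shadow_max)
      tent <- names(status)[status == "tentative"]
      p_more <- stats::pbinom(hits[tent] - 1L, run, 0.5, lower.tail = FALSE)
      p_less <- stats::pbinom(hits[tent], run, 0.5)
      status[tent[p_more < p_threshold]] <<- "confirmed"
      status[tent[p_less < p_threshold]] <<- "rejected"
      if (!any(status == "tentative")) break
    }
  })
  pool <- names(status)[status != "rejected"]
  if (!length(pool)) {
    stop("all genes rejected by feature preselection")
  }
  list(pool = pool,
       status = factor(status, levels = c("confirmed", "tentative", "rejected")))
}

# order-independent registry key of a gene set
set_key <- function(genes) paste(sort(genes), collapse = "\x1f")

#' Propose neighboring gene sets
#'
#' All single-gene additions from `pool \ current` and all single-gene
#' removals from `current` (removals to the empty set excluded), minus any
#' set already in the registry. If that leaves nothing, a single random
#' swap replacement (one gene of `current` exchanged for one outside gene)
#' is generated instead.
#'
#' @param current current non-empty gene set.
#' @param pool the candidate pool.
#' @param registry previously evaluated sets: an environment keyed by
#'   sorted-set key (as used internally) or a character vector of such keys;
#'   `NULL` for none.
#' @return List of candidate gene sets (character vectors).
#' @export
propose_candidates <- function(current, pool, registry = NULL) {
  if (!length(current)) stop("current gene set is empty")
  additions <- lapply(setdiff(pool, current), function(g) c(current, g))
  removals <- if (length(current) >= 2L) {
    lapply(seq_along(current), function(i) current[-i])
  } else list()
  cands <- c(additions, removals)
  if (!is.null(registry)) {
    seen <- if (is.environment(registry)) {
      function(key) !is.null(registry[[key]])
    } else {
      function(key) key %in% registry
    }
    cands <- Filter(function(s) !seen(set_key(s)), cands)
  }
  if (!length(cands)) {
    outside <- setdiff(pool, current)
    if (!length(outside)) stop("pool exhausted: no replacement gene available")
    # swap replacement; prefer a set not yet sampled
    for (try in 1:20) {
      g_j <- if (length(current) == 1L) current else sample(current, 1L)
      g_k <- if (length(outside) == 1L) outside else sample(outside, 1L)
      cand <- c(setdiff(current, g_j), g_k)
      if (is.null(registry) || try == 20L || !seen(set_key(cand))) break
    }
    cands <- list(cand)
  }
  cands
}

#' Candidate selection probabilities
#'
#' Standardized softmax over candidate scores with exponent
#' `c = sqrt(N / 2)` for `N` candidates; equal scores give uniform
#' probabilities.
#'
#' @param scores numeric vector of clustering scores, one per candidate.
#' @return Probabilities summing to 1.
#' @export
candidate_selection_probabilities <- function(scores) {
  if (!length(scores)) stop("no candidates")
  softmax_standardized(scores, sqrt(length(scores) / 2))
}

#' Replica-exchange swap probability
#'
#' `p = min(1, exp((E_i - E_j) * (1 / T_i - 1 / T_j)))` for replicas `i`
#' and `j` with energies `E` and temperatures `T`.
#'
#' @param E_i,E_j replica energies (here the negated clustering score).
#' @param T_i,T_j replica temperatures, positive.
#' @return Exchange probability in \[0, 1\].
#' @export
replica_exchange_probability <- function(E_i, E_j, T_i, T_j) {
  if (any(c(T_i, T_j) <= 0)) stop("temperatures must be positive")
  pmin(1, exp((E_i - E_j) * (1 / T_i - 1 / T_j)))
}

# deterministic per-evaluation fit seed below 2^31
fit_seed_for <- function(seed, chain_id, step, idx) {
  base <- if (is.null(seed)) 0 else as.double(seed)
  as.integer((base * 2654435761 + chain_id * 97 + step * 131071 + idx * 8191) %%
               2147483629) + 1L
}

# evaluation context shared by all chains of one search
search_context <- function(expr, graph, pool, som_steps, sigma0, sigma_final,
                           alloc_steps, weight_a) {
  if (is.null(expr$domain_labels)) stop("expression set has no domain labels")
  bad <- setdiff(unique(expr$domain_labels), graph$vertex_names)
  if (length(bad)) stop("domain labels not in graph: ", paste(bad, collapse = ", "))
  missing <- setdiff(pool, expr$gene_ids)
  if (length(missing)) stop("pool genes absent from expression: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  if (is.null(sigma0)) sigma0 <- default_sigma0(graph)
  list(xt = t(expr$values[pool, , drop = FALSE]),
       cells = expr$cell_ids,
       true_idx = match(expr$domain_labels[expr$cell_ids], graph$vertex_names) - 1L,
       graph = graph, pool = pool,
       som_steps = as.integer(som_steps), sigma0 = sigma0,
       sigma_final = sigma_final, alloc_steps = as.integer(alloc_steps),
       weight_a = weight_a)
}

eval_subset <- function(ctx, genes, fit_seed) {
  with_seed(fit_seed, function() {
    gsom_fit_cpp(ctx$xt[, genes, drop = FALSE], ctx$graph$distances,
                 ctx$graph$adjacency, ctx$true_idx, ctx$som_steps,
                 ctx$sigma0, ctx$sigma_final, ctx$alloc_steps,
                 ctx$weight_a, NA_real_, NULL)
  })
}

chain_new <- function(ctx, n_init, chain_id, seed) {
  n_init <- min(n_init, length(ctx$pool))
  current <- if (length(ctx$pool) == 1L) ctx$pool else sample(ctx$pool, n_init)
  chain <- list(id = chain_id, current = current, cur_score = -Inf,
                best_set = character(), best_score = -Inf,
                best_accuracy = -Inf, best_ari = -Inf, best_assignment = NULL,
                registry = new.env(parent = emptyenv()), n_eval = 0L)
  fit <- eval_subset(ctx, current, fit_seed_for(seed, chain_id, 0L, 1L))
  chain$registry[[set_key(current)]] <- TRUE
  chain$n_eval <- 1L
  chain$cur_score <- fit$score
  chain$best_set <- current
  chain$best_score <- fit$score
  chain$best_accuracy <- fit$accuracy
  chain$best_ari <- fit$ari
  chain$best_assignment <- stats::setNames(ctx$graph$vertex_names[fit$assignment],
                                           ctx$cells)
  chain
}

chain_step <- function(chain, ctx, step, total_steps, seed, max_candidates) {
  cands <- propose_candidates(chain$current, ctx$pool, chain$registry)
  if (!is.null(max_candidates) && length(cands) > max_candidates) {
    cands <- cands[sample.int(length(cands), max_candidates)]
  }
  scores <- numeric(length(cands))
  s_prev <- chain$best_score
  for (i in seq_along(cands)) {
    fit <- eval_subset(ctx, cands[[i]], fit_seed_for(seed, chain$id, step, i))
    chain$registry[[set_key(cands[[i]])]] <- TRUE
    chain$n_eval <- chain$n_eval + 1L
    scores[i] <- fit$score
    if (fit$score > chain$best_score) {
      chain$best_score <- fit$score
      chain$best_set <- cands[[i]]
      chain$best_assignment <- stats::setNames(
        ctx$graph$vertex_names[fit$assignment], ctx$cells)
    }
    chain$best_accuracy <- max(chain$best_accuracy, fit$accuracy)
    chain$best_ari <- max(chain$best_ari, fit$ari)
  }
  probs <- candidate_selection_probabilities(scores)
  x <- if (length(cands) == 1L) 1L else sample.int(length(cands), 1L, prob = probs)
  delta_f <- -(scores[x] - s_prev)
  p_sa <- sa_adoption_probability(delta_f, anneal_temperature(step - 1L, total_steps))
  adopted <- p_sa >= 1 || stats::runif(1) < p_sa
  if (adopted) {
    chain$current <- cands[[x]]
    chain$cur_score <- scores[x]
  }
  chain$last <- list(step = step, n_candidates = length(cands),
                     selected_score = scores[x], adopted = adopted)
  chain
}

#' Single-chain MCMC gene-set search
#'
#' Runs the sampling scheme of one replica: start from a uniform random
#' subset of size `n_init`, and per step propose all unseen single-gene
#' additions/removals, score each candidate with a full graph-SOM fit (plus
#' allocation optimization), select one by standardized softmax, and adopt or
#' reject it by the simulated-annealing rule with
#' `delta_f = -(s_candidate - s_best)`. The best-scoring set over all
#' evaluations is tracked and returned.
#'
#' @param pool candidate gene ids (normally from [preselect_features]).
#' @param expr `expression_set` with domain labels.
#' @param graph the [topology_graph].
#' @param steps MCMC steps (default 1000).
#' @param n_init initial subset size (default 10).
#' @param som_steps,sigma0,sigma_final,alloc_steps,weight_a fit parameters
#'   passed to each candidate evaluation (see [gsom_fit]).
#' @param max_candidates cap on scored candidates per step (uniform
#'   subsample); `NULL` disables the cap.
#' @param seed integer seed; the search is fully reproducible.
#' @return Object of class `gene_search` (fields `best_set`, `best_score`,
#'   `best_accuracy`, `best_ari`, `best_assignment`, `trace`, ...).
#' @export
mcmc_run <- function(pool, expr, graph, steps = 1000L, n_init = 10L,
                     som_steps = 50L, sigma0 = NULL, sigma_final = 0.3,
                     alloc_steps = 50L, weight_a = 1.0,
                     max_candidates = NULL, seed = NULL) {
  replica_exchange_search(pool, expr, graph, replicas = 1L, steps = steps,
                          n_init = n_init, som_steps = som_steps,
                          sigma0 = sigma0, sigma_final = sigma_final,
                          alloc_steps = alloc_steps, weight_a = weight_a,
                          max_candidates = max_candidates, seed = seed)
}

#' Replica-exchange MCMC gene-set search
#'
#' Runs `replicas` parallel chains (see [mcmc_run]) on a geometric
#' temperature ladder. Every `exchange_interval` steps, adjacent-temperature
#' replica pairs (alternating even/odd pairing) attempt to exchange their
#' current gene sets with probability [replica_exchange_probability], using
#' the negated clustering score as the energy, so high-scoring sets migrate
#' toward cold replicas. The global best over all replicas is returned.
#'
#' @inheritParams mcmc_run
#' @param replicas number of parallel chains (default 8).
#' @param ladder replica temperatures (cold to hot); default geometric from
#'   0.005 to 0.5.
#' @param exchange_interval steps between exchange attempts (default 10).
#' @return Object of class `gene_search`: global `best_set`, `best_score`,
#'   `best_accuracy`, `best_ari`, `best_assignment`, per-replica summaries in
#'   `replicas`, a step `trace` data frame, `pool`, and `seed`.
#' @export
replica_exchange_search <- function(pool, expr, graph, replicas = 8L,
                                    steps = 1000L, n_init = 10L,
                                    ladder = NULL, exchange_interval = 10L,
                                    som_steps = 50L, sigma0 = NULL,
                                    sigma_final = 0.3, alloc_steps = 50L,
                                    weight_a = 1.0, max_candidates = NULL,
                                    seed = NULL) {
  if (replicas < 1L) stop("need at least one replica")
  if (!length(pool)) stop("empty gene pool")
  ctx <- search_context(expr, graph, pool, som_steps, sigma0, sigma_final,
                        alloc_steps, weight_a)
  if (is.null(ladder)) {
    ladder <- if (replicas == 1L) 0.005 else
      0.005 * (0.5 / 0.005)^((seq_len(replicas) - 1) / (replicas - 1))
  }
  if (length(ladder) != replicas) stop("ladder length must equal replicas")
  run <- with_seed(seed, function() {
    trace_rows <- vector("list", replicas * steps)
    chains <- lapply(seq_len(replicas), function(r) chain_new(ctx, n_init, r, seed))
    exchange_count <- 0L
    for (step in seq_len(steps)) {
      for (r in seq_len(replicas)) {
        chains[[r]] <- chain_step(chains[[r]], ctx, step, steps, seed,
                                  max_candidates)
        trace_rows[[(step - 1L) * replicas + r]] <- data.frame(
          step = step, replica = r,
          n_candidates = chains[[r]]$last$n_candidates,
          selected_score = chains[[r]]$last$selected_score,
          adopted = chains[[r]]$last$adopted,
          current_score = chains[[r]]$cur_score,
          best_score = chains[[r]]$best_score)
      }
      if (replicas > 1L && step %% exchange_interval == 0L) {
        exchange_count <- exchange_count + 1L
        start <- if (exchange_count %% 2L == 1L) 1L else 2L
        r <- start
        while (r + 1L <= replicas) {
          p <- replica_exchange_probability(-chains[[r]]$cur_score,
                                            -chains[[r + 1L]]$cur_score,
                                            ladder[r], ladder[r + 1L])
          if (p >= 1 || stats::runif(1) < p) {
            tmp_set <- chains[[r]]$current
            tmp_score <- chains[[r]]$cur_score
            chains[[r]]$current <- chains[[r + 1L]]$current
            chains[[r]]$cur_score <- chains[[r + 1L]]$cur_score
            chains[[r + 1L]]$current <- tmp_set
            chains[[r + 1L]]$cur_score <- tmp_score
          }
          r <- r + 2L
        }
      }
    }
    list(chains = chains, trace_rows = trace_rows)
  })
  chains <- run$chains
  trace_rows <- run$trace_rows
  best_r <- which.max(vapply(chains, `[[`, numeric(1), "best_score"))
  best <- chains[[best_r]]
  structure(
    list(best_set = sort(best$best_set),
         best_score = best$best_score,
         best_accuracy = max(vapply(chains, `[[`, numeric(1), "best_accuracy")),
         best_ari = max(vapply(chains, `[[`, numeric(1), "best_ari")),
         best_assignment = best$best_assignment,
         replicas = lapply(chains, function(ch) {
           list(id = ch$id, best_set = sort(ch$best_set),
                best_score = ch$best_score, best_accuracy = ch$best_accuracy,
                best_ari = ch$best_ari, n_evaluations = ch$n_eval,
                n_unique_sets = length(ls(ch$registry, all.names = TRUE)))
         }),
         trace = do.call(rbind, trace_rows),
         pool = pool, ladder = ladder, seed = seed),
    class = "gene_search"
  )
}

#' @export
print.gene_search <- function(x, ...) {
  cat(sprintf("gene_search: best score %.4f with %d genes (%d replicas, %d evaluations)\n",
              x$best_score, length(x$best_set), length(x$replicas),
              sum(vapply(x$replicas, `[[`, integer(1), "n_evaluations"))))
  invisible(x)
}
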
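#' Pipeline configuration
#'
#' Collects all tunable parameters with their defaults: the SOM learning
#' schedule, allocation annealing, MCMC search budget, ensemble settings and
#' the mandatory seed. Any subset can be overridden.
#'
#' @param ... named overrides of the defaults listed below.
#' @return A validated named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    transform = "none",       # none | log10p1 | cpm_log10p1
    min_value = 1.0,          # prefilter: expression threshold
    min_cells = 2L,           # prefilter: cells above threshold
    min_sd = 0.05,            # prefilter: SD threshold
    boruta_max_runs = 30L,    # feature preselection iterations
    boruta_trees = 300L,
    som_steps = 50L,          # batch updates per candidate fit
    sigma_final = 0.3,
    alloc_steps = 50L,        # allocation annealing steps per fit
    weight_a = 1.0,           # ARI weight in the score
    steps = 1000L,            # MCMC steps per replica
    replicas = 8L,
    n_init = 10L,             # initial gene-subset size
    exchange_interval = 10L,
    max_candidates = NULL,    # cap on scored candidates per step
    runs = 10L,               # ensemble runs
    downsample = 10L,         # cells per domain per run
    consensus_min = 3L,       # minimum run count for consensus genes
    final_som_steps = 200L,   # final full-data fit
    final_alloc_steps = 100L,
    seed = NULL
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  num_keys <- c("min_value", "min_cells", "min_sd", "boruta_max_runs",
                "boruta_trees", "som_steps", "sigma_final", "alloc_steps",
                "steps", "replicas", "n_init", "exchange_interval", "runs",
                "downsample", "consensus_min", "final_som_steps")
  for (key in num_keys) {
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L || cfg[[key]] <= 0) {
      stop("config key '", key, "' must be a positive number")
    }
  }
  if (cfg$weight_a < 0) stop("weight_a must be non-negative")
  structure(cfg, class = c("run_config", "list"))
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values are parsed
#' as numbers where possible. Keys must match [run_config] keys.
#'
#' @param path file path.
#' @return Named list of overrides, to splice into [run_config].
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Run the full topological-clustering pipeline
#'
#' Prefilters genes, preselects a candidate pool by the Boruta-style shadow
#' procedure, then performs `runs` independent replica-exchange searches,
#' each on a fresh per-domain downsample of the cells. Best gene sets and
#' evaluation maxima are collected per run; genes recurring in at least
#' `consensus_min` runs form the consensus discriminator set, on which a
#' final full-data clustering is fit.
#'
#' @param expr `expression_set` with domain labels (or `labels` supplied).
#' @param graph the input [topology_graph].
#' @param config a [run_config]; `config$seed` is mandatory.
#' @param labels optional named cell -> domain vector overriding the labels
#'   on `expr`.
#' @return Object of class `pipeline_result`: `pool`, `feature_status`,
#'   `ensemble` (class `run_ensemble`), `consensus`, `final_fit`, `config`.
#' @export
run_pipeline <- function(expr, graph, config = run_config(), labels = NULL) {
  stopifnot(inherits(expr, "expression_set"), inherits(graph, "topology_graph"))
  if (is.null(config$seed)) stop("config$seed is mandatory for a pipeline run")
  if (!is.null(labels)) {
    expr <- expression_matrix(expr$values, domain_labels = labels,
                              scale = expr$scale)
  }
  if (is.null(expr$domain_labels)) stop("domain labels are required")
  seed <- as.integer(config$seed)
  if (config$consensus_min > config$runs) {
    warning("consensus_min exceeds the number of runs; ",
            "the consensus gene set will be empty")
  }

  kept <- prefilter_genes(expr, config$min_value, config$min_cells, config$min_sd)
  message(sprintf("prefilter: %d of %d genes kept", length(kept),
                  length(expr$gene_ids)))
  sel <- preselect_features(expr, genes = kept,
                            max_runs = config$boruta_max_runs,
                            num_trees = config$boruta_trees,
                            seed = seed)
  message(sprintf("feature preselection (seed %d): pool of %d genes", seed,
                  length(sel$pool)))
  runs <- lapply(seq_len(config$runs), function(r) {
    run_seed <- (seed + r * 7919L) %% 2147480009L
    message(sprintf("search run %d/%d (seed %d)", r, config$runs, run_seed))
    cells <- downsample_cells(expr$domain_labels, size = config$downsample,
                              seed = run_seed)
    sub <- subset_expression(expr, cells = cells)
    rs <- replica_exchange_search(
      sel$pool, sub, graph,
      replicas = config$replicas, steps = config$steps,
      n_init = config$n_init, exchange_interval = config$exchange_interval,
      som_steps = config$som_steps, sigma_final = config$sigma_final,
      alloc_steps = config$alloc_steps, weight_a = config$weight_a,
      max_candidates = config$max_candidates, seed = run_seed)
    list(run = r, seed = run_seed, cells = cells,
         best_set = rs$best_set, best_score = rs$best_score,
         best_accuracy = rs$best_accuracy, best_ari = rs$best_ari,
         best_assignment = rs$best_assignment)
  })
  freq <- table(unlist(lapply(runs, function(x) unique(x$best_set))))
  ensemble <- structure(
    list(runs = runs,
         downsample_size = config$downsample,
         gene_frequencies = stats::setNames(as.integer(freq), names(freq)),
         summary = data.frame(
           runs = length(runs),
           avg_max_score = mean(vapply(runs, `[[`, numeric(1), "best_score")),
           avg_max_accuracy = mean(vapply(runs, `[[`, numeric(1), "best_accuracy")),
           avg_max_ari = mean(vapply(runs, `[[`, numeric(1), "best_ari")))),
    class = "run_ensemble")
  consensus <- consensus_genes(lapply(runs, `[[`, "best_set"),
                               min_count = config$consensus_min)
  final_fit <- NULL
  if (length(consensus)) {
    final_fit <- gsom_fit(expr, graph, genes = consensus,
                          som_steps = config$final_som_steps,
                          alloc_steps = config$final_alloc_steps,
                          sigma_final = config$sigma_final,
                          weight_a = config$weight_a, seed = seed)
  }
  structure(
    list(pool = sel$pool, feature_status = sel$status, ensemble = ensemble,
         consensus = consensus, final_fit = final_fit, config = config),
    class = "pipeline_result"
  )
}

#' @export
print.run_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf("run_ensemble: %d runs; avg max score %.3f (accuracy %.3f, ARI %.3f)\n",
              s$runs, s$avg_max_score, s$avg_max_accuracy, s$avg_max_ari))
  invisible(x)
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$ensemble)
  cat(sprintf("pool: %d genes; consensus: %d genes\n",
              length(x$pool), length(x$consensus)))
  if (!is.null(x$final_fit)) {
    cat("final full-data fit: ")
    print(x$final_fit)
  }
  invisible(x)
}

#' Write pipeline results to a directory
#'
#' Emits `results.json` (config echo, per-run maxima, ensemble averages,
#' consensus genes, final-fit scores), `consensus_genes.txt`,
#' `assignment.csv` (final full-data cell -> vertex assignment) and
#' `run_sets.csv` (per-run best gene sets).
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  runs <- result$ensemble$runs
  payload <- list(
    config = result$config[!vapply(result$config, is.null, logical(1))],
    runs = lapply(runs, function(r) {
      list(run = r$run, seed = r$seed, n_cells = length(r$cells),
           best_score = r$best_score, best_accuracy = r$best_accuracy,
           best_ari = r$best_ari, best_set = as.list(r$best_set))
    }),
    averages = as.list(result$ensemble$summary),
    consensus = as.list(result$consensus))
  if (!is.null(result$final_fit)) {
    payload$final_fit <- list(score = result$final_fit$score,
                              accuracy = result$final_fit$accuracy,
                              ari = result$final_fit$ari)
  }
  jsonlite::write_json(payload, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(result$consensus, file.path(dir, "consensus_genes.txt"))
  sets <- do.call(rbind, lapply(runs, function(r) {
    data.frame(run = r$run, gene = r$best_set)
  }))
  utils::write.csv(sets, file.path(dir, "run_sets.csv"), row.names = FALSE)
  if (!is.null(result$final_fit)) {
    utils::write.csv(
      data.frame(cell_id = names(result$final_fit$predicted),
                 vertex = unname(result$final_fit$predicted),
                 true_domain = unname(result$final_fit$true_domains[
                   names(result$final_fit$predicted)])),
      file.path(dir, "assignment.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Score an existing assignment against a topology graph
#'
#' @param predicted,true_domains named cell -> vertex/domain vectors.
#' @param graph the [topology_graph].
#' @param weight_a ARI weight.
#' @return A `clustering_result`.
#' @export
score_assignment <- function(predicted, true_domains, graph, weight_a = 1.0) {
  clustering_result(predicted, true_domains, graph, weight_a)
}
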
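#' Downsample cells per domain
#'
#' Uniformly samples without replacement up to `size` cells from each domain
#' (all cells when a domain has fewer). Used to keep repeated search runs
#' cheap and to balance domain sizes.
#'
#' @param labels named cell -> domain vector.
#' @param size cells kept per domain (default 10).
#' @param seed optional seed (caller's stream preserved).
#' @return Character vector of kept cell ids (original order).
#' @export
downsample_cells <- function(labels, size = 10L, seed = NULL) {
  if (is.null(names(labels))) stop("labels must be named by cell id")
  domains <- split(names(labels), labels)
  if (any(lengths(domains) == 0L)) stop("empty domain")
  kept <- with_seed(seed, function() {
    unlist(lapply(domains, function(cells) {
      if (length(cells) <= size) cells
      else sample(cells, size)
    }), use.names = FALSE)
  })
  names(labels)[names(labels) %in% kept]
}

#' Consensus discriminator genes over repeated runs
#'
#' Genes selected in at least `min_count` of the runs' best sets, sorted by
#' frequency (ties by name). Repeating the stochastic search and keeping only
#' recurrent genes guards against single-run artifacts.
#'
#' @param run_sets list of character vectors (one best gene set per run), or
#'   a `run_ensemble` object from [run_pipeline].
#' @param min_count minimum number of runs containing the gene (default 3).
#' @return Character vector of consensus gene ids.
#' @export
consensus_genes <- function(run_sets, min_count = 3L) {
  if (inherits(run_sets, "run_ensemble")) {
    run_sets <- lapply(run_sets$runs, `[[`, "best_set")
  }
  if (!length(run_sets)) stop("need at least one run")
  freq <- table(unlist(lapply(run_sets, unique)))
  freq <- freq[freq >= min_count]
  if (!length(freq)) return(character())
  ord <- order(-as.integer(freq), names(freq))
  names(freq)[ord]
}

#' Virtual knockout ranking
#'
#' For each knockout set (plus the no-knockout baseline), removes the genes
#' from the consensus gene set and re-runs graph-SOM clustering `runs` times
#' with distinct seeds (the same seeds for every knockout, so rows are
#' paired). Knockouts are ranked by ascending mean score: the larger the drop
#' against the baseline, the more the removed genes carry the topology.
#'
#' @param expr `expression_set` with domain labels.
#' @param graph the [topology_graph].
#' @param consensus consensus gene set used as the baseline.
#' @param knockouts named list of character vectors to remove; a `noKO`
#'   baseline row is always added.
#' @param runs clustering repetitions per knockout (default 100).
#' @param seed base seed; run `r` uses `seed + r`.
#' @param ... fit parameters forwarded to [gsom_fit] (e.g. `som_steps`).
#' @return `data.frame` with one row per knockout: mean/max of score,
#'   accuracy and ARI, ordered by ascending mean score.
#' @export
virtual_knockout <- function(expr, graph, consensus, knockouts, runs = 100L,
                             seed = 1L, ...) {
  stopifnot(inherits(expr, "expression_set"))
  if (!length(consensus)) stop("empty consensus gene set")
  if (is.null(names(knockouts)) || any(!nzchar(names(knockouts)))) {
    stop("knockouts must be a named list")
  }
  outside <- setdiff(unique(unlist(knockouts)), consensus)
  if (length(outside)) {
    warning("knockout genes not in the consensus set: ",
            paste(outside, collapse = ", "))
  }
  sets <- c(list(noKO = character()), knockouts)
  rows <- lapply(names(sets), function(nm) {
    genes <- setdiff(consensus, sets[[nm]])
    if (!length(genes)) stop("knockout '", nm, "' removes all consensus genes")
    fits <- lapply(seq_len(runs), function(r) {
      gsom_fit(expr, graph, genes = genes, seed = seed + r, ...)
    })
    score <- vapply(fits, `[[`, numeric(1), "score")
    acc <- vapply(fits, `[[`, numeric(1), "accuracy")
    ari <- vapply(fits, `[[`, numeric(1), "ari")
    data.frame(knockout = nm, n_genes = length(genes),
               mean_score = mean(score), max_score = max(score),
               mean_accuracy = mean(acc), max_accuracy = max(acc),
               mean_ari = mean(ari), max_ari = max(ari))
  })
  out <- do.call(rbind, rows)
  out[order(out$mean_score, out$knockout), , drop = FALSE]
}

#' Hypergeometric term enrichment
#'
#' For each annotation term, the upper-tail hypergeometric probability of
#' observing at least the overlap between the gene set and the term's genes,
#' drawing `|set|` genes from the universe. Terms with no annotated gene in
#' the universe are skipped with a message. Raw p-values are reported (with a
#' Benjamini-Hochberg column for convenience).
#'
#' @param genes the gene set (must be contained in `universe`).
#' @param annotation data frame with columns `gene` and `term` (extra
#'   columns such as `term_name` are carried through).
#' @param universe background gene ids; defaults to all annotated genes.
#' @return `data.frame` with term, annotated count, overlap, p_value and
#'   p_adjust (BH), sorted by p_value.
#' @export
hypergeometric_enrichment <- function(genes, annotation, universe = NULL) {
  if (!all(c("gene", "term") %in% colnames(annotation))) {
    stop("annotation needs 'gene' and 'term' columns")
  }
  if (is.null(universe)) universe <- unique(annotation$gene)
  outside <- setdiff(genes, universe)
  if (length(outside)) {
    stop("gene set not contained in universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  annotation <- annotation[annotation$gene %in% universe, , drop = FALSE]
  N <- length(universe)
  n_draw <- length(unique(genes))
  terms <- split(annotation$gene, annotation$term)
  rows <- lapply(names(terms), function(tm) {
    ann <- unique(terms[[tm]])
    K <- length(ann)
    if (K == 0L) {
      message("term with zero annotated genes skipped: ", tm)
      return(NULL)
    }
    q <- length(intersect(genes, ann))
    p <- stats::phyper(q - 1, K, N - K, n_draw, lower.tail = FALSE)
    data.frame(term = tm, annotated = K, overlap = q, p_value = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) {
    return(data.frame(term = character(), annotated = integer(),
                      overlap = integer(), p_value = numeric(),
                      p_adjust = numeric()))
  }
  if ("term_name" %in% colnames(annotation)) {
    nm <- annotation[!duplicated(annotation$term), c("term", "term_name")]
    out$term_name <- nm$term_name[match(out$term, nm$term)]
  }
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Load a gene -> term annotation table
#'
#' @param path two-column TSV `gene_id<TAB>term_id` (optional third column:
#'   term name), header optional.
#' @return `data.frame` with columns gene, term (and term_name when present).
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(gene = character(), term = character()))
  }
  tab <- utils::read.delim(text = lines, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) && identical(tolower(unlist(tab[1, 1:2], use.names = FALSE)),
                             c("gene_id", "term_id"))) {
    tab <- tab[-1, , drop = FALSE]
  }
  if (ncol(tab) < 2L) stop("annotation file must have two columns")
  out <- data.frame(gene = tab[[1]], term = tab[[2]])
  if (ncol(tab) >= 3L) out$term_name <- tab[[3]]
  out
}
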
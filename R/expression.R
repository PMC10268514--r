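#' Expression matrix container
#'
#' A light container for a genes-by-cells expression matrix on a declared
#' value scale, with optional per-cell domain labels. Values must be complete
#' (no `NA`) and identifiers unique.
#'
#' @param values numeric matrix, genes in rows, cells in columns.
#' @param gene_ids,cell_ids identifiers; default to the dimnames.
#' @param domain_labels optional named character vector (names = cell ids)
#'   giving the true domain of each cell.
#' @param scale declared value scale, e.g. `"log10p1"` after
#'   `log10(x + 1)` transformation, `"cpm_log10p1"`, or `"counts"`.
#' @return Object of class `expression_set`.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              domain_labels = NULL,
                              scale = "log10p1") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene and cell identifiers are required")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids")
  if (anyNA(values)) stop("expression matrix contains missing values")
  dimnames(values) <- list(gene_ids, cell_ids)
  if (!is.null(domain_labels)) {
    domain_labels <- domain_labels[cell_ids]
    if (anyNA(domain_labels)) {
      stop("domain labels missing for some cells")
    }
    names(domain_labels) <- cell_ids
  }
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         domain_labels = domain_labels, scale = scale),
    class = "expression_set"
  )
}

#' @export
print.expression_set <- function(x, ...) {
  cat(sprintf("expression_set: %d genes x %d cells (scale: %s)%s\n",
              length(x$gene_ids), length(x$cell_ids), x$scale,
              if (is.null(x$domain_labels)) "" else
                sprintf(", %d domains", length(unique(x$domain_labels)))))
  invisible(x)
}

#' Subset an expression set
#'
#' @param expr an `expression_set`.
#' @param genes,cells character vectors of identifiers (or NULL to keep all).
#' @return A new `expression_set`.
#' @export
subset_expression <- function(expr, genes = NULL, cells = NULL) {
  stopifnot(inherits(expr, "expression_set"))
  genes <- if (is.null(genes)) expr$gene_ids else as.character(genes)
  cells <- if (is.null(cells)) expr$cell_ids else as.character(cells)
  missing_g <- setdiff(genes, expr$gene_ids)
  if (length(missing_g)) stop("unknown genes: ", paste(utils::head(missing_g, 5), collapse = ", "))
  missing_c <- setdiff(cells, expr$cell_ids)
  if (length(missing_c)) stop("unknown cells: ", paste(utils::head(missing_c, 5), collapse = ", "))
  expression_matrix(expr$values[genes, cells, drop = FALSE],
                    gene_ids = genes, cell_ids = cells,
                    domain_labels = expr$domain_labels[cells],
                    scale = expr$scale)
}

#' Apply the declared transform to a raw matrix
#'
#' @param values numeric matrix of non-negative raw values (counts, FPKM, ...).
#' @param transform `"none"`, `"log10p1"` (log10(x+1)), or `"cpm_log10p1"`
#'   (counts-per-million then log10(x+1)).
#' @return Transformed matrix.
#' @export
apply_transform <- function(values, transform = c("none", "log10p1", "cpm_log10p1")) {
  transform <- match.arg(transform)
  switch(transform,
         none = values,
         log10p1 = log10(values + 1),
         cpm_log10p1 = {
           libsize <- colSums(values)
           if (any(libsize == 0)) stop("cell with zero total counts; cannot compute CPM")
           log10(sweep(values, 2, libsize, "/") * 1e6 + 1)
         })
}

#' Load an expression matrix from disk
#'
#' Dense TSV/CSV (genes in rows, first column = gene id, header = cell ids),
#' or MatrixMarket MTX with companion row (gene) and column (cell) name files.
#'
#' @param path matrix file.
#' @param transform declared transform applied after loading; see
#'   [apply_transform]. The resulting scale is recorded on the object.
#' @param labels_path optional two-column TSV (cell_id, domain).
#' @param genes_path,cells_path one-identifier-per-line files, required for MTX.
#' @return An `expression_set`.
#' @export
load_expression <- function(path, transform = "none", labels_path = NULL,
                            genes_path = NULL, cells_path = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(cells_path)) {
      stop("MTX input requires genes_path and cells_path")
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_path)
    colnames(m) <- readLines(cells_path)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                             check.names = FALSE)
    m <- as.matrix(tab)
  }
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("expression matrix contains missing values")
  m <- apply_transform(m, transform)
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- load_domain_labels(labels_path)
    missing <- setdiff(colnames(m), names(labels))
    if (length(missing)) {
      stop("no domain label for cells: ", paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  scale <- if (transform == "none") "as_provided" else transform
  expression_matrix(m, domain_labels = labels, scale = scale)
}

#' Load per-cell domain labels
#'
#' @param path two-column TSV `cell_id<TAB>domain`, header optional.
#' @return Named character vector (names = cell ids).
#' @export
load_domain_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("label file must have two columns")
  if (identical(tolower(unlist(tab[1, 1:2], use.names = FALSE)),
                c("cell_id", "domain"))) {
    tab <- tab[-1, , drop = FALSE]
  }
  stats::setNames(tab[[2]], tab[[1]])
}

#' Prefilter genes by expression level and variability
#'
#' Keeps genes whose (log-scale) expression exceeds `min_value` in at least
#' `min_cells` cells and whose standard deviation across all cells exceeds
#' `min_sd`. This removes silent and flat genes before feature selection.
#'
#' @param expr an `expression_set` on the declared log scale.
#' @param min_value expression threshold (default 1.0).
#' @param min_cells minimum number of cells above threshold (default 2).
#' @param min_sd minimum across-cell standard deviation (default 0.05).
#' @return Character vector of surviving gene ids.
#' @export
prefilter_genes <- function(expr, min_value = 1.0, min_cells = 2L, min_sd = 0.05) {
  stopifnot(inherits(expr, "expression_set"))
  v <- expr$values
  n_high <- rowSums(v > min_value)
  sds <- apply(v, 1, stats::sd)
  keep <- n_high >= min_cells & sds > min_sd
  if (!any(keep)) {
    stop(sprintf(paste0("no genes pass the prefilter (%d genes checked; ",
                        "%d with > %g in >= %d cells; %d with SD > %g)"),
                 nrow(v), sum(n_high >= min_cells), min_value, min_cells,
                 sum(sds > min_sd), min_sd))
  }
  expr$gene_ids[keep]
}
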
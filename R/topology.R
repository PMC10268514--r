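#' Cell-domain topology graphs
#'
#' A topology graph encodes the adjacency between cell domains (tissue layers,
#' cell types, developmental stages). It doubles as the mapping layer of the
#' graph-based self-organizing map: each vertex hosts one centroid, and the
#' distance between two map units is the shortest-path edge count between the
#' corresponding vertices.
#'
#' @param adjacency square symmetric 0/1 matrix with zero diagonal. Row/column
#'   names, when present, must agree and be unique.
#' @param vertex_names optional character vector overriding the dimnames.
#' @return An object of class `topology_graph`: a list with elements
#'   `vertex_names`, `adjacency`, `distances` (shortest-path edge counts, with
#'   unreachable pairs set to the number of vertices), and `is_connected`.
#' @examples
#' g <- topology_graph(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)),
#'                     vertex_names = c("A", "B", "C"))
#' g$distances["A", "C"]  # 2
#' @export
topology_graph <- function(adjacency, vertex_names = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) {
    stop("adjacency matrix must be square")
  }
  if (is.null(vertex_names)) {
    vertex_names <- rownames(adjacency)
  }
  if (is.null(vertex_names)) {
    vertex_names <- paste0("V", seq_len(nrow(adjacency)))
  }
  vertex_names <- as.character(vertex_names)
  if (length(vertex_names) != nrow(adjacency)) {
    stop("vertex_names length does not match adjacency dimension")
  }
  if (anyDuplicated(vertex_names)) {
    stop("duplicate vertex names: ",
         paste(unique(vertex_names[duplicated(vertex_names)]), collapse = ", "))
  }
  storage.mode(adjacency) <- "double"
  if (anyNA(adjacency) || !all(adjacency %in% c(0, 1))) {
    stop("adjacency entries must be 0 or 1")
  }
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("adjacency matrix must be symmetric")
  }
  if (any(diag(adjacency) != 0)) {
    stop("self-loops are not allowed (non-zero diagonal)")
  }
  dimnames(adjacency) <- list(vertex_names, vertex_names)
  distances <- shortest_path_distances(adjacency)
  structure(
    list(
      vertex_names = vertex_names,
      adjacency = adjacency,
      distances = distances,
      is_connected = all(distances < nrow(adjacency))
    ),
    class = "topology_graph"
  )
}

#' @export
print.topology_graph <- function(x, ...) {
  cat(sprintf("topology_graph: %d vertices, %d edges, %s\n",
              length(x$vertex_names), sum(x$adjacency) / 2,
              if (x$is_connected) "connected" else "disconnected"))
  cat("vertices:", paste(x$vertex_names, collapse = ", "), "\n")
  invisible(x)
}

#' All-pairs shortest-path distances of an unweighted graph
#'
#' Distances are edge counts of shortest paths. Unreachable pairs receive the
#' sentinel value `nrow(adjacency)` (one more than any achievable path length),
#' so that neighborhood weights stay small but finite on disconnected mapping
#' layers.
#'
#' @param adjacency symmetric 0/1 matrix with zero diagonal.
#' @return Integer-valued numeric matrix of the same dimension.
#' @export
shortest_path_distances <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                           diag = FALSE)
  d <- igraph::distances(g)
  d[is.infinite(d)] <- nrow(adjacency)
  dimnames(d) <- dimnames(adjacency)
  d
}

#' Randomize a topology graph by flipping edge states
#'
#' Each unordered vertex pair has its edge state (present/absent) flipped
#' independently with probability `p`. Used to study how robust topological
#' clustering is to misspecification of the input topology. When a
#' connectivity constraint is requested, graphs violating it are redrawn up to
#' `max_attempts` times.
#'
#' @param graph a [topology_graph].
#' @param p flip probability in \[0, 1\] per unordered vertex pair.
#' @param constraint `"none"`, `"connected"` (result must be connected) or
#'   `"disconnected"` (result must have at least two components).
#' @param seed integer seed; the draw is reproducible.
#' @param max_attempts resampling budget before failing.
#' @return A new `topology_graph` on the same vertex set.
#' @export
randomize_topology <- function(graph, p, constraint = c("none", "connected", "disconnected"),
                               seed = NULL, max_attempts = 1000L) {
  stopifnot(inherits(graph, "topology_graph"))
  constraint <- match.arg(constraint)
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
    stop("p must be a single probability in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- length(graph$vertex_names)
  upper <- upper.tri(matrix(0, k, k))
  for (attempt in seq_len(max_attempts)) {
    adj <- graph$adjacency
    flips <- stats::runif(sum(upper)) < p
    adj[upper][flips] <- 1 - adj[upper][flips]
    adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
    out <- topology_graph(adj, graph$vertex_names)
    ok <- switch(constraint,
                 none = TRUE,
                 connected = out$is_connected,
                 disconnected = !out$is_connected)
    if (ok) return(out)
    if (p == 0) break  # deterministic draw, retrying cannot help
  }
  stop(sprintf("could not satisfy constraint '%s' within %d attempts (p = %g)",
               constraint, max_attempts, p))
}

#' Load a topology graph from a file
#'
#' Accepts either an edge-list TSV (two columns, `source<TAB>target`, header
#' optional) or a square adjacency CSV whose first row and column hold domain
#' names. Edge lists are symmetrized; self-loops and duplicate names are
#' rejected.
#'
#' @param path path to the file.
#' @param format `"auto"` (guess from extension/shape), `"edgelist"` or
#'   `"adjacency"`.
#' @return A [topology_graph].
#' @export
load_topology <- function(path, format = c("auto", "edgelist", "adjacency")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("topology file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "adjacency" else "edgelist"
  }
  if (format == "adjacency") {
    tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    mat <- as.matrix(tab)
    if (!identical(rownames(mat), colnames(mat))) {
      stop("adjacency CSV row and column names differ")
    }
    return(topology_graph(mat))
  }
  lines <- readLines(path)
  extra_verts <- character()
  vert_line <- grep("^#\\s*vertices:", lines, value = TRUE)
  if (length(vert_line)) {
    extra_verts <- strsplit(sub("^#\\s*vertices:\\s*", "", vert_line[1]), ",")[[1]]
    extra_verts <- trimws(extra_verts)
  }
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  edges <- utils::read.delim(text = lines, header = FALSE,
                             stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(edges) < 2L) stop("edge list must have two columns")
  edges <- edges[, 1:2]
  # tolerate a header line such as "source\ttarget"
  if (identical(tolower(unlist(edges[1, ], use.names = FALSE)),
                c("source", "target"))) {
    edges <- edges[-1, , drop = FALSE]
  }
  if (nrow(edges) == 0L) stop("edge list is empty")
  if (any(edges[[1]] == edges[[2]])) stop("self-loop in edge list input")
  verts <- unique(c(edges[[1]], edges[[2]]))
  if (length(extra_verts)) verts <- union(extra_verts, verts)
  adj <- matrix(0, length(verts), length(verts), dimnames = list(verts, verts))
  for (i in seq_len(nrow(edges))) {
    adj[edges[i, 1], edges[i, 2]] <- 1
    adj[edges[i, 2], edges[i, 1]] <- 1
  }
  topology_graph(adj)
}

#' Write a topology graph as an edge-list TSV
#'
#' @param graph a [topology_graph].
#' @param path output path.
#' @return `path`, invisibly. The full vertex set (including isolated
#'   vertices) is recorded in a `# vertices:` header comment that
#'   [load_topology] understands.
#' @export
write_topology <- function(graph, path) {
  stopifnot(inherits(graph, "topology_graph"))
  idx <- which(upper.tri(graph$adjacency) & graph$adjacency == 1, arr.ind = TRUE)
  df <- data.frame(source = graph$vertex_names[idx[, 1]],
                   target = graph$vertex_names[idx[, 2]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# vertices: ", paste(graph$vertex_names, collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
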
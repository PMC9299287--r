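#' Construct an undirected simple graph
#'
#' The basic data container of the package: a symmetric binary adjacency
#' matrix with an empty diagonal (no self loops), optionally carrying the
#' original string identifiers of the nodes.
#'
#' @param adjacency square 0/1 matrix; symmetrized entries must agree and the
#'   diagonal must be zero.
#' @param node_ids optional character vector of original node identifiers,
#'   one per row of `adjacency`.
#' @return An object of class `eb_graph` with components `n`, `adjacency`
#'   (base integer matrix) and `node_ids`.
#' @export
eb_graph <- function(adjacency, node_ids = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency))
    stop("adjacency must be square")
  storage.mode(adjacency) <- "integer"
  if (!all(adjacency %in% c(0L, 1L)))
    stop("adjacency entries must be 0/1")
  if (!isTRUE(all(adjacency == t(adjacency))))
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0L))
    stop("adjacency diagonal must be zero (self loops are excluded)")
  n <- nrow(adjacency)
  if (!is.null(node_ids)) {
    node_ids <- as.character(node_ids)
    if (length(node_ids) != n) stop("node_ids length must equal n")
  }
  dimnames(adjacency) <- NULL
  structure(list(n = n, adjacency = adjacency, node_ids = node_ids),
            class = "eb_graph")
}

#' @export
print.eb_graph <- function(x, ...) {
  m <- sum(x$adjacency) / 2
  cat(sprintf("<eb_graph> %d nodes, %d edges, density %.4g\n",
              x$n, m, if (x$n > 1) 2 * m / (x$n * (x$n - 1)) else 0))
  invisible(x)
}

#' Number of edges of a graph
#' @param g an `eb_graph`.
#' @return Integer edge count.
#' @export
edge_count <- function(g) {
  stopifnot(inherits(g, "eb_graph"))
  as.integer(sum(g$adjacency) / 2)
}

#' Construct a node partition
#'
#' A partition assigns every node to exactly one of `K` communities labelled
#' `1..K`. Empty communities are disallowed; use [compact_partition()] to
#' drop them after an operation that may empty a community.
#'
#' @param labels integer vector of community labels in `1..K`, one per node.
#' @param K number of communities; defaults to `max(labels)`.
#' @return An object of class `eb_partition` with components `labels`, `K`
#'   and `sizes` (community node counts, summing to `n`).
#' @export
eb_partition <- function(labels, K = max(labels)) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) stop("labels must be non-empty")
  if (anyNA(labels) || any(labels < 1L) || any(labels > K))
    stop("labels must lie in 1..K")
  sizes <- tabulate(labels, nbins = K)
  if (any(sizes == 0L))
    stop("empty communities are not allowed; compact the labels first")
  structure(list(labels = labels, K = as.integer(K), sizes = sizes),
            class = "eb_partition")
}

#' @export
print.eb_partition <- function(x, ...) {
  cat(sprintf("<eb_partition> %d nodes in %d communities; sizes: %s\n",
              length(x$labels), x$K, paste(x$sizes, collapse = " ")))
  invisible(x)
}

#' Compact community labels to 1..K
#'
#' Relabels so that only occupied communities remain, preserving the
#' first-appearance order of the original labels.
#'
#' @param labels integer (or factor-like) label vector.
#' @return An `eb_partition` over the occupied communities.
#' @export
compact_partition <- function(labels) {
  labels <- as.integer(labels)
  eb_partition(match(labels, unique(labels)))
}

#' Read an undirected graph from an edge list file
#'
#' One edge per line, two whitespace-separated node tokens; lines starting
#' with `#` are ignored. Nodes are indexed internally in first-appearance
#' order. Duplicate and reciprocal arcs collapse to a single undirected
#' edge; self loops are dropped with a warning reporting their count.
#'
#' @param path file path.
#' @param directed if `TRUE` the file is interpreted as arcs, each of which
#'   contributes an undirected edge (orientation removal).
#' @return An `eb_graph` whose `node_ids` are the original tokens.
#' @export
load_edge_list <- function(path, directed = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty edge list: ", path)
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  bad <- which(lengths(toks) != 2L)
  if (length(bad) > 0L)
    stop(sprintf("malformed edge list line %d in %s: %s",
                 idx[bad[1L]], path, lines[idx[bad[1L]]]))
  from <- vapply(toks, `[`, "", 1L)
  to <- vapply(toks, `[`, "", 2L)
  ids <- unique(c(rbind(from, to)))  # first-appearance order within each line
  i <- match(from, ids)
  j <- match(to, ids)
  loops <- i == j
  if (any(loops)) {
    warning(sprintf("dropped %d self loop(s)", sum(loops)))
    i <- i[!loops]; j <- j[!loops]
  }
  n <- length(ids)
  adj <- matrix(0L, n, n)
  adj[cbind(i, j)] <- 1L
  adj[cbind(j, i)] <- 1L
  eb_graph(adj, node_ids = ids)
}

#' Write / read an adjacency matrix in MatrixMarket format
#'
#' The graph is stored as a `coordinate pattern symmetric` MatrixMarket
#' file holding the lower-triangle edges, so `load_adjacency(save_adjacency(g))`
#' reproduces the adjacency pattern exactly.
#'
#' @param g an `eb_graph`.
#' @param path destination file path.
#' @return `save_adjacency` returns `path` invisibly; `load_adjacency`
#'   returns an `eb_graph`.
#' @export
save_adjacency <- function(g, path) {
  stopifnot(inherits(g, "eb_graph"))
  m <- Matrix::Matrix(g$adjacency != 0L, sparse = TRUE)
  m <- as(Matrix::forceSymmetric(m), "nMatrix")
  Matrix::writeMM(m, path)
  invisible(path)
}

#' @rdname save_adjacency
#' @export
load_adjacency <- function(path) {
  m <- Matrix::readMM(path)
  a <- as.matrix(m)
  storage.mode(a) <- "integer"
  if (nrow(a) != ncol(a) || !isTRUE(all(a == t(a))))
    stop("adjacency file is not a symmetric square matrix: ", path)
  if (!all(a %in% c(0L, 1L)))
    stop("adjacency file is not binary: ", path)
  if (any(diag(a) != 0L))
    stop("adjacency file has nonzero diagonal entries: ", path)
  eb_graph(a)
}

#' Read a node-label TSV as a partition
#'
#' Two whitespace-separated columns: node token, label token. Every node of
#' the graph must be assigned exactly one label. Label tokens are compacted
#' to `1..K` preserving their first-appearance order in the file.
#'
#' @param path file path.
#' @param g the `eb_graph` the labels refer to; must carry `node_ids`.
#' @return An `eb_partition`.
#' @export
load_labels <- function(path, g) {
  stopifnot(inherits(g, "eb_graph"))
  if (is.null(g$node_ids)) stop("graph carries no node identifiers")
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = "character",
                           col.names = c("node", "label"))
  unknown <- setdiff(tab$node, g$node_ids)
  if (length(unknown) > 0L)
    stop("unknown node token(s) in label file: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  pos <- match(g$node_ids, tab$node)
  if (anyNA(pos))
    stop("nodes missing a label: ",
         paste(utils::head(g$node_ids[is.na(pos)], 5L), collapse = ", "))
  lab_tokens <- tab$label[pos]
  # compaction order follows first appearance in the file, not in the graph
  levels_in_file <- unique(tab$label)
  compact_partition(match(lab_tokens, levels_in_file))
}
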
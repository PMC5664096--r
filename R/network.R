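#' Construct a gene interaction network
#'
#' Builds an undirected, unweighted gene network from a two-column table of
#' interactions. Self-loops are dropped and duplicate edges (in either
#' orientation) are collapsed; the counts of both are reported with
#' `message()`. Gene identifiers are matched as exact strings, case
#' preserved — identifier translation (symbol/Entrez/UniProt) is out of
#' scope and must happen upstream.
#'
#' Nodes listed in `nodes` but absent from any edge are retained as isolated
#' nodes: their transition-matrix column is all zero, and under random walk
#' with restart their converged value is exactly `restart * V[i]`.
#'
#' @param edges two-column character matrix or data frame; each row one
#'   interaction (extra columns are ignored).
#' @param nodes optional character vector of node identifiers to register in
#'   addition to edge endpoints (e.g. isolated genes). Node order is `nodes`
#'   first, then edge endpoints in order of first appearance.
#' @return an object of class `gene_network` with components `nodes`
#'   (character), `edges` (integer matrix, one canonical `i < j` row per
#'   edge), `degree` (named integer) and `transition` (column-stochastic
#'   `dgCMatrix`; entry `[i, j]` is the probability of stepping from j to i,
#'   `1/degree(j)` for every neighbor i of j).
#' @seealso [read_edge_list()], [build_transition_matrix()]
#' @export
#' @examples
#' net <- gene_network(rbind(c("A", "B"), c("B", "C")))
#' net$degree
gene_network <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2, drop = FALSE])
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2, byrow = TRUE)
  edges <- matrix(as.character(edges[, 1:2]), ncol = 2)

  loop <- edges[, 1] == edges[, 2]
  if (any(loop)) {
    message("dropped ", sum(loop), " self-loop edge(s)")
    edges <- edges[!loop, , drop = FALSE]
  }
  if (nrow(edges) == 0L) {
    stop("network has no edges after removing self-loops", call. = FALSE)
  }

  node_ids <- unique(c(as.character(nodes), as.vector(t(edges))))
  ei <- cbind(match(edges[, 1], node_ids), match(edges[, 2], node_ids))
  flip <- ei[, 1] > ei[, 2]
  ei[flip, ] <- ei[flip, 2:1]
  dup <- duplicated(ei)
  if (any(dup)) {
    message("collapsed ", sum(dup), " duplicate edge(s)")
    ei <- ei[!dup, , drop = FALSE]
  }

  degree <- tabulate(ei, nbins = length(node_ids))
  names(degree) <- node_ids
  dimnames(ei) <- NULL

  net <- structure(
    list(nodes = node_ids, edges = ei, degree = degree, transition = NULL),
    class = "gene_network"
  )
  build_transition_matrix(net)
}

#' Build (or rebuild) the random-walk transition matrix
#'
#' Populates the `transition` field of a network with the column-stochastic
#' matrix M used by the random walk: column j is uniform over the neighbors
#' of j (`M[i, j] = 1/degree(j)` when `{i, j}` is an edge, 0 otherwise).
#' Isolated nodes get an all-zero column, so every non-empty column sums to
#' one.
#'
#' @param network a `gene_network`.
#' @return the network with `transition` populated.
#' @export
build_transition_matrix <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  if (nrow(network$edges) < 1L) stop("network has no edges", call. = FALSE)
  n <- length(network$nodes)
  ei <- network$edges
  i <- c(ei[, 1], ei[, 2])
  j <- c(ei[, 2], ei[, 1])
  network$transition <- Matrix::sparseMatrix(
    i = i, j = j, x = 1 / network$degree[j], dims = c(n, n),
    dimnames = list(network$nodes, network$nodes)
  )
  network
}

#' Read a network from a tab-separated edge list
#'
#' One interaction per line; the first two tab-separated fields are gene
#' identifiers and any further columns (HPRD-style dumps carry several) are
#' ignored. Lines starting with `comment_prefix` and blank lines are
#' skipped; lines with fewer than two fields are dropped with a message.
#'
#' @param path file path.
#' @param comment_prefix lines starting with this string are ignored.
#' @return a [gene_network()].
#' @export
read_edge_list <- function(path, comment_prefix = "#") {
  if (!file.exists(path)) {
    stop("network file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, comment_prefix)]
  if (length(lines) == 0L) stop("no edges in ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 2L
  if (any(!ok)) {
    message("dropped ", sum(!ok), " malformed line(s) with < 2 fields")
    fields <- fields[ok]
  }
  if (length(fields) == 0L) stop("no edges in ", path, call. = FALSE)
  edges <- cbind(
    vapply(fields, `[[`, character(1), 1L),
    vapply(fields, `[[`, character(1), 2L)
  )
  gene_network(edges)
}

#' Write a network as a tab-separated edge list
#'
#' @param network a `gene_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  ei <- network$edges
  writeLines(
    paste(network$nodes[ei[, 1]], network$nodes[ei[, 2]], sep = "\t"),
    path
  )
  invisible(path)
}

#' @export
print.gene_network <- function(x, ...) {
  cat(
    "gene_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges",
    sprintf("(%d isolated)\n", sum(x$degree == 0L))
  )
  invisible(x)
}
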
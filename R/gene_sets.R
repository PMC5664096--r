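#' Construct a collection of named gene sets
#'
#' @param members named list of character vectors (one per set); names are
#'   the set identifiers and must be unique. Members are deduplicated,
#'   preserving first-appearance order.
#' @param descriptions optional character vector of per-set descriptions
#'   (recycled from `""` if missing).
#' @return an object of class `gene_set_collection` with components `ids`,
#'   `descriptions` (named), `members` (named list) and — after
#'   [map_to_network()] — `mapped` (named list of members present in the
#'   network) and `scorable` (named logical; FALSE when no member maps).
#' @export
gene_set_collection <- function(members, descriptions = NULL) {
  ids <- names(members)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop("every gene set needs a non-empty identifier", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate gene set identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(descriptions)) descriptions <- rep("", length(ids))
  members <- lapply(members, function(g) unique(as.character(g)))
  structure(
    list(
      ids = ids,
      descriptions = setNames(as.character(descriptions), ids),
      members = setNames(members, ids)
    ),
    class = "gene_set_collection"
  )
}

#' Read gene sets in GMT format
#'
#' Broad/MSigDB dialect: tab-separated, column 1 the set name, column 2 a
#' free-text description, columns 3+ the member genes. Members are
#' deduplicated and input order is preserved.
#'
#' @param path file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(gene_set_collection(setNames(list(), character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line ", bad[1L], " (needs id, description, >= 1 gene)",
         call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate gene set identifier(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  gene_set_collection(
    members = setNames(lapply(fields, function(f) f[-(1:2)]), ids),
    descriptions = vapply(fields, `[[`, character(1), 2L)
  )
}

#' Write gene sets in GMT format
#'
#' @param sets a `gene_set_collection`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  writeLines(
    vapply(sets$ids, function(id) {
      paste(c(id, sets$descriptions[[id]], sets$members[[id]]),
            collapse = "\t")
    }, character(1)),
    path
  )
  invisible(path)
}

#' Construct an input gene set
#'
#' @param genes character vector of gene identifiers; duplicates removed.
#' @return object of class `input_gene_set` with components `genes` and —
#'   after [map_to_network()] — `mapped`, the subset present in the network.
#' @export
input_gene_set <- function(genes) {
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  structure(list(genes = genes, mapped = NULL), class = "input_gene_set")
}

#' Read an input gene set from a plain-text list
#'
#' One gene per line; lines starting with `#` and blank lines are ignored.
#'
#' @param path file path.
#' @return an [input_gene_set()].
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    stop("gene list file not found: ", path, call. = FALSE)
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  input_gene_set(lines)
}

#' Map gene sets onto a network
#'
#' Annotates a gene set collection or an input gene set with the subset of
#' members that are nodes of `network`. Pathway similarity scores are
#' averages over mapped members only, so sets with zero mapped members are
#' flagged unscorable and excluded from ranking. Input genes absent from
#' the network are dropped from the effective seed set with a message.
#'
#' @param x a `gene_set_collection` or `input_gene_set`.
#' @param network a `gene_network`.
#' @param ... unused.
#' @return `x` with mapping fields filled in.
#' @export
map_to_network <- function(x, network, ...) UseMethod("map_to_network")

#' @rdname map_to_network
#' @export
map_to_network.gene_set_collection <- function(x, network, ...) {
  stopifnot(inherits(network, "gene_network"))
  x$mapped <- lapply(x$members, intersect, network$nodes)
  x$scorable <- setNames(lengths(x$mapped) > 0L, x$ids)
  if (any(!x$scorable)) {
    message(sum(!x$scorable),
            " gene set(s) have no network-mapped members (unscorable)")
  }
  x
}

#' @rdname map_to_network
#' @export
map_to_network.input_gene_set <- function(x, network, ...) {
  stopifnot(inherits(network, "gene_network"))
  x$mapped <- intersect(x$genes, network$nodes)
  n_drop <- length(x$genes) - length(x$mapped)
  if (n_drop > 0L) {
    message("dropped ", n_drop, " input gene(s) absent from the network")
  }
  x
}

#' @export
length.gene_set_collection <- function(x) length(x$ids)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$ids), "sets")
  if (!is.null(x$scorable)) cat(",", sum(x$scorable), "scorable")
  cat("\n")
  invisible(x)
}

#' @export
print.input_gene_set <- function(x, ...) {
  cat("input_gene_set:", length(x$genes), "genes")
  if (!is.null(x$mapped)) cat(",", length(x$mapped), "mapped")
  cat("\n")
  invisible(x)
}
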
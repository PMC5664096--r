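#' Sample a random gene set from network nodes
#'
#' Draws `size` nodes uniformly without replacement — the randomized input
#' used by the permutation background. With `degree_matched = TRUE` each
#' gene of `reference` is instead replaced by a random node from the same
#' degree decile (sampling without replacement, widening to the nearest
#' degrees when a decile is exhausted); this is off by default, matching
#' the plain uniform randomization of the standard background.
#'
#' @param network a [gene_network()].
#' @param size number of genes to draw (1..number of nodes). Ignored when
#'   `reference` is supplied with `degree_matched = TRUE`.
#' @param degree_matched match the degree distribution of `reference`.
#' @param reference character vector of mapped genes to degree-match.
#' @return an [input_gene_set()] whose genes are all network nodes.
#' @export
sample_random_gene_set <- function(network, size, degree_matched = FALSE,
                                   reference = NULL) {
  stopifnot(inherits(network, "gene_network"))
  n <- length(network$nodes)
  if (degree_matched) {
    if (is.null(reference)) {
      stop("degree-matched sampling needs a reference gene set",
           call. = FALSE)
    }
    genes <- .sample_degree_matched(network, reference)
  } else {
    if (!(length(size) == 1L && size >= 1L && size <= n)) {
      stop("size must be between 1 and the number of network nodes (", n,
           ")", call. = FALSE)
    }
    genes <- network$nodes[sample.int(n, size)]
  }
  out <- input_gene_set(genes)
  out$mapped <- out$genes
  out
}

.sample_degree_matched <- function(network, reference) {
  reference <- intersect(reference, network$nodes)
  if (length(reference) == 0L) stop("reference maps to no nodes", call. = FALSE)
  deg <- network$degree
  breaks <- unique(quantile(deg, probs = seq(0, 1, 0.1), type = 1))
  bin <- if (length(breaks) > 1L) {
    cut(deg, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  } else {
    rep(1L, length(deg))
  }
  ref_bin <- bin[match(reference, network$nodes)]
  chosen <- character(0)
  for (b in ref_bin) {
    pool <- setdiff(network$nodes[bin == b], chosen)
    if (length(pool) == 0L) {
      # widen to the globally nearest degrees among unchosen nodes
      rest <- setdiff(network$nodes, chosen)
      pool <- rest[order(abs(deg[rest] - mean(deg[bin == b])))][1:5]
      pool <- pool[!is.na(pool)]
    }
    chosen <- c(chosen, pool[sample.int(length(pool), 1L)])
  }
  chosen
}

#' Degree-preserving network rewiring
#'
#' Randomizes the edge set by repeated double-edge swaps: two edges
#' `{a, b}` and `{c, d}` are replaced by `{a, d}` and `{c, b}` whenever
#' doing so creates no self-loop and no duplicate edge. Each swap leaves
#' every node's degree unchanged, so the rewired network has exactly the
#' original degree sequence while its wiring is randomized. The routine
#' performs `swap_factor * |E|` successful swaps (the usual mixing
#' heuristic), abandoning with a warning if the attempt budget is exhausted
#' first — e.g. a star graph admits no valid swap at all and is returned
#' unchanged.
#'
#' @param network a [gene_network()] with at least 2 edges.
#' @param swap_factor number of successful swaps per edge; 0 returns the
#'   network unchanged.
#' @param attempt_factor budget of attempted swaps per requested swap.
#' @return a `gene_network` with identical nodes and degrees and a rebuilt
#'   transition matrix.
#' @export
rewire_network <- function(network, swap_factor = 10, attempt_factor = 30) {
  stopifnot(inherits(network, "gene_network"))
  E <- network$edges
  m <- nrow(E)
  if (swap_factor == 0) return(network)
  if (m < 2L) {
    warning("network has fewer than 2 edges; no rewiring possible",
            call. = FALSE)
    return(network)
  }
  target <- as.integer(round(swap_factor * m))
  budget <- max(100L, as.integer(attempt_factor) * target)

  present <- new.env(hash = TRUE, size = 2L * m)
  key <- function(a, b) paste0(a, ".", b)
  for (r in seq_len(m)) assign(key(E[r, 1], E[r, 2]), TRUE, envir = present)

  successes <- 0L
  attempts <- 0L
  batch <- 2048L
  while (successes < target && attempts < budget) {
    k <- min(batch, budget - attempts)
    e1s <- sample.int(m, k, replace = TRUE)
    e2s <- sample.int(m, k, replace = TRUE)
    flips <- runif(k) < 0.5
    for (t in seq_len(k)) {
      attempts <- attempts + 1L
      e1 <- e1s[t]; e2 <- e2s[t]
      if (e1 == e2) next
      a <- E[e1, 1]; b <- E[e1, 2]
      c_ <- E[e2, 1]; d <- E[e2, 2]
      if (flips[t]) { tmp <- c_; c_ <- d; d <- tmp }
      if (a == d || c_ == b) next
      n1a <- min(a, d); n1b <- max(a, d)
      n2a <- min(c_, b); n2b <- max(c_, b)
      k1 <- key(n1a, n1b); k2 <- key(n2a, n2b)
      if (k1 == k2) next
      if (exists(k1, envir = present, inherits = FALSE) ||
          exists(k2, envir = present, inherits = FALSE)) next
      rm(list = c(key(a, b), key(E[e2, 1], E[e2, 2])), envir = present)
      assign(k1, TRUE, envir = present)
      assign(k2, TRUE, envir = present)
      E[e1, ] <- c(n1a, n1b)
      E[e2, ] <- c(n2a, n2b)
      successes <- successes + 1L
      if (successes >= target) break
    }
  }

  if (successes == 0L) {
    warning("no valid edge swap found; returning the network unchanged",
            call. = FALSE)
    return(network)
  }
  if (successes < target) {
    warning("completed only ", successes, " of ", target,
            " requested edge swaps", call. = FALSE)
  }
  out <- network
  out$edges <- E
  build_transition_matrix(out)
}

#' Build the permutation background ensembles
#'
#' Computes the four pieces of similarity scores that feed the enrichment
#' z-scores, for all scorable pathways at once:
#' \describe{
#'   \item{DN}{real input on the real network (one score per pathway).}
#'   \item{DR}{real input on each rewired network (pathway x network).}
#'   \item{RN}{each of `n_perm` random gene sets — drawn uniformly from
#'     network nodes, size-matched to the mapped input — on the real
#'     network (pathway x replicate).}
#'   \item{RR}{the *same* `n_perm` random gene sets on each rewired network
#'     (pathway x network x replicate). Reusing the sets pairs each RR
#'     column with its RN column, so `RN - mean(RR)` is a per-replicate
#'     paired difference.}
#' }
#' With an empty `rewired` list only `DN` and `RN` are produced (the plain
#' NetPEA background).
#'
#' @param network a [gene_network()].
#' @param pathways a mapped [gene_set_collection()].
#' @param input a mapped [input_gene_set()].
#' @param n_perm number of random gene sets (>= 2).
#' @param rewired list of rewired `gene_network`s (possibly empty).
#' @param restart,tol,max_iter propagation parameters, see [rwr()].
#' @param degree_matched draw degree-matched rather than uniform random
#'   gene sets.
#' @return object of class `null_ensembles`: `pathway_ids`, `DN` (named
#'   vector), `RN` (matrix), and with rewired networks also `DR` (matrix)
#'   and `RR` (3-d array pathway x network x replicate).
#' @export
build_null_ensembles <- function(network, pathways, input, n_perm = 1000L,
                                 rewired = list(), restart = 0.5,
                                 tol = 1e-10, max_iter = 1000L,
                                 degree_matched = FALSE) {
  stopifnot(inherits(network, "gene_network"),
            inherits(pathways, "gene_set_collection"),
            inherits(input, "input_gene_set"))
  if (n_perm < 2L) stop("n_perm must be >= 2", call. = FALSE)
  if (is.null(pathways$mapped)) {
    pathways <- map_to_network(pathways, network)
  }
  if (is.null(input$mapped)) input <- map_to_network(input, network)
  if (length(input$mapped) == 0L) {
    stop("no input genes map onto the network", call. = FALSE)
  }

  ids <- pathways$ids[pathways$scorable]
  if (length(ids) == 0L) stop("no scorable pathways", call. = FALSE)
  n <- length(network$nodes)
  size <- length(input$mapped)

  # pathway averaging operator: row k = 1/|mapped_k| over mapped members
  A <- .pathway_operator(network, pathways, ids)

  # seed matrix: column 1 = real input, columns 2..n_perm+1 = random sets
  V <- matrix(0, n, n_perm + 1L)
  V[match(input$mapped, network$nodes), 1L] <- 1
  for (r in seq_len(n_perm)) {
    rset <- sample_random_gene_set(network, size,
                                   degree_matched = degree_matched,
                                   reference = if (degree_matched)
                                     input$mapped else NULL)
    V[match(rset$mapped, network$nodes), r + 1L] <- 1
  }

  score_on <- function(net) {
    S <- .rwr_batch(net$transition, V, restart, tol, max_iter)
    as.matrix(A %*% S)
  }

  sc_real <- score_on(network)
  out <- list(
    pathway_ids = ids,
    DN = setNames(sc_real[, 1L], ids),
    RN = sc_real[, -1L, drop = FALSE],
    DR = NULL,
    RR = NULL,
    n_perm = as.integer(n_perm),
    n_nets = length(rewired)
  )
  rownames(out$RN) <- ids

  if (length(rewired) > 0L) {
    out$DR <- matrix(NA_real_, length(ids), length(rewired),
                     dimnames = list(ids, NULL))
    out$RR <- array(NA_real_,
                    dim = c(length(ids), length(rewired), n_perm),
                    dimnames = list(ids, NULL, NULL))
    for (j in seq_along(rewired)) {
      sc <- score_on(rewired[[j]])
      out$DR[, j] <- sc[, 1L]
      out$RR[, j, ] <- sc[, -1L, drop = FALSE]
    }
  }
  structure(out, class = "null_ensembles")
}

# Sparse pathway-averaging operator restricted to scorable pathway ids.
.pathway_operator <- function(network, pathways, ids) {
  idx <- lapply(pathways$mapped[ids], match, network$nodes)
  Matrix::sparseMatrix(
    i = rep(seq_along(ids), lengths(idx)),
    j = unlist(idx),
    x = rep(1 / lengths(idx), lengths(idx)),
    dims = c(length(ids), length(network$nodes)),
    dimnames = list(ids, network$nodes)
  )
}

#' @export
print.null_ensembles <- function(x, ...) {
  cat("null_ensembles:", length(x$pathway_ids), "pathways,",
      x$n_perm, "random gene sets,", x$n_nets, "rewired network(s)\n")
  invisible(x)
}
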
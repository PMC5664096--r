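#' Random walk with restart from a seed gene set
#'
#' Spreads unit seed values over the network by iterating
#' `S_n = (1 - p) * M %*% S_{n-1} + p * V` from `S_0 = V`, where `V` is the
#' indicator vector of the mapped seed genes (value 1, all other nodes 0),
#' `M` the column-stochastic transition matrix, and `p` the restart
#' probability — the per-step probability that the walker jumps back to its
#' starting node rather than moving to a uniformly chosen neighbor. The
#' converged vector measures the proximity of every node to the seed set.
#'
#' Iteration stops when the L1 change between successive vectors drops
#' below `tol` (a contraction with factor `1 - p` guarantees geometric
#' convergence) or after `max_iter` iterations, in which case the profile
#' is returned with `converged = FALSE` and a warning.
#'
#' On networks without isolated nodes the converged values sum to the
#' number of mapped seeds, because every column of `M` sums to one. An
#' isolated seed node keeps exactly `p * V[i]`.
#'
#' @param network a [gene_network()].
#' @param seeds an [input_gene_set()] (mapped or not) or a character vector
#'   of gene identifiers; at least one must be a network node.
#' @param restart restart probability `p` in (0, 1); default 0.5.
#' @param tol L1 convergence tolerance (> 0).
#' @param max_iter maximum number of iterations.
#' @return object of class `propagation_profile`: `values` (named,
#'   non-negative, one per node), `restart`, `seeds` (mapped seed genes),
#'   `iterations`, `residual`, `converged`.
#' @seealso [rwr_closed_form()] for the exact fixed point,
#'   [similarity_score()] for pathway scoring.
#' @export
#' @examples
#' net <- gene_network(rbind(c("A", "B")))
#' p <- rwr(net, "A", restart = 0.5)
#' p$values  # A = 2/3, B = 1/3
rwr <- function(network, seeds, restart = 0.5, tol = 1e-10,
                max_iter = 1000L) {
  stopifnot(inherits(network, "gene_network"))
  if (!(restart > 0 && restart < 1)) {
    stop("restart probability must be in (0, 1)", call. = FALSE)
  }
  if (!(tol > 0)) stop("tol must be > 0", call. = FALSE)
  mapped <- .mapped_seeds(network, seeds)
  n <- length(network$nodes)
  V <- matrix(0, n, 1)
  V[match(mapped, network$nodes), 1] <- 1
  fit <- .rwr_iterate(network$transition, V, restart, tol, max_iter)
  if (!fit$converged) {
    warning("random walk did not converge in ", max_iter,
            " iterations (residual ", format(fit$residual), ")",
            call. = FALSE)
  }
  structure(
    list(
      values = setNames(fit$S[, 1], network$nodes),
      restart = restart,
      seeds = mapped,
      iterations = fit$iterations,
      residual = fit$residual,
      converged = fit$converged
    ),
    class = "propagation_profile"
  )
}

#' Exact stationary solution of the restart walk
#'
#' Solves the fixed point `S = p * (I - (1 - p) * M)^{-1} %*% V` by a dense
#' linear solve. The system is non-singular for any restart probability in
#' (0, 1) because `(1 - p) * M` has spectral radius at most `1 - p < 1`.
#' Intended as an independent oracle for [rwr()] on small networks; refuses
#' networks above 2000 nodes where the dense solve becomes wasteful.
#'
#' @inheritParams rwr
#' @return a `propagation_profile` with `iterations = NA` and
#'   `residual = 0`.
#' @export
rwr_closed_form <- function(network, seeds, restart = 0.5) {
  stopifnot(inherits(network, "gene_network"))
  if (!(restart > 0 && restart < 1)) {
    stop("restart probability must be in (0, 1)", call. = FALSE)
  }
  n <- length(network$nodes)
  if (n > 2000L) {
    stop("closed-form solve is limited to networks of <= 2000 nodes",
         call. = FALSE)
  }
  mapped <- .mapped_seeds(network, seeds)
  V <- numeric(n)
  V[match(mapped, network$nodes)] <- 1
  A <- diag(n) - (1 - restart) * as.matrix(network$transition)
  S <- solve(A, restart * V)
  structure(
    list(
      values = setNames(as.vector(S), network$nodes),
      restart = restart,
      seeds = mapped,
      iterations = NA_integer_,
      residual = 0,
      converged = TRUE
    ),
    class = "propagation_profile"
  )
}

#' Pathway similarity score
#'
#' The similarity of a pathway to the seed set that produced `profile` is
#' the arithmetic mean of the converged node values over the pathway's
#' network-mapped members.
#'
#' @param profile a `propagation_profile`.
#' @param members character vector of pathway member genes; at least one
#'   must be a node of the profiled network.
#' @return a non-negative scalar.
#' @export
similarity_score <- function(profile, members) {
  stopifnot(inherits(profile, "propagation_profile"))
  mm <- intersect(members, names(profile$values))
  if (length(mm) == 0L) {
    stop("pathway has no members mapped to the network; unscorable",
         call. = FALSE)
  }
  mean(profile$values[mm])
}

#' Export a propagation profile as TSV
#'
#' Writes `(gene, value)` pairs sorted by decreasing value.
#'
#' @param profile a `propagation_profile`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "propagation_profile"))
  ord <- order(-profile$values, names(profile$values))
  df <- data.frame(
    gene = names(profile$values)[ord],
    value = unname(profile$values[ord])
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.propagation_profile <- function(x, ...) {
  cat("propagation_profile:", length(x$values), "nodes,",
      length(x$seeds), "seeds, restart", x$restart, "\n")
  cat("  iterations:", x$iterations, " residual:", format(x$residual),
      " converged:", x$converged, "\n")
  invisible(x)
}

# Resolve seeds (input_gene_set or character) to mapped node identifiers.
.mapped_seeds <- function(network, seeds) {
  if (inherits(seeds, "input_gene_set")) {
    if (is.null(seeds$mapped)) seeds <- map_to_network(seeds, network)
    mapped <- seeds$mapped
  } else {
    mapped <- intersect(unique(as.character(seeds)), network$nodes)
  }
  if (length(mapped) == 0L) {
    stop("no seed genes map onto the network", call. = FALSE)
  }
  mapped
}

# Batched power iteration: V is an n x k matrix of seed indicator columns;
# every column is iterated until its own L1 residual is below tol.
.rwr_iterate <- function(M, V, restart, tol, max_iter) {
  S <- V
  resid <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    S_new <- (1 - restart) * as.matrix(M %*% S) + restart * V
    resid <- max(colSums(abs(S_new - S)))
    S <- S_new
    if (resid < tol) break
  }
  list(S = S, iterations = iter, residual = resid,
       converged = resid < tol)
}

# Chunked batch propagation for permutation ensembles; returns the n x k
# matrix of converged profiles.
.rwr_batch <- function(M, V, restart, tol, max_iter, chunk = 512L) {
  k <- ncol(V)
  if (k <= chunk) {
    return(.rwr_iterate(M, V, restart, tol, max_iter)$S)
  }
  out <- matrix(0, nrow(V), k)
  for (start in seq(1L, k, by = chunk)) {
    cols <- start:min(start + chunk - 1L, k)
    out[, cols] <- .rwr_iterate(M, V[, cols, drop = FALSE],
                                restart, tol, max_iter)$S
  }
  out
}
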
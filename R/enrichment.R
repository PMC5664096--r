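#' Permutation z-score against randomized gene sets
#'
#' `z = (D - mean(R)) / sd(R)`, where `D` is the observed pathway
#' similarity score and `R` the scores of the same pathway under
#' size-matched random input gene sets. The standard deviation uses the
#' sample (n - 1) convention. When `sd(R)` is zero the z-score is
#' undefined and `NA` is returned; [run_enrichment()] flags such pathways
#' and ranks them last.
#'
#' @param D observed similarity score.
#' @param R numeric vector of null similarity scores (length >= 2).
#' @return a scalar z-score, or `NA` if the null has zero variance.
#' @export
netpea_zscore <- function(D, R) {
  if (length(R) < 2L) stop("need at least 2 null scores", call. = FALSE)
  s <- sd(R)
  if (s == 0) return(NA_real_)
  (D - mean(R)) / s
}

#' Joint gene-set and network permutation z-score
#'
#' The network-corrected z-score
#' `z = ((DN - mean(DR)) - mean(C)) / sd(C)` with
#' `C_i = RN_i - mean_j(RR[j, i])` in the default `"paired"` mode, where
#' `DN` is the observed score on the real network, `DR` its scores on
#' rewired networks, `RN` the random-gene-set scores on the real network
#' and `RR` those same random gene sets on the rewired networks. Pathways
#' whose score survives degree-preserving rewiring (i.e. `mean(DR)` close
#' to `DN`) are corrected toward insignificance, which de-emphasizes
#' enrichment driven purely by direct overlap.
#'
#' In `"grand"` mode `C_i = RN_i - mean(RR)` with the grand mean over the
#' whole RR matrix; the numerator is unchanged but the null spread differs.
#'
#' @param DN observed score on the real network.
#' @param DR numeric vector: observed input on each rewired network.
#' @param RN numeric vector: random gene sets on the real network
#'   (length >= 2).
#' @param RR matrix `length(DR)` x `length(RN)`: random gene sets on
#'   rewired networks, replicates paired column-wise with `RN`.
#' @param mode `"paired"` (default) or `"grand"`; see Details.
#' @return a scalar z-score, or `NA` if the corrected null has zero
#'   variance (e.g. when the "rewired" networks are identical copies).
#' @export
netpea_prime_zscore <- function(DN, DR, RN, RR,
                                mode = c("paired", "grand")) {
  mode <- match.arg(mode)
  if (length(DR) < 1L) stop("need at least 1 rewired score", call. = FALSE)
  if (length(RN) < 2L) stop("need at least 2 null scores", call. = FALSE)
  RR <- as.matrix(RR)
  if (nrow(RR) != length(DR) || ncol(RR) != length(RN)) {
    stop("RR must have dimensions length(DR) x length(RN)", call. = FALSE)
  }
  C <- if (mode == "paired") RN - colMeans(RR) else RN - mean(RR)
  s <- sd(C)
  if (s == 0) return(NA_real_)
  ((DN - mean(DR)) - mean(C)) / s
}

#' Convert a z-score to a one-sided p-value
#'
#' Upper-tail standard normal probability `1 - Phi(z)`; the z = 1.65
#' significance cutoff corresponds to p = 0.05 under this convention.
#'
#' @param z numeric vector of z-scores.
#' @return p-values in `[0, 1]`.
#' @export
z_to_p <- function(z) pnorm(z, lower.tail = FALSE)

#' Hypergeometric over-representation p-value
#'
#' Cumulative upper-tail probability `P[X >= overlap]` of observing at
#' least the given overlap between an input gene set and a pathway, for
#' `X ~ Hypergeometric(universe, pathway_size, input_size)`.
#'
#' @param overlap observed number of shared genes.
#' @param input_size number of input genes in the universe.
#' @param pathway_size number of pathway genes in the universe.
#' @param universe total number of genes considered.
#' @return p-value in `[0, 1]` (vectorized over `overlap`/`pathway_size`).
#' @export
ora_pvalue <- function(overlap, input_size, pathway_size, universe) {
  if (any(overlap > pmin(input_size, pathway_size)) ||
      any(input_size > universe) || any(pathway_size > universe) ||
      any(overlap < 0)) {
    stop("inconsistent overlap/size arguments", call. = FALSE)
  }
  phyper(overlap - 1, pathway_size, universe - pathway_size, input_size,
         lower.tail = FALSE)
}

#' Network-based pathway enrichment analysis
#'
#' End-to-end enrichment of an input gene set against a pathway
#' collection. For the network methods the input is propagated over the
#' network by random walk with restart, each pathway is scored as the mean
#' converged value of its mapped members, and significance comes from a
#' permutation z-score: against random gene sets (`"netpea"`), or jointly
#' against random gene sets and degree-preserving rewired networks
#' (`"netpea-prime"`, Details in [netpea_prime_zscore()]). The `"ora"`
#' baseline scores direct overlap with the cumulative hypergeometric test
#' over all network nodes (or the gene-set universe).
#'
#' Pathways are ranked by decreasing z-score (ORA: increasing p-value),
#' ties broken lexicographically by identifier; pathways whose null has
#' zero variance are flagged, given `z = 0`, `p = 1`, and placed after all
#' unflagged pathways. Significance is `z > cutoff` (ORA: `p <= 0.05`),
#' or `BH-adjusted p <= 0.05` when `bh = TRUE`.
#'
#' @param network a [gene_network()].
#' @param pathways a [gene_set_collection()] (mapping is done internally).
#' @param input an [input_gene_set()] or character vector of genes.
#' @param method `"netpea"`, `"netpea-prime"` or `"ora"`.
#' @param restart restart probability of the walk (default 0.5).
#' @param n_perm number of random gene sets (default 1000).
#' @param n_nets number of rewired networks for netpea-prime (default 10).
#' @param swap_factor successful double-edge swaps per edge when rewiring.
#' @param cutoff z-score significance cutoff (default 1.65, one-sided
#'   p = 0.05).
#' @param seed integer seed controlling gene-set sampling and rewiring;
#'   identical seeds give byte-identical results.
#' @param rr_mode `"paired"` or `"grand"`, see [netpea_prime_zscore()].
#' @param degree_matched sample degree-matched rather than uniform random
#'   gene sets.
#' @param bh also compute Benjamini-Hochberg adjusted p-values and base
#'   the significance flag on `padj <= 0.05`.
#' @param min_size,max_size keep only pathways whose mapped size is within
#'   this window (defaults keep everything).
#' @param ora_universe `"network"` (all network nodes, default) or
#'   `"genesets"` (union of all pathway members) as the ORA universe.
#' @param tol,max_iter propagation controls, see [rwr()].
#' @return an `enrichment_result`: a data frame with one row per scored
#'   pathway — `pathway_id`, `description`, `size` (annotated),
#'   `mapped_size`, `overlap`, `similarity`, `zscore`, `pvalue` (and
#'   `padj` if `bh`), `rank`, `significant`, `flagged` — sorted by rank,
#'   with run metadata in `attr(, "metadata")`.
#' @export
run_enrichment <- function(network, pathways, input,
                           method = c("netpea", "netpea-prime", "ora"),
                           restart = 0.5, n_perm = 1000L, n_nets = 10L,
                           swap_factor = 10, cutoff = 1.65, seed = NULL,
                           rr_mode = c("paired", "grand"),
                           degree_matched = FALSE, bh = FALSE,
                           min_size = 0L, max_size = Inf,
                           ora_universe = c("network", "genesets"),
                           tol = 1e-10, max_iter = 1000L) {
  method <- match.arg(method)
  rr_mode <- match.arg(rr_mode)
  ora_universe <- match.arg(ora_universe)
  stopifnot(inherits(network, "gene_network"))
  if (!inherits(input, "input_gene_set")) input <- input_gene_set(input)
  if (!is.null(seed)) set.seed(as.integer(seed))

  pathways <- map_to_network(pathways, network)
  input <- map_to_network(input, network)
  if (length(input$mapped) == 0L) {
    stop("no input genes map onto the network", call. = FALSE)
  }

  keep <- pathways$scorable &
    lengths(pathways$mapped) >= min_size &
    lengths(pathways$mapped) <= max_size
  ids <- pathways$ids[keep]
  if (length(ids) == 0L) {
    stop("no scorable pathways after size filtering", call. = FALSE)
  }

  overlap <- vapply(pathways$mapped[ids],
                    function(g) length(intersect(g, input$mapped)),
                    integer(1))

  if (method == "ora") {
    universe <- if (ora_universe == "network") {
      length(network$nodes)
    } else {
      length(unique(unlist(pathways$members)))
    }
    pvalue <- ora_pvalue(overlap, length(input$mapped),
                         lengths(pathways$mapped[ids]), universe)
    zscore <- rep(NA_real_, length(ids))
    similarity <- rep(NA_real_, length(ids))
    flagged <- rep(FALSE, length(ids))
    ord <- order(pvalue, ids)
  } else {
    rewired <- list()
    if (method == "netpea-prime") {
      if (n_nets < 1L) stop("netpea-prime needs n_nets >= 1", call. = FALSE)
      rewired <- lapply(seq_len(n_nets), function(j) {
        rewire_network(network, swap_factor = swap_factor)
      })
    }
    ens <- build_null_ensembles(
      network, pathways, input, n_perm = n_perm, rewired = rewired,
      restart = restart, tol = tol, max_iter = max_iter,
      degree_matched = degree_matched
    )
    # keep order consistent with ids (scorable sets may differ from filter)
    ids <- intersect(ids, ens$pathway_ids)
    overlap <- overlap[ids]
    similarity <- unname(ens$DN[ids])
    if (method == "netpea") {
      zscore <- vapply(ids, function(k) {
        netpea_zscore(ens$DN[[k]], ens$RN[k, ])
      }, numeric(1))
    } else {
      zscore <- vapply(ids, function(k) {
        RRk <- matrix(ens$RR[k, , ], nrow = dim(ens$RR)[2L])
        netpea_prime_zscore(ens$DN[[k]], ens$DR[k, ], ens$RN[k, ],
                            RRk, mode = rr_mode)
      }, numeric(1))
    }
    flagged <- is.na(zscore)
    zscore[flagged] <- 0
    pvalue <- z_to_p(zscore)
    pvalue[flagged] <- 1
    ord <- order(flagged, -zscore, ids)
  }

  padj <- if (bh) p.adjust(pvalue, method = "BH") else NULL
  significant <- if (bh) {
    padj <= 0.05 & !flagged
  } else if (method == "ora") {
    pvalue <= 0.05
  } else {
    zscore > cutoff & !flagged
  }

  res <- data.frame(
    pathway_id = ids,
    description = unname(pathways$descriptions[ids]),
    size = lengths(pathways$members[ids]),
    mapped_size = lengths(pathways$mapped[ids]),
    overlap = unname(overlap),
    similarity = similarity,
    zscore = zscore,
    pvalue = pvalue,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (bh) res$padj <- padj
  res$significant <- significant
  res$flagged <- flagged
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL

  attr(res, "metadata") <- list(
    method = method, n_perm = as.integer(n_perm),
    n_nets = if (method == "netpea-prime") as.integer(n_nets) else 0L,
    swap_factor = swap_factor, restart = restart, cutoff = cutoff,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    rr_mode = rr_mode, bh = bh,
    n_input = length(input$genes), n_input_mapped = length(input$mapped),
    n_unscorable = sum(!pathways$scorable)
  )
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Write an enrichment result as annotated TSV
#'
#' Run metadata goes into `#`-prefixed header lines, followed by the
#' tab-separated result table.
#'
#' @param result an `enrichment_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  stopifnot(inherits(result, "enrichment_result"))
  md <- attr(result, "metadata")
  hdr <- vapply(names(md), function(k) {
    paste0("# ", k, ": ", format(md[[k]]))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(as.data.frame(result), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read back an enrichment result TSV
#'
#' @param path file written by [write_enrichment()].
#' @return an `enrichment_result` with metadata restored (as strings).
#' @export
read_enrichment <- function(path) {
  if (!file.exists(path)) stop("result file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^# ", lines, value = TRUE)
  md <- list()
  for (ln in meta_lines) {
    kv <- sub("^# ", "", ln)
    k <- sub(":.*$", "", kv)
    md[[k]] <- trimws(sub("^[^:]*:", "", kv))
  }
  res <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(res, "metadata") <- md
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  md <- attr(x, "metadata")
  cat("enrichment_result (", md$method, "): ", nrow(x), " pathways, ",
      sum(x$significant), " significant\n", sep = "")
  print.data.frame(head(as.data.frame(x), n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  invisible(x)
}
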
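#' Generate a synthetic planted-module scenario
#'
#' Builds a planted-partition benchmark standing in for a real PPI network
#' plus pathway collection: `n_modules` disjoint modules of `module_size`
#' nodes are wired densely (each intra-module pair is an edge with
#' probability `p_in`) on top of a sparse background (every other pair
#' with probability `p_out`). Each module is registered as a pathway, and
#' `n_decoys` additional pathways are uniform random node sets of the same
#' size, so the planted truth is exact and recovery can be scored.
#'
#' @param n_nodes total number of nodes.
#' @param n_modules number of planted modules.
#' @param module_size nodes per module (`n_modules * module_size` must not
#'   exceed `n_nodes`).
#' @param p_in intra-module edge probability (must exceed `p_out`).
#' @param p_out background edge probability.
#' @param n_decoys number of decoy pathways (random node sets of
#'   `module_size` genes).
#' @param seed integer seed; identical seeds reproduce the scenario
#'   exactly.
#' @return object of class `synthetic_scenario`: `network`
#'   (a [gene_network()] over all nodes, isolated ones retained),
#'   `pathways` (a [gene_set_collection()] of planted modules `M1..` and
#'   decoys `D01..`), `truth` (named list: planted pathway id to module
#'   node set) and `params`.
#' @export
generate_scenario <- function(n_nodes = 300L, n_modules = 5L,
                              module_size = 20L, p_in = 0.8, p_out = 0.02,
                              n_decoys = 20L, seed = NULL) {
  if (n_modules * module_size > n_nodes) {
    stop("n_modules * module_size exceeds n_nodes", call. = FALSE)
  }
  if (!(p_in >= 0 && p_in <= 1 && p_out >= 0 && p_out <= 1)) {
    stop("edge probabilities must be in [0, 1]", call. = FALSE)
  }
  if (p_in <= p_out) stop("p_in must exceed p_out", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  nodes <- sprintf("G%04d", seq_len(n_nodes))
  membership <- c(rep(seq_len(n_modules), each = module_size),
                  rep(0L, n_nodes - n_modules * module_size))

  pair <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  same <- membership[pair[, 1]] == membership[pair[, 2]] &
    membership[pair[, 1]] > 0L
  keep <- runif(nrow(pair)) < ifelse(same, p_in, p_out)
  if (!any(keep)) keep[1L] <- TRUE  # degenerate parameters: force one edge
  edges <- cbind(nodes[pair[keep, 1]], nodes[pair[keep, 2]])
  network <- gene_network(edges, nodes = nodes)

  planted <- split(nodes[membership > 0L], membership[membership > 0L])
  names(planted) <- sprintf("M%d", seq_len(n_modules))
  decoys <- lapply(seq_len(n_decoys), function(i) {
    nodes[sample.int(n_nodes, module_size)]
  })
  names(decoys) <- sprintf("D%02d", seq_len(n_decoys))
  pathways <- gene_set_collection(
    members = c(planted, decoys),
    descriptions = c(rep("planted module", n_modules),
                     rep("decoy random set", n_decoys))
  )

  structure(
    list(
      network = network,
      pathways = pathways,
      truth = planted,
      params = list(
        n_nodes = n_nodes, n_modules = n_modules,
        module_size = module_size, p_in = p_in, p_out = p_out,
        n_decoys = n_decoys,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
      )
    ),
    class = "synthetic_scenario"
  )
}

#' Derive an input gene set from a planted scenario
#'
#' Assembles an input gene set carrying a controllable amount of direct
#' overlap with one planted (causal) pathway: `round(overlap_fraction *
#' size)` genes are drawn from the causal module itself and the remainder
#' from the module's network neighbors (`mode = "hidden"` — emulating a
#' causal pathway whose members are mostly upstream/downstream of the
#' observed genes) or from uniform background nodes (`mode = "noise"`).
#' With `overlap_fraction = 0` in hidden mode the input shares no gene
#' with the causal pathway yet remains adjacent to it in the network —
#' the regime where overlap tests fail but propagation-based scores
#' still recover the pathway.
#'
#' @param scenario a [generate_scenario()] result.
#' @param causal_id planted pathway identifier (e.g. `"M1"`).
#' @param overlap_fraction fraction of the input drawn from the causal
#'   module itself, in `[0, 1]`.
#' @param size input gene count; defaults to the module size.
#' @param mode `"hidden"` (module neighbors) or `"noise"` (background).
#' @return an [input_gene_set()].
#' @export
make_input_set <- function(scenario, causal_id, overlap_fraction = 1,
                           size = NULL, mode = c("hidden", "noise")) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  mode <- match.arg(mode)
  module <- scenario$truth[[causal_id]]
  if (is.null(module)) {
    stop("unknown planted pathway: ", causal_id, call. = FALSE)
  }
  if (!(overlap_fraction >= 0 && overlap_fraction <= 1)) {
    stop("overlap_fraction must be in [0, 1]", call. = FALSE)
  }
  if (is.null(size)) size <- length(module)
  if (size < 1L) stop("size must be >= 1", call. = FALSE)

  n_overlap <- min(round(overlap_fraction * size), length(module))
  chosen <- if (n_overlap > 0L) sample(module, n_overlap) else character()

  n_rest <- size - n_overlap
  if (n_rest > 0L) {
    net <- scenario$network
    if (mode == "hidden") {
      midx <- match(module, net$nodes)
      touch <- net$edges[, 1] %in% midx | net$edges[, 2] %in% midx
      nb <- net$nodes[unique(as.vector(net$edges[touch, , drop = FALSE]))]
      pool <- setdiff(nb, c(module, chosen))
    } else {
      pool <- setdiff(net$nodes, c(module, chosen))
    }
    if (length(pool) < n_rest) {
      warning("not enough neighbor candidates; topping up from background",
              call. = FALSE)
      extra <- setdiff(net$nodes, c(module, chosen, pool))
      pool <- c(pool, sample(extra, min(length(extra),
                                        n_rest - length(pool))))
    }
    chosen <- c(chosen, sample(pool, min(n_rest, length(pool))))
  }

  out <- input_gene_set(chosen)
  out$mapped <- out$genes
  out
}

#' Write a scenario as a runnable example directory
#'
#' Emits the edge-list, GMT and (optionally) input gene-list files in the
#' same formats the command-line interface consumes, plus a YAML record of
#' the generation parameters.
#'
#' @param scenario a [generate_scenario()] result.
#' @param dir output directory (created if needed).
#' @param input optional [input_gene_set()] written as `input.txt`.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir, input = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edge_list(scenario$network, file.path(dir, "network.tsv"))
  write_gmt(scenario$pathways, file.path(dir, "pathways.gmt"))
  yaml::write_yaml(scenario$params, file.path(dir, "params.yaml"))
  if (!is.null(input)) {
    writeLines(input$genes, file.path(dir, "input.txt"))
  }
  invisible(dir)
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  p <- x$params
  cat("synthetic_scenario:", p$n_nodes, "nodes,", p$n_modules,
      "planted modules of", p$module_size, "+", p$n_decoys, "decoys\n")
  invisible(x)
}
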
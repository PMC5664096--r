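# Small random test networks built in code; no fixture files needed.

# Erdos-Renyi-ish network on n labelled nodes; optionally patch isolated
# nodes by attaching each to a random partner so that mass-conservation
# holds exactly.
random_test_network <- function(n, p = 0.08, no_isolated = TRUE) {
  nodes <- sprintf("n%03d", seq_len(n))
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pair)) < p
  if (!any(keep)) keep[1L] <- TRUE
  edges <- cbind(nodes[pair[keep, 1]], nodes[pair[keep, 2]])
  net <- suppressMessages(gene_network(edges, nodes = nodes))
  if (no_isolated) {
    iso <- which(net$degree == 0L)
    if (length(iso) > 0L) {
      extra <- cbind(
        nodes[iso],
        vapply(iso, function(i) nodes[sample(setdiff(seq_len(n), i), 1L)],
               character(1))
      )
      net <- suppressMessages(gene_network(rbind(edges, extra),
                                           nodes = nodes))
    }
  }
  net
}

triangle_network <- function() {
  suppressMessages(gene_network(rbind(c("A", "B"), c("B", "C"),
                                      c("A", "C"))))
}

# Exhaustive hypergeometric upper tail by enumerating every possible draw.
brute_force_upper_tail <- function(overlap, input_size, pathway_size,
                                   universe) {
  draws <- utils::combn(universe, input_size)
  hits <- colSums(draws <= pathway_size)  # pathway = elements 1..K
  mean(hits >= overlap)
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
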
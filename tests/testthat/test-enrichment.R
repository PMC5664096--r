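test_that("permutation z-score matches hand arithmetic", {
  expect_equal(netpea_zscore(2, c(1, 3)), 0)
  expect_equal(netpea_zscore(5, c(1, 3)), 3 / sqrt(2), tolerance = 1e-12)
  expect_true(is.na(netpea_zscore(1, c(2, 2, 2))))
  expect_error(netpea_zscore(1, c(2)), "at least 2")
  # invariance under common rescaling (scores scale with seed count, z not)
  set.seed(1)
  R <- runif(20)
  expect_equal(netpea_zscore(0.7, R), netpea_zscore(7, 10 * R),
               tolerance = 1e-12)
})

test_that("network-corrected z-score matches hand arithmetic", {
  # C = RN - colMeans(RR) = {0, 2}; z = ((4 - 2) - 1) / sqrt(2)
  expect_equal(
    netpea_prime_zscore(4, 2, c(1, 3), matrix(c(1, 1), nrow = 1)),
    1 / sqrt(2), tolerance = 1e-12
  )
  # identity rewiring degenerates: C is the zero vector
  expect_true(is.na(
    netpea_prime_zscore(4, c(4, 4), c(1, 3),
                        matrix(c(1, 3, 1, 3), nrow = 2, byrow = TRUE))
  ))
  # grand-mean mode differs when RR varies within a network:
  # paired C = {0, 0} (flagged), grand C = {-1, 1}, z = 2 / sqrt(2)
  RR <- matrix(c(1, 3), nrow = 1)
  expect_true(is.na(netpea_prime_zscore(4, 2, c(1, 3), RR,
                                        mode = "paired")))
  expect_equal(netpea_prime_zscore(4, 2, c(1, 3), RR, mode = "grand"),
               sqrt(2), tolerance = 1e-12)
  expect_error(netpea_prime_zscore(4, c(2, 2), c(1, 3), RR), "dimensions")
})

test_that("z-to-p conversion is the one-sided upper normal tail", {
  expect_equal(z_to_p(0), 0.5)
  expect_equal(round(z_to_p(1.65), 2), 0.05)
  zs <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(z_to_p(zs)) < 0))
  expect_true(all(abs(z_to_p(zs) + z_to_p(-zs) - 1) < 1e-12))
})

test_that("ORA p-values match exact combinatorics", {
  expect_equal(ora_pvalue(0, 5, 5, 10), 1)
  expect_equal(ora_pvalue(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  # brute-force enumeration oracle on a non-trivial configuration
  for (q in 0:5) {
    expect_equal(ora_pvalue(q, 5, 5, 10),
                 brute_force_upper_tail(q, 5, 5, 10), tolerance = 1e-12)
  }
  expect_equal(ora_pvalue(3, 4, 6, 12),
               brute_force_upper_tail(3, 4, 6, 12), tolerance = 1e-12)
  expect_error(ora_pvalue(6, 5, 5, 10), "inconsistent")
  expect_error(ora_pvalue(2, 11, 5, 10), "inconsistent")
})

test_that("end-to-end enrichment is deterministic and well-ranked", {
  sc <- generate_scenario(n_nodes = 120, n_modules = 3, module_size = 10,
                          p_in = 0.9, p_out = 0.03, n_decoys = 8,
                          seed = 101)
  input <- make_input_set(sc, "M2", overlap_fraction = 1)
  res1 <- suppressMessages(run_enrichment(
    sc$network, sc$pathways, input, method = "netpea", n_perm = 50,
    seed = 202))
  res2 <- suppressMessages(run_enrichment(
    sc$network, sc$pathways, input, method = "netpea", n_perm = 50,
    seed = 202))
  expect_identical(res1, res2)

  expect_equal(res1$pathway_id[1], "M2")  # self-recovery
  expect_equal(sort(res1$rank), seq_len(nrow(res1)))
  expect_equal(res1$significant,
               res1$zscore > 1.65 & !res1$flagged)
  expect_equal(res1$pvalue, z_to_p(res1$zscore) * (!res1$flagged) +
                 1 * res1$flagged, tolerance = 1e-12)
  # similarity of the causal pathway at full overlap: each member >= p
  expect_gte(res1$similarity[1], 0.5)
})

test_that("ORA with a disjoint input calls nothing significant", {
  net <- suppressMessages(gene_network(rbind(c("A", "B"), c("C", "D"),
                                             c("E", "F"))))
  sets <- gene_set_collection(list(P1 = c("A", "B"), P2 = c("C", "D")))
  res <- suppressMessages(run_enrichment(net, sets, c("E", "F"),
                                         method = "ora"))
  expect_true(all(res$pvalue == 1))
  expect_false(any(res$significant))
  expect_true(all(res$overlap == 0))
})

test_that("un-rewired netpea-prime flags every pathway (zero variance)", {
  sc <- generate_scenario(n_nodes = 80, n_modules = 2, module_size = 8,
                          p_in = 0.9, p_out = 0.05, n_decoys = 3,
                          seed = 303)
  input <- make_input_set(sc, "M1", overlap_fraction = 1)
  res <- suppressMessages(suppressWarnings(run_enrichment(
    sc$network, sc$pathways, input, method = "netpea-prime", n_perm = 20,
    n_nets = 2, swap_factor = 0, seed = 404)))
  expect_true(all(res$flagged))
  expect_true(all(res$zscore == 0))
  expect_true(all(res$pvalue == 1))
  expect_false(any(res$significant))
  # flagged pathways are ordered lexicographically at the tail
  expect_equal(res$pathway_id, sort(res$pathway_id))
})

test_that("BH adjustment is applied behind the flag", {
  sc <- generate_scenario(n_nodes = 100, n_modules = 2, module_size = 10,
                          p_in = 0.9, p_out = 0.03, n_decoys = 6,
                          seed = 505)
  input <- make_input_set(sc, "M1", overlap_fraction = 1)
  res <- suppressMessages(run_enrichment(
    sc$network, sc$pathways, input, method = "netpea", n_perm = 50,
    seed = 606, bh = TRUE))
  expect_true("padj" %in% names(res))
  ord <- order(res$pathway_id)
  expect_equal(res$padj[ord],
               p.adjust(res$pvalue, "BH")[ord], tolerance = 1e-12)
  expect_equal(res$significant, res$padj <= 0.05 & !res$flagged)
})

test_that("result TSV round-trips through write and read", {
  sc <- generate_scenario(n_nodes = 80, n_modules = 2, module_size = 8,
                          p_in = 0.9, p_out = 0.04, n_decoys = 4,
                          seed = 707)
  input <- make_input_set(sc, "M1", overlap_fraction = 1)
  res <- suppressMessages(run_enrichment(
    sc$network, sc$pathways, input, method = "netpea", n_perm = 30,
    seed = 808))
  path <- tempfile(fileext = ".tsv")
  write_enrichment(res, path)
  back <- read_enrichment(path)
  expect_equal(back$pathway_id, res$pathway_id)
  expect_equal(back$zscore, res$zscore, tolerance = 1e-6)
  expect_equal(attr(back, "metadata")$method, "netpea")
})
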
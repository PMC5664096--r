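test_that("random gene sets are uniform samples of network nodes", {
  net <- triangle_network()
  full <- sample_random_gene_set(net, 3)
  expect_setequal(full$genes, net$nodes)
  expect_equal(full$mapped, full$genes)

  expect_error(sample_random_gene_set(net, 0), "size")
  expect_error(sample_random_gene_set(net, 4), "size")

  set.seed(123)
  net10 <- random_test_network(10, p = 0.3)
  draws <- replicate(10000, sample_random_gene_set(net10, 1)$genes)
  freq <- table(factor(draws, levels = net10$nodes)) / 10000
  expect_true(all(abs(freq - 0.1) < 0.01))
})

test_that("degree-matched sampling tracks the reference degrees", {
  set.seed(5)
  net <- random_test_network(100, p = 0.06)
  ref <- names(sort(net$degree, decreasing = TRUE))[1:10]  # hubs
  draws <- replicate(50, {
    mean(net$degree[sample_random_gene_set(net, 10, degree_matched = TRUE,
                                           reference = ref)$genes])
  })
  uniform <- replicate(50, {
    mean(net$degree[sample_random_gene_set(net, 10)$genes])
  })
  expect_gt(mean(draws), mean(uniform))
})

test_that("rewiring preserves every node's degree exactly", {
  set.seed(17)
  for (trial in 1:20) {
    net <- random_test_network(30, p = 0.12)
    rew <- rewire_network(net, swap_factor = 10)
    expect_identical(rew$degree, net$degree)
    # simple graph: no self-loops, no duplicates
    expect_true(all(rew$edges[, 1] < rew$edges[, 2]))
    expect_false(anyDuplicated(rew$edges) > 0)
    expect_equal(nrow(rew$edges), nrow(net$edges))
  }
})

test_that("degenerate graphs are returned unchanged with a warning", {
  single <- suppressMessages(gene_network(rbind(c("A", "B"))))
  expect_warning(rew <- rewire_network(single, swap_factor = 10),
                 "fewer than 2 edges")
  expect_identical(rew$edges, single$edges)

  star <- suppressMessages(gene_network(cbind("H", paste0("L", 1:5))))
  set.seed(3)
  expect_warning(rew2 <- rewire_network(star, swap_factor = 2),
                 "no valid edge swap")
  expect_identical(rew2$edges, star$edges)
})

test_that("swap_factor zero is the identity and a 4-cycle stays 2-regular", {
  net <- triangle_network()
  expect_identical(rewire_network(net, swap_factor = 0)$edges, net$edges)

  cyc <- suppressMessages(gene_network(rbind(c("A", "B"), c("B", "C"),
                                             c("C", "D"), c("A", "D"))))
  set.seed(9)
  for (i in 1:10) {
    rew <- suppressWarnings(rewire_network(cyc, swap_factor = 5))
    expect_equal(unname(rew$degree), rep(2L, 4))
    expect_false(anyDuplicated(rew$edges) > 0)
    expect_true(all(rew$edges[, 1] != rew$edges[, 2]))
  }
})

test_that("null ensembles have the documented shapes", {
  set.seed(31)
  net <- random_test_network(30, p = 0.15)
  sets <- suppressMessages(map_to_network(
    gene_set_collection(list(P1 = net$nodes[1:5])), net))
  input <- sample_random_gene_set(net, 4)
  rew <- list(rewire_network(net, swap_factor = 5))
  ens <- build_null_ensembles(net, sets, input, n_perm = 2, rewired = rew)
  expect_equal(names(ens$DN), "P1")
  expect_equal(dim(ens$RN), c(1L, 2L))
  expect_equal(dim(ens$DR), c(1L, 1L))
  expect_equal(dim(ens$RR), c(1L, 1L, 2L))
  expect_true(all(is.finite(unlist(ens[c("DN", "DR", "RN", "RR")]))))
  expect_true(all(unlist(ens[c("DN", "DR", "RN", "RR")]) >= 0))
  expect_error(build_null_ensembles(net, sets, input, n_perm = 1), "n_perm")
})

test_that("identity rewiring makes DR equal DN exactly", {
  set.seed(41)
  net <- random_test_network(25, p = 0.2)
  sets <- suppressMessages(map_to_network(
    gene_set_collection(list(P1 = net$nodes[1:6], P2 = net$nodes[7:12])),
    net))
  input <- sample_random_gene_set(net, 5)
  rew <- list(rewire_network(net, swap_factor = 0),
              rewire_network(net, swap_factor = 0))
  ens <- build_null_ensembles(net, sets, input, n_perm = 3, rewired = rew)
  expect_equal(unname(ens$DR[, 1]), unname(ens$DN))
  expect_equal(unname(ens$DR[, 2]), unname(ens$DN))
  # paired replicates: RR equals RN on identical networks
  expect_equal(unname(ens$RR[, 1, ]), unname(ens$RN))
})

test_that("ensembles are bit-identical under the same seed", {
  net <- random_test_network(25, p = 0.2)
  sets <- suppressMessages(map_to_network(
    gene_set_collection(list(P1 = net$nodes[1:6])), net))
  input <- input_gene_set(net$nodes[10:14])
  run <- function() {
    set.seed(99)
    rew <- list(rewire_network(net, swap_factor = 5))
    suppressMessages(
      build_null_ensembles(net, sets, input, n_perm = 5, rewired = rew))
  }
  expect_identical(run(), run())
})

test_that("a random input's observed score is exchangeable with its null", {
  set.seed(55)
  net <- random_test_network(60, p = 0.08)
  sets <- suppressMessages(map_to_network(
    gene_set_collection(list(P1 = net$nodes[1:10])), net))
  n_perm <- 50
  ranks <- replicate(100, {
    input <- sample_random_gene_set(net, 5)
    ens <- build_null_ensembles(net, sets, input, n_perm = n_perm)
    (sum(ens$RN[1, ] < ens$DN[1]) + 0.5 * sum(ens$RN[1, ] == ens$DN[1])) /
      n_perm
  })
  expect_gt(mean(ranks), 0.35)
  expect_lt(mean(ranks), 0.65)
})
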
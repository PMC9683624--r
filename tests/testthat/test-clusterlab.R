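test_that("spectral clustering recovers planted blocks exactly", {
  A <- planted_blocks(c(4, 5))
  truth <- cluster_assignment(stats::setNames(attr(A, "truth"), rownames(A)))
  got <- spectral_cluster(A, k = 2)
  expect_true(same_partition(got, truth))
  expect_error(spectral_cluster(A, k = 20), "exceeds")
})

test_that("spectral clustering is invariant under node permutation", {
  A <- planted_blocks(c(3, 4, 3), noise_sd = 0.02, seed = 2)
  set.seed(5); perm <- sample(nrow(A))
  B <- A[perm, perm]
  a <- spectral_cluster(A, k = 3)
  b <- spectral_cluster(B, k = 3)
  expect_true(same_partition(a, b))
})

test_that("noisy planted blocks are recovered across seeds (with an independent cross-check)", {
  truth_lab <- NULL
  for (s in 1:20) {
    A <- planted_blocks(c(4, 4, 4), noise_sd = 0.05, seed = s)
    truth <- cluster_assignment(stats::setNames(attr(A, "truth"), rownames(A)))
    got <- spectral_cluster(A, k = 3, seed = s)
    expect_true(same_partition(got, truth))
  }
  # independent implementation agrees on a clean instance
  skip_if_not_installed("kernlab")
  A <- planted_blocks(c(4, 4, 4), noise_sd = 0.02, seed = 1)
  set.seed(1)
  ks <- kernlab::specc(kernlab::as.kernelMatrix(A + 1e-6 * diag(nrow(A))),
                       centers = 3)
  ref <- cluster_assignment(stats::setNames(as.integer(ks), rownames(A)))
  expect_true(same_partition(spectral_cluster(A, k = 3), ref))
})

test_that("the eigengap heuristic picks the planted block count", {
  A <- planted_blocks(c(5, 5, 5), noise_sd = 0.02, seed = 3)
  got <- spectral_cluster(A, k = "auto")
  expect_equal(got$parameters$k, 3)
})

test_that("markov clustering separates components and respects loop gain", {
  A <- planted_blocks(c(3, 3))
  got <- mcl(A)  # defaults: inflation 2.0, loop gain 0, thresholds 1e-7
  expect_equal(length(unique(got$membership)), 2)
  truth <- cluster_assignment(stats::setNames(attr(A, "truth"), rownames(A)))
  expect_true(same_partition(got, truth))
  # identity matrix with loop gain 0.5: every node its own attractor
  singletons <- mcl(diag(6), mcl_config(loop_gain = 0.5))
  expect_equal(length(unique(singletons$membership)), 6)
  # output is a partition: every node appears exactly once
  expect_setequal(names(got$membership), rownames(A))
  expect_error(mcl_config(inflation = 1), "> 1")
})

test_that("clustering Jaccard similarity matches hand-enumerated cases", {
  A <- cluster_assignment(c(n1 = 1, n2 = 1, n3 = 2, n4 = 2))
  B <- cluster_assignment(c(n1 = 1, n2 = 1, n3 = 1, n4 = 1))
  S <- cluster_assignment(c(n1 = 1, n2 = 2, n3 = 3, n4 = 4))
  expect_equal(jaccard_clustering_similarity(A, A), 1)
  expect_equal(jaccard_clustering_similarity(A, B), 0.5)
  expect_equal(jaccard_clustering_similarity(B, S), 0.25)
  # symmetry, and 1 iff identical partitions
  expect_equal(jaccard_clustering_similarity(A, B),
               jaccard_clustering_similarity(B, A))
  expect_lt(jaccard_clustering_similarity(A, S), 1)
  relabeled <- cluster_assignment(c(n1 = 9, n2 = 9, n3 = 7, n4 = 7))
  expect_equal(jaccard_clustering_similarity(A, relabeled), 1)
  expect_error(jaccard_clustering_similarity(
    A, cluster_assignment(c(x = 1, n2 = 1, n3 = 2, n4 = 2))),
    "different node sets")
})

test_that("sweep grids enumerate inclusive endpoints in a deterministic order", {
  expect_equal(n_combinations(sweep_preset("gm_2param")), 16)
  expect_equal(n_combinations(sweep_preset("gm_4param")), 256)
  expect_equal(n_combinations(sweep_preset("mm_540")), 540)
  expect_equal(n_combinations(sweep_preset("mm_375")), 375)
  expect_equal(n_combinations(sweep_grid(a = list(c(1)))), 1)
  g <- sweep_grid(x = c(1, 3, 1), y = c(10, 20, 10))
  # lexicographic order, first parameter fastest; index <-> tuple bijection
  expect_equal(g$combinations$x, rep(c(1, 2, 3), 2))
  expect_equal(g$combinations$y, rep(c(10, 20), each = 3))
  expect_equal(nrow(unique(g$combinations)), 6)
  g2 <- sweep_grid(x = c(1, 3, 1), y = c(10, 20, 10))
  expect_identical(g$combinations, g2$combinations)
})

test_that("a small sweep produces consistent matrices and clustering similarities", {
  cn <- random_graph(n = 6, m = 15, seed = 4)
  grid <- sweep_grid(sigmaA = c(0.002, 0.004, 0.002), muA = list(c(0.03)))
  res <- run_sweep(grid, gm_model(Du = 0.01, Dv = 0.01), cn,
                   init = list(u = rep(2, 6) + 0.05 * (1:6), v = rep(4, 6)),
                   solver = solver_config(dt = 2, n_steps = 800,
                                          record_every = 4),
                   clustering = "spectral", k = 2)
  expect_equal(run_sweep(grid, gm_model(), cn, init = c(2, 4),
                         dry_run = TRUE), 2)
  expect_length(res$matrices, 2)
  # averaged matrix equals the recomputed mean of stored matrices
  expect_equal(as.matrix(res$average_matrix),
               (as.matrix(res$matrices[[1]]) +
                as.matrix(res$matrices[[2]])) / 2)
  CS <- res$clustering_similarity
  expect_equal(diag(CS), c(1, 1))
  expect_equal(CS[1, 2], CS[2, 1])
  expect_equal(CS[1, 2],
               jaccard_clustering_similarity(res$clusterings[[1]],
                                             res$clusterings[[2]]))
})
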
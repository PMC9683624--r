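test_that("cross-correlation recovers exact relationships of constructed signals", {
  tt <- seq(0, 8 * pi, length.out = 1601)[-1601]  # whole periods
  tr <- mk_traj(u = rbind(sin(tt), cos(tt), -sin(tt), sin(tt)))
  C <- as.matrix(cross_correlation_matrix(tr, transient = 0))
  expect_equal(unname(diag(C)), rep(1, 4))
  expect_equal(C[1, 4], 1)
  expect_equal(C[1, 3], -1)
  expect_lt(abs(C[1, 2]), 1e-10)  # sin vs cos orthogonal over whole periods
  expect_true(isSymmetric(C))
})

test_that("constant series get zero correlation with a warning", {
  tr <- mk_traj(u = rbind(sin(1:100), rep(2, 100)))
  expect_warning(C <- cross_correlation_matrix(tr, transient = 0),
                 "zero-variance")
  M <- as.matrix(C)
  expect_equal(M[1, 2], 0)
  expect_equal(unname(diag(M)), c(1, 1))
})

test_that("averaged sweep matrices equal the entrywise mean", {
  set.seed(1)
  mats <- lapply(1:3, function(i) {
    tr <- mk_traj(u = matrix(rnorm(5 * 60), 5))
    cross_correlation_matrix(tr, transient = 0)
  })
  avg <- average_similarity(mats)
  expect_equal(as.matrix(avg),
               (as.matrix(mats[[1]]) + as.matrix(mats[[2]]) +
                as.matrix(mats[[3]])) / 3)
})

test_that("the Kuramoto order parameter reflects phase coherence", {
  tt <- seq(0, 40 * pi, length.out = 4000)
  same <- mk_traj(u = rbind(sin(tt), sin(tt), sin(tt)))
  expect_gt(kuramoto_order(same, transient = 0)$mean_r, 1 - 1e-6)
  anti <- mk_traj(u = rbind(sin(tt), -sin(tt)))
  expect_lt(kuramoto_order(anti, transient = 0)$mean_r, 0.05)
  quad <- mk_traj(u = rbind(sin(tt), sin(tt + pi / 2), sin(tt + pi),
                            sin(tt + 3 * pi / 2)))
  expect_lt(kuramoto_order(quad, transient = 0)$mean_r, 0.05)
})

test_that("the Kuramoto order parameter stays in [0, 1] on random trajectories", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    M <- matrix(rnorm(n * 400), n)
    M <- t(apply(M, 1, cumsum))  # smooth-ish random walks
    r <- kuramoto_order(mk_traj(u = M), transient = 0.1)$r
    expect_true(all(r >= 0 & r <= 1 + 1e-12))
  }
  # constant nodes are excluded with a warning
  tt <- seq(0, 20 * pi, length.out = 1000)
  expect_warning(
    r <- kuramoto_order(mk_traj(u = rbind(sin(tt), sin(tt), rep(1, 1000))),
                        transient = 0),
    "excluded")
  expect_gt(r$mean_r, 0.99)
})

test_that("co-activation scores binarized overlap as a Jaccard fraction", {
  a <- rep(c(5, 0), each = 50)                 # active first half
  b <- rep(c(5, 0, 5, 0), c(25, 25, 25, 25))   # active half of that window
  tr <- mk_traj(u = rbind(a, a, b))
  C <- as.matrix(coactivation_matrix(tr, transient = 0))
  expect_equal(C[1, 2], 1)            # identical series
  # overlap 25 bins, union 75 bins -> 1/3
  expect_equal(C[1, 3], 1 / 3)
  disj <- mk_traj(u = rbind(rep(c(5, 0), each = 50), rep(c(0, 5), each = 50)))
  expect_equal(as.matrix(coactivation_matrix(disj, transient = 0))[1, 2], 0)
  # two pulses: active 1-60 and 21-80 -> overlap 40 bins, union 80 -> 0.5
  p1 <- rep(c(5, 0), c(60, 40))
  p2 <- rep(c(0, 5, 0), c(20, 60, 20))
  half <- mk_traj(u = rbind(p1, p2))
  expect_equal(as.matrix(coactivation_matrix(half, transient = 0))[1, 2], 0.5)
})

test_that("local graph metrics match their defining cases", {
  ids <- paste0("n", 1:4)
  full <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  full <- full[full$source != full$target, ]
  full$weight <- 1
  K4 <- connectome(ids, full)
  m <- local_graph_metrics(K4)
  expect_equal(m$CluC_out, rep(1, 4))  # saturated out-neighbourhoods
  expect_equal(m$DGinDGall, rep(0.5, 4))
  star <- connectome(c("hub", "a", "b"),
                     data.frame(source = c("a", "b"), target = "hub",
                                weight = 1))
  ms <- local_graph_metrics(star)
  expect_equal(ms$DGinDGall[ms$node == "hub"], 1)   # only afferents
  expect_equal(ms$DGinDGall[ms$node == "a"], 0)     # only efferents
  # identical out-neighbourhoods give pairwise matching 1
  M <- as.matrix(matching_matrix(star, "out"))
  expect_equal(M["a", "b"], 1)
  # ranks use average ties
  expect_equal(sort(unique(m$rank_deg_all)), 2.5)
})

test_that("modularity partitioning recovers planted modules", {
  clique <- function(ids) {
    e <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
    e <- e[e$source != e$target, ]; e$weight <- 1; e
  }
  ids1 <- paste0("a", 1:5); ids2 <- paste0("b", 1:5)
  two <- connectome(c(ids1, ids2), rbind(clique(ids1), clique(ids2)))
  p2 <- modularity_partition(two)
  expect_equal(length(unique(p2$membership)), 2)
  expect_true(same_partition(p2, cluster_assignment(
    stats::setNames(rep(1:2, each = 5), c(ids1, ids2)))))
  # ring of 3 weakly-linked 6-cliques
  idsl <- lapply(1:3, function(i) paste0("c", i, "_", 1:6))
  bridge <- data.frame(source = c("c1_1", "c2_1", "c3_1"),
                       target = c("c2_2", "c3_2", "c1_2"), weight = 0.1)
  ring <- connectome(unlist(idsl), rbind(do.call(rbind, lapply(idsl, clique)),
                                         bridge))
  p3 <- modularity_partition(ring)
  expect_equal(length(unique(p3$membership)), 3)
  expect_gt(p3$Q, 0)  # better than the trivial one-module partition (Q = 0)
})
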
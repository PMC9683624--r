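# Wrap per-node series matrices into a trajectory object for analysis tests.
mk_traj <- function(...) {
  mats <- list(...)
  if (is.null(names(mats)) || any(names(mats) == "")) names(mats) <- "u"
  M <- mats[[1]]
  if (is.null(rownames(M)))
    for (s in names(mats)) rownames(mats[[s]]) <- paste0("n", seq_len(nrow(M)))
  structure(list(times = seq_len(ncol(M)), states = mats,
                 metadata = list(model = "synthetic")),
            class = "rd_trajectory")
}

# Two-node graph with a single directed edge A -> B.
two_node <- function(w = 1)
  connectome(c("A", "B"),
             data.frame(source = "A", target = "B", weight = w))

# Seeded random directed weighted graph without self-loops or duplicates.
random_graph <- function(n = 6, m = 12, seed = 1) {
  set.seed(seed)
  ids <- paste0("v", seq_len(n))
  pairs <- expand.grid(s = ids, t = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$s != pairs$t, ]
  pick <- pairs[sample.int(nrow(pairs), m), ]
  connectome(ids, data.frame(source = pick$s, target = pick$t,
                             weight = runif(m, 0.1, 1)))
}

# Linear relay chain A -> E1..Ek -> B realizing the distance-node kinetics.
relay_chain <- function(k = 1, D = 0.1, theta = 1)
  insert_distance_nodes(two_node(), D = D, theta = theta,
                        relay_counts = k)$connectome

# Zero-reaction simulation of species u on a connectome.
diffuse <- function(cn, u0, solver) {
  rd_simulate(diffusion_model(1), cn, init = list(u = u0), solver = solver)
}

# Block-structured affinity matrix with optional symmetric noise.
planted_blocks <- function(sizes, noise_sd = 0, seed = 1) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  A <- outer(lab, lab, `==`) * 1
  if (noise_sd > 0) {
    set.seed(seed)
    E <- matrix(rnorm(n * n, sd = noise_sd), n)
    A <- A + (E + t(E)) / 2
    A <- pmin(pmax(A, 0), 1)
  }
  dimnames(A) <- list(paste0("n", 1:n), paste0("n", 1:n))
  attr(A, "truth") <- lab
  A
}

# Agreement of two partitions up to label permutation.
same_partition <- function(a, b) {
  isTRUE(all.equal(jaccard_clustering_similarity(a, b), 1))
}
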
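#' Cluster assignment
#'
#' @param membership named integer vector: node id -> cluster id; every node
#'   belongs to exactly one cluster.
#' @param method label of the producing algorithm.
#' @param parameters optional parameter list.
#' @export
cluster_assignment <- function(membership, method = "unknown",
                               parameters = list()) {
  if (is.null(names(membership)) || anyDuplicated(names(membership)))
    stop("membership must be a named vector with unique node names")
  structure(list(membership = membership, method = method,
                 parameters = parameters),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  k <- length(unique(x$membership))
  cat("<cluster_assignment> ", x$method, ": ", length(x$membership),
      " nodes in ", k, " clusters\n", sep = "")
  if (!is.null(x$Q)) cat("  modularity Q =", format(x$Q, digits = 4), "\n")
  invisible(x)
}

# Partition as a list of node-name sets.
.clusters_of <- function(a) {
  split(names(a$membership), a$membership)
}

#' Map correlations to a nonnegative affinity
#'
#' Correlation-type similarities in [-1, 1] are mapped to [0, 1] via
#' \code{(1 + c)/2} before spectral or Markov clustering (both require
#' nonnegative input). Matrices that are already nonnegative are returned
#' unchanged.
#'
#' @param M numeric matrix.
#' @export
affinity_from_correlation <- function(M) {
  M <- as.matrix(M)
  if (any(M < 0)) (1 + M) / 2 else M
}

#' Spectral clustering of a similarity matrix
#'
#' Normalized-Laplacian spectral embedding (symmetric normalization
#' D^{-1/2} A D^{-1/2}, top-k eigenvectors, row-normalized) followed by
#' k-means with a fixed seed. Negative similarities are first shifted into
#' a nonnegative affinity via \code{\link{affinity_from_correlation}}.
#' With \code{k = "auto"} the cluster count is chosen by the eigengap
#' heuristic (largest gap among the leading normalized-Laplacian
#' eigenvalues).
#'
#' @param sim a \code{similarity_matrix} or symmetric numeric matrix.
#' @param k integer cluster count, or \code{"auto"}.
#' @param seed seed for the k-means initialization.
#' @param max_k ceiling for the eigengap search.
#' @return a \code{\link{cluster_assignment}}.
#' @export
spectral_cluster <- function(sim, k = "auto", seed = 1, max_k = 10) {
  A <- affinity_from_correlation(as.matrix(sim))
  if (!isSymmetric(unname(A), tol = 1e-8)) stop("similarity matrix must be symmetric")
  n <- nrow(A)
  if (is.numeric(k) && k > n) stop("k exceeds the number of nodes")
  diag(A) <- 0
  d <- rowSums(A)
  d[d == 0] <- 1e-12
  Dm <- 1 / sqrt(d)
  Lsym <- diag(n) - (Dm * A) %*% diag(Dm)  # I - D^-1/2 A D^-1/2
  eig <- eigen(Lsym, symmetric = TRUE)
  lam <- rev(eig$values)             # ascending
  vecs <- eig$vectors[, n:1, drop = FALSE]
  if (identical(k, "auto")) {
    kk <- min(max_k, n - 1)
    gaps <- diff(lam[seq_len(kk + 1)])
    k <- which.max(gaps)
    if (k < 2) k <- max(2, k)
  }
  U <- vecs[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
  U <- U / rn
  set.seed(seed)
  km <- stats::kmeans(U, centers = k, nstart = 20, iter.max = 100)
  cluster_assignment(stats::setNames(km$cluster, rownames(A)),
                     method = "spectral",
                     parameters = list(k = k, seed = seed))
}

#' Markov clustering configuration
#'
#' Defaults follow the standard parameter set: values below
#' \code{zero_threshold} are treated as zero each round; iteration stops
#' when successive iterates differ by less than \code{equal_threshold}
#' entrywise; \code{loop_gain} > 0 sets every diagonal entry to that value
#' before the iteration starts; the inflation exponent is applied elementwise
#' with column renormalization.
#'
#' @param zero_threshold maximum value considered zero (default 1e-7).
#' @param equal_threshold maximum difference for convergence (default 1e-7).
#' @param loop_gain diagonal (self-connection) value, >= 0 (default 0).
#' @param inflation inflation exponent, > 1 (default 2).
#' @param max_iter iteration cap.
#' @export
mcl_config <- function(zero_threshold = 1e-7, equal_threshold = 1e-7,
                       loop_gain = 0, inflation = 2.0, max_iter = 100) {
  if (zero_threshold < 0 || equal_threshold < 0 || loop_gain < 0)
    stop("thresholds and loop gain must be >= 0")
  if (inflation <= 1) stop("inflation must be > 1")
  list(zero_threshold = zero_threshold, equal_threshold = equal_threshold,
       loop_gain = loop_gain, inflation = inflation,
       max_iter = as.integer(max_iter))
}

#' Markov clustering (MCL)
#'
#' Alternates expansion (matrix squaring) and inflation (elementwise power
#' with column renormalization) on the column-stochastic similarity matrix
#' until successive iterates are equal to within \code{equal_threshold}.
#' Input values are normalized to [0, 1] (dividing by the maximum);
#' correlations are first shifted via
#' \code{\link{affinity_from_correlation}}. Clusters are the connected
#' components of the nonzero structure of the limit matrix.
#'
#' @param sim a \code{similarity_matrix} or nonnegative numeric matrix.
#' @param cfg an \code{\link{mcl_config}}.
#' @return a \code{\link{cluster_assignment}}.
#' @export
mcl <- function(sim, cfg = mcl_config()) {
  A <- affinity_from_correlation(as.matrix(sim))
  n <- nrow(A)
  mx <- max(A)
  if (mx > 0) A <- A / mx
  if (cfg$loop_gain > 0) diag(A) <- cfg$loop_gain
  A[A < cfg$zero_threshold] <- 0
  normalize_cols <- function(M) {
    cs <- colSums(M)
    cs[cs == 0] <- 1
    sweep(M, 2, cs, "/")
  }
  M <- normalize_cols(A)
  for (it in seq_len(cfg$max_iter)) {
    Mexp <- M %*% M
    Minf <- normalize_cols(Mexp^cfg$inflation)
    Minf[Minf < cfg$zero_threshold] <- 0
    Minf <- normalize_cols(Minf)
    delta <- max(abs(Minf - M))
    M <- Minf
    if (delta < cfg$equal_threshold) break
    if (it == cfg$max_iter)
      stop("MCL did not converge after ", cfg$max_iter,
           " iterations (max entry change ", format(delta), ")")
  }
  adj <- (M > 0) | (t(M) > 0)
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  ids <- rownames(A)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  cluster_assignment(stats::setNames(as.integer(comp), ids), method = "mcl",
                     parameters = cfg)
}

#' Average Jaccard similarity of two clusterings
#'
#' For clusterings A and B of the same node set, every cluster X of A is
#' matched with the cluster Y of B maximizing the Jaccard coefficient
#' J(X, Y) = |X n Y| / |X u Y| (and symmetrically for B against A); the
#' similarity is
#' \deqn{\frac{\sum_{X \in A} \max_Y J(X,Y) + \sum_{Y \in B} \max_X J(Y,X)}
#'            {|A| + |B|} \in [0, 1],}
#' equal to 1 exactly when the partitions coincide.
#'
#' @param A,B \code{\link{cluster_assignment}} objects over the same nodes.
#' @return a number in [0, 1].
#' @examples
#' A <- cluster_assignment(c(n1 = 1, n2 = 1, n3 = 2, n4 = 2))
#' B <- cluster_assignment(c(n1 = 1, n2 = 1, n3 = 1, n4 = 1))
#' jaccard_clustering_similarity(A, B)  # 0.5
#' @export
jaccard_clustering_similarity <- function(A, B) {
  stopifnot(inherits(A, "cluster_assignment"), inherits(B, "cluster_assignment"))
  if (!setequal(names(A$membership), names(B$membership)))
    stop("clusterings cover different node sets")
  ca <- .clusters_of(A); cb <- .clusters_of(B)
  J <- outer(seq_along(ca), seq_along(cb), Vectorize(function(i, j) {
    x <- ca[[i]]; y <- cb[[j]]
    length(intersect(x, y)) / length(union(x, y))
  }))
  (sum(apply(J, 1, max)) + sum(apply(J, 2, max))) / (length(ca) + length(cb))
}

#' Parameter sweep grid
#'
#' Inclusive-endpoint grids: \code{sweep_grid(rateA = c(0.004, 0.016, 0.004))}
#' enumerates 0.004, 0.008, 0.012, 0.016. Each argument is either a
#' \code{c(min, max, step)} triple or an explicit value vector (wrapped in
#' \code{list()}).
#'
#' @param ... named parameter ranges.
#' @return object of class \code{sweep_grid}: list with \code{values} (per
#'   parameter) and \code{combinations} (data frame of the Cartesian product
#'   in lexicographic order, first parameter varying fastest).
#' @export
sweep_grid <- function(...) {
  args <- list(...)
  if (is.null(names(args)) || any(names(args) == ""))
    stop("all grid arguments must be named")
  values <- lapply(args, function(a) {
    if (is.list(a)) unlist(a)
    else if (length(a) == 3) seq(a[1], a[2], by = a[3])
    else a
  })
  combos <- do.call(expand.grid, c(values, KEEP.OUT.ATTRS = FALSE))
  structure(list(values = values, combinations = combos),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat("<sweep_grid> ", nrow(x$combinations), " combinations over ",
      length(x$values), " parameter(s):\n", sep = "")
  for (nm in names(x$values))
    cat("  ", nm, ": ", paste(format(x$values[[nm]]), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Number of combinations in a sweep grid
#'
#' @param grid a \code{\link{sweep_grid}}.
#' @export
n_combinations <- function(grid) nrow(grid$combinations)

#' Shipped sweep-grid presets
#'
#' \describe{
#'   \item{\code{gm_2param}}{rateA, rateI in 0.004..0.016 step 0.004
#'     (16 combinations).}
#'   \item{\code{gm_4param}}{rateA, rateI, muA, muI over the same range
#'     (256 combinations).}
#'   \item{\code{mm_540}}{A 10-15, B 13-18, C 8-10 (step 1), D 0.2-0.6
#'     (step 0.1): 540 combinations.}
#'   \item{\code{mm_375}}{A, B, C 14-18 (step 1), D 0.2-0.6 (step 0.2):
#'     375 combinations.}
#' }
#'
#' @param name preset name.
#' @return a \code{\link{sweep_grid}}.
#' @export
sweep_preset <- function(name = c("gm_2param", "gm_4param", "mm_540",
                                  "mm_375")) {
  name <- match.arg(name)
  switch(name,
    gm_2param = sweep_grid(rateA = c(0.004, 0.016, 0.004),
                           rateI = c(0.004, 0.016, 0.004)),
    gm_4param = sweep_grid(rateA = c(0.004, 0.016, 0.004),
                           rateI = c(0.004, 0.016, 0.004),
                           muA = c(0.004, 0.016, 0.004),
                           muI = c(0.004, 0.016, 0.004)),
    mm_540 = sweep_grid(A = c(10, 15, 1), B = c(13, 18, 1), C = c(8, 10, 1),
                        D = c(0.2, 0.6, 0.1)),
    mm_375 = sweep_grid(A = c(14, 18, 1), B = c(14, 18, 1), C = c(14, 18, 1),
                        D = c(0.2, 0.6, 0.2)))
}

#' Run a parameter sweep
#'
#' Enumerates the grid's Cartesian product in its documented order; for each
#' combination substitutes the parameters into the model, integrates on the
#' connectome, computes the similarity matrix of the chosen statistic, and
#' clusters it. The result carries the entrywise-averaged similarity matrix
#' and the combinations x combinations clustering-similarity matrix (pairwise
#' \code{\link{jaccard_clustering_similarity}}). Failed simulations are
#' recorded and excluded with a warning rather than aborting the sweep.
#'
#' @param grid a \code{\link{sweep_grid}}.
#' @param model template \code{rd_model}; grid parameters override its
#'   entries per combination.
#' @param connectome a \code{\link{connectome}}.
#' @param init initial conditions (as in \code{\link{rd_simulate}}).
#' @param solver a \code{\link{solver_config}}.
#' @param statistic similarity statistic: \code{"cross_correlation"} or
#'   \code{"coactivation"}.
#' @param clustering \code{"spectral"} or \code{"mcl"}.
#' @param k,mcl_cfg clustering options.
#' @param coupling,transient passed through.
#' @param dry_run if TRUE, return the combination count without simulating.
#' @return a \code{sweep_result}: list with \code{grid}, \code{matrices},
#'   \code{clusterings}, \code{average_matrix},
#'   \code{clustering_similarity}, \code{failed}.
#' @export
run_sweep <- function(grid, model, connectome, init, solver = solver_config(),
                      statistic = c("cross_correlation", "coactivation"),
                      clustering = c("spectral", "mcl"), k = "auto",
                      mcl_cfg = mcl_config(), coupling = "out_diffusion",
                      transient = 0.1, dry_run = FALSE) {
  stopifnot(inherits(grid, "sweep_grid"))
  statistic <- match.arg(statistic)
  clustering <- match.arg(clustering)
  combos <- grid$combinations
  if (dry_run) return(nrow(combos))
  mats <- vector("list", nrow(combos))
  cls <- vector("list", nrow(combos))
  failed <- integer(0)
  for (i in seq_len(nrow(combos))) {
    res <- tryCatch({
      mod <- set_params(model, as.list(combos[i, , drop = FALSE]))
      tr <- rd_simulate(mod, connectome, init = init, coupling = coupling,
                        solver = solver)
      sim <- if (statistic == "cross_correlation")
        suppressWarnings(cross_correlation_matrix(tr, transient = transient))
      else suppressWarnings(coactivation_matrix(tr, transient = transient))
      cl <- if (clustering == "spectral") spectral_cluster(sim, k = k)
            else mcl(sim, mcl_cfg)
      list(sim = sim, cl = cl)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, i)
      warning("combination ", i, " failed: ", conditionMessage(res))
    } else {
      mats[[i]] <- res$sim; cls[[i]] <- res$cl
    }
  }
  ok <- setdiff(seq_len(nrow(combos)), failed)
  avg <- if (length(ok)) average_similarity(mats[ok]) else NULL
  CS <- matrix(NA_real_, nrow(combos), nrow(combos))
  for (i in ok) for (j in ok[ok >= i]) {
    CS[i, j] <- CS[j, i] <-
      if (i == j) 1 else jaccard_clustering_similarity(cls[[i]], cls[[j]])
  }
  structure(list(grid = grid, matrices = mats, clusterings = cls,
                 average_matrix = avg, clustering_similarity = CS,
                 statistic = statistic, clustering = clustering,
                 failed = failed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  n <- nrow(x$grid$combinations)
  cat("<sweep_result> ", n, " combinations, statistic=", x$statistic,
      ", clustering=", x$clustering, "\n", sep = "")
  if (length(x$failed)) cat("  failed:", length(x$failed), "combinations\n")
  invisible(x)
}
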
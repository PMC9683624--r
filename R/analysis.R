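# Resolve a transient specification: a fraction (< 1) or a sample count.
.transient_cut <- function(n, transient) {
  k <- if (transient < 1) floor(n * transient) else as.integer(transient)
  if (n - k < 3) stop("fewer than 3 samples remain after the transient")
  k
}

.similarity <- function(M, statistic, transient) {
  structure(list(matrix = M, statistic = statistic, transient = transient,
                 nodes = rownames(M)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix> ", x$statistic, ", ", nrow(x$matrix), "x",
      ncol(x$matrix), ", range [", format(min(x$matrix), digits = 3), ", ",
      format(max(x$matrix), digits = 3), "]\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.similarity_matrix <- function(x, ...) x$matrix

#' @export
plot.similarity_matrix <- function(x, ...) {
  M <- x$matrix[, rev(seq_len(ncol(x$matrix))), drop = FALSE]
  graphics::image(seq_len(nrow(M)), seq_len(ncol(M)), M, xlab = "", ylab = "",
                  axes = FALSE, main = x$statistic, ...)
  invisible(x)
}

#' Zero-lag cross-correlation matrix of node time series
#'
#' Pearson correlation of every node pair's post-transient series of one
#' species. Zero-variance (constant) series yield correlation 0 with a
#' warning, a documented convention; the diagonal is exactly 1.
#'
#' @param traj an \code{rd_trajectory}.
#' @param species species name (default: first = activator).
#' @param transient initial fraction (< 1) or number of samples to discard;
#'   default 0.1 (the first 10\%).
#' @return a \code{similarity_matrix}.
#' @export
cross_correlation_matrix <- function(traj, species = names(traj$states)[1],
                                     transient = 0.1) {
  M <- traj$states[[species]]
  k <- .transient_cut(ncol(M), transient)
  X <- t(M[, (k + 1):ncol(M), drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  C <- matrix(0, ncol(X), ncol(X), dimnames = list(colnames(X), colnames(X)))
  ok <- sds > 0
  if (any(!ok))
    warning("zero-variance series for node(s) ",
            paste(colnames(X)[!ok], collapse = ", "),
            "; their correlations are set to 0")
  if (any(ok)) C[ok, ok] <- stats::cor(X[, ok, drop = FALSE])
  diag(C) <- 1
  .similarity(C, "cross_correlation", k)
}

#' Entrywise average of similarity matrices
#'
#' @param mats list of \code{similarity_matrix} objects over a common node
#'   set (e.g. one per sweep combination).
#' @return a \code{similarity_matrix} holding the entrywise mean.
#' @export
average_similarity <- function(mats) {
  stopifnot(length(mats) >= 1)
  A <- Reduce(`+`, lapply(mats, as.matrix)) / length(mats)
  .similarity(A, paste0("mean_", mats[[1]]$statistic), mats[[1]]$transient)
}

# Discrete analytic signal via FFT (positive-frequency doubling).
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x - mean(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Kuramoto order parameter of node oscillations
#'
#' Extracts instantaneous phases phi_j(t) from the analytic signal (discrete
#' Hilbert transform of each node's mean-subtracted post-transient series)
#' and computes \deqn{r(t) = |N^{-1} \sum_j e^{i \phi_j(t)}| \in [0, 1],}
#' 1 meaning full phase synchrony and 0 incoherence. The first and last 5\%
#' of the window are trimmed (analytic-signal edge effects). Constant series
#' cannot carry a phase and are excluded with a warning.
#'
#' @inheritParams cross_correlation_matrix
#' @return list with \code{times}, \code{r} (instantaneous) and
#'   \code{mean_r}.
#' @export
kuramoto_order <- function(traj, species = names(traj$states)[1],
                           transient = 0.1) {
  M <- traj$states[[species]]
  if (nrow(M) < 2) stop("kuramoto_order needs >= 2 nodes")
  k <- .transient_cut(ncol(M), transient)
  X <- M[, (k + 1):ncol(M), drop = FALSE]
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    warning("constant series excluded from Kuramoto order: ",
            paste(rownames(X)[sds == 0], collapse = ", "))
    X <- X[sds > 0, , drop = FALSE]
    if (nrow(X) < 2) stop("fewer than 2 oscillating nodes remain")
  }
  phases <- t(apply(X, 1, function(x) Arg(.analytic_signal(x))))
  r <- Mod(colMeans(exp(1i * phases)))
  nt <- length(r)
  trim <- max(1L, floor(0.05 * nt))
  idx <- (trim + 1):(nt - trim)
  times <- traj$times[(k + 1):ncol(M)][idx]
  list(times = times, r = r[idx], mean_r = mean(r[idx]))
}

#' Co-activation similarity matrix
#'
#' Binarizes each node's post-transient series at a per-node threshold
#' (default: mean + 0.5 SD) and scores every pair by the Jaccard overlap of
#' their active time bins: time both active / time either active. Nodes that
#' never exceed their threshold get a zero row with a warning.
#'
#' @inheritParams cross_correlation_matrix
#' @param threshold function mapping a numeric series to its activation
#'   threshold; default \code{mean(x) + 0.5 sd(x)}.
#' @return a \code{similarity_matrix} with entries in [0, 1].
#' @export
coactivation_matrix <- function(traj, species = names(traj$states)[1],
                                threshold = function(x) mean(x) + 0.5 * stats::sd(x),
                                transient = 0.1) {
  M <- traj$states[[species]]
  k <- .transient_cut(ncol(M), transient)
  X <- M[, (k + 1):ncol(M), drop = FALSE]
  B <- t(apply(X, 1, function(x) x > threshold(x)))
  act <- rowSums(B)
  if (any(act == 0))
    warning("node(s) never active: ",
            paste(rownames(X)[act == 0], collapse = ", "),
            "; their co-activation rows are 0")
  n <- nrow(B)
  Bi <- B * 1
  inter <- Bi %*% t(Bi)
  uni <- outer(act, act, `+`) - inter
  C <- ifelse(uni > 0, inter / uni, 0)
  dimnames(C) <- list(rownames(X), rownames(X))
  diag(C)[act > 0] <- 1
  .similarity(C, "coactivation", k)
}

#' Local graph metrics per node
#'
#' Degree-based and neighbourhood-overlap statistics for every node of a
#' directed network: in/out/total degree, the convergent-divergent degree
#' coefficient \code{DGinDGall = deg_in / deg_all} (adopted ratio
#' definition), the clustering coefficient over each node's out-neighbourhood
#' (\code{CluC_out}: density of directed edges among the out-neighbours),
#' and mean matching indices (Jaccard overlap of in- resp. out-neighbour
#' sets with every other node, the pair itself excluded). A rank column
#' (average ranks on ties, largest value = rank 1) accompanies each metric.
#' Isolated nodes score 0.
#'
#' @param c a \code{\link{connectome}}.
#' @return data frame, one row per node.
#' @export
local_graph_metrics <- function(c) {
  stopifnot(inherits(c, "connectome"))
  if (nrow(c$nodes) == 0) stop("empty connectome")
  W <- as.matrix(c) > 0
  diag(W) <- FALSE
  n <- nrow(W)
  deg_out <- rowSums(W); deg_in <- colSums(W)
  deg_all <- deg_out + deg_in
  dgindgall <- ifelse(deg_all > 0, deg_in / deg_all, 0)
  cluc_out <- vapply(seq_len(n), function(i) {
    nb <- which(W[i, ])
    if (length(nb) < 2) return(0)
    sum(W[nb, nb]) / (length(nb) * (length(nb) - 1))
  }, 0)
  # per-node mean matching index over all other nodes
  mean_match <- function(which) {
    M <- as.matrix(matching_matrix(c, which))
    diag(M) <- NA
    rowMeans(M, na.rm = TRUE)
  }
  matching_out <- mean_match("out")
  matching_in <- mean_match("in")
  res <- data.frame(node = rownames(W), deg_in = deg_in, deg_out = deg_out,
                    deg_all = deg_all, DGinDGall = dgindgall,
                    CluC_out = cluc_out, matching_in = matching_in,
                    matching_out = matching_out, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (m in c("deg_in", "deg_out", "deg_all", "DGinDGall", "CluC_out",
              "matching_in", "matching_out"))
    res[[paste0("rank_", m)]] <- rank(-res[[m]], ties.method = "average")
  res
}

#' Pairwise matching-index matrix
#'
#' Jaccard overlap of neighbour sets for every node pair,
#' M(i, j) = |N(i) n N(j)| / |N(i) u N(j)|, with the pair itself excluded
#' from both sets; computed on out- or in-neighbourhoods of the directed
#' graph. The connectivity-matching matrix is a structural similarity
#' suitable for the same clustering pipeline as the dynamic similarities.
#'
#' @param c a \code{\link{connectome}}.
#' @param which \code{"out"} or \code{"in"} neighbourhoods.
#' @return a \code{similarity_matrix} with unit diagonal.
#' @export
matching_matrix <- function(c, which = c("out", "in")) {
  which <- match.arg(which)
  W <- as.matrix(c) > 0
  diag(W) <- FALSE
  A <- if (which == "out") W * 1 else t(W) * 1
  n <- nrow(A)
  M <- matrix(0, n, n, dimnames = dimnames(A))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { M[i, j] <- 1; next }
    a <- A[i, ]; b <- A[j, ]
    a[c(i, j)] <- 0; b[c(i, j)] <- 0
    u <- sum(a | b)
    M[i, j] <- if (u == 0) 0 else sum(a & b) / u
  }
  .similarity(M, paste0("matching_", which), 0)
}

#' Modularity partition of a connectome
#'
#' Louvain modularity maximization on the symmetrized weighted graph
#' ((W + W')/2, undirected), as implemented in \pkg{igraph}.
#'
#' @param c a \code{\link{connectome}}.
#' @return a \code{\link{cluster_assignment}} whose \code{Q} element holds
#'   the modularity of the returned partition.
#' @export
modularity_partition <- function(c) {
  stopifnot(inherits(c, "connectome"))
  if (nrow(c$nodes) == 0) stop("empty connectome")
  W <- as.matrix(c)
  S <- (W + t(W)) / 2
  g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cl <- igraph::cluster_louvain(g)
  memb <- igraph::membership(cl)
  out <- cluster_assignment(stats::setNames(as.integer(memb), c$nodes$id),
                            method = "louvain")
  out$Q <- igraph::modularity(cl)
  out
}
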
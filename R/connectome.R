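#' Construct a connectome
#'
#' A connectome is a node-labelled, weighted, directed graph. Nodes carry
#' optional hemisphere labels (\code{"L"}, \code{"R"} or \code{NA}) and
#' optional 3D centroid coordinates in millimetres; edges carry a nonnegative
#' real weight and, optionally, the ordinal weight category (0--4) from which
#' the weight was derived (see \code{\link{weight_from_category}}).
#'
#' @param nodes character vector of unique node identifiers, or a data frame
#'   with columns \code{id} and optionally \code{hemisphere}, \code{x},
#'   \code{y}, \code{z}.
#' @param edges data frame with columns \code{source}, \code{target},
#'   \code{weight} and optionally \code{category} (ordinal, 0--4) and
#'   \code{contralateral} (logical).
#' @param name optional name for the network.
#' @param allow_self_loops logical; self-loops are rejected unless this is set.
#' @return An object of class \code{connectome}: a list with elements
#'   \code{nodes} (data frame), \code{edges} (data frame) and \code{name}.
#' @examples
#' cn <- connectome(c("A", "B"), data.frame(source = "A", target = "B", weight = 1))
#' cn
#' @export
connectome <- function(nodes, edges = NULL, name = "connectome",
                       allow_self_loops = FALSE) {
  if (is.character(nodes)) nodes <- data.frame(id = nodes, stringsAsFactors = FALSE)
  if (!is.data.frame(nodes) || !"id" %in% names(nodes))
    stop("'nodes' must be a character vector or a data frame with an 'id' column")
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id))
    stop("duplicate node identifiers: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  if (!"hemisphere" %in% names(nodes)) nodes$hemisphere <- NA_character_
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("source", "target", "weight")
  if (!all(need %in% names(edges)))
    stop("'edges' must have columns source, target, weight")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)
  unknown <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(unknown))
    stop("edges reference unknown nodes: ", paste(unknown, collapse = ", "))
  if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
    stop("edge weights must be finite and >= 0")
  key <- paste(edges$source, edges$target, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate directed edges: ",
         paste(unique(gsub("\r", " -> ", key[duplicated(key)])), collapse = ", "))
  if (!allow_self_loops && any(edges$source == edges$target))
    stop("self-loops present; pass allow_self_loops = TRUE to keep them")
  structure(list(nodes = nodes, edges = edges, name = name,
                 allow_self_loops = allow_self_loops),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("<connectome> ", x$name, ": ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " directed edges\n", sep = "")
  hemi <- table(x$nodes$hemisphere, useNA = "no")
  if (length(hemi)) cat("  hemispheres:",
                        paste(names(hemi), hemi, sep = "=", collapse = " "), "\n")
  if (nrow(x$edges)) cat("  weight range: [",
                         format(min(x$edges$weight)), ", ",
                         format(max(x$edges$weight)), "]\n", sep = "")
  invisible(x)
}

#' @export
summary.connectome <- function(object, ...) {
  W <- as.matrix(object)
  out <- list(name = object$name, n_nodes = nrow(object$nodes),
              n_edges = nrow(object$edges),
              density = if (nrow(object$nodes) > 1)
                nrow(object$edges) / (nrow(object$nodes) * (nrow(object$nodes) - 1))
              else NA_real_,
              deg_out = rowSums(W > 0), deg_in = colSums(W > 0))
  class(out) <- "summary.connectome"
  out
}

#' @export
print.summary.connectome <- function(x, ...) {
  cat("<connectome> ", x$name, ": ", x$n_nodes, " nodes, ", x$n_edges,
      " edges, density ", format(round(x$density, 4)), "\n", sep = "")
  cat("  out-degree:"); print(summary(x$deg_out))
  cat("  in-degree:"); print(summary(x$deg_in))
  invisible(x)
}

#' Weighted adjacency matrix of a connectome
#'
#' Entry \code{[i, j]} holds the weight of the directed edge i -> j, zero if
#' absent. Row and column names are the node identifiers, in node order.
#'
#' @param x a \code{connectome}.
#' @param ... unused.
#' @export
as.matrix.connectome <- function(x, ...) {
  ids <- x$nodes$id
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(x$edges))
    W[cbind(match(x$edges$source, ids), match(x$edges$target, ids))] <- x$edges$weight
  W
}

#' Convert a connectome to an igraph graph
#'
#' @param x a \code{connectome}.
#' @return a directed, weighted \code{igraph} graph; node attributes are
#'   carried over as vertex attributes.
#' @export
as_igraph <- function(x) {
  stopifnot(inherits(x, "connectome"))
  g <- igraph::graph_from_data_frame(x$edges, directed = TRUE,
                                     vertices = x$nodes)
  if (nrow(x$edges)) igraph::E(g)$weight <- x$edges$weight
  g
}

#' Build a connectome from an igraph graph
#'
#' @param g a directed igraph graph; the \code{weight} edge attribute is used
#'   if present, otherwise all weights are 1.
#' @param name network name.
#' @keywords internal
connectome_from_igraph <- function(g, name = "connectome") {
  vn <- igraph::vertex_attr(g, "name")
  if (is.null(vn)) vn <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::edge_attr(g, "weight")
  if (is.null(w)) w <- rep(1, nrow(el))
  nodes <- data.frame(id = vn, stringsAsFactors = FALSE)
  for (a in setdiff(igraph::vertex_attr_names(g), c("name", "id")))
    nodes[[a]] <- igraph::vertex_attr(g, a)
  connectome(nodes,
             data.frame(source = el[, 1], target = el[, 2], weight = w,
                        stringsAsFactors = FALSE),
             name = name)
}

#' @export
plot.connectome <- function(x, ...) {
  g <- as_igraph(x)
  ew <- igraph::E(g)$weight
  plot(g, edge.width = 0.5 + 2 * ew / max(ew, 1e-12),
       edge.arrow.size = 0.3, vertex.size = 8, vertex.label.cex = 0.6, ...)
  invisible(x)
}

#' Exponential weight from an ordinal connection-strength category
#'
#' Tract-tracing metastudies grade connection strength on an ordinal scale
#' (0 = absent/very weak ... 4 = very strong). For weighted network analysis
#' the categories x are mapped onto an exponential scale,
#' \deqn{w(x) = 10^{-\frac{16}{49}(x-4)^2},}
#' which is strictly increasing on [0, 4] and anchored at w(4) = 1. Fractional
#' categories (e.g. "weak-to-moderate" = 1.5) are permitted.
#'
#' @param x numeric vector of ordinal categories in [0, 4].
#' @return weights in (0, 1].
#' @examples
#' weight_from_category(c(0, 2, 4))
#' @export
weight_from_category <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 4))
    stop("ordinal categories must lie in [0, 4]")
  10^(-(16 / 49) * (x - 4)^2)
}

#' Distance factor for an edge
#'
#' Combines the straight-line Euclidean distance d (mm) between region
#' centroids with the transformed connection weight w into the scalar
#' \code{F1 * d + F2 / w + S}. The factor is used to derive per-edge relay
#' counts for \code{\link{insert_distance_nodes}} (rounded to the nearest
#' nonnegative integer) or, alternatively, to scale the relay leverage.
#'
#' @param d Euclidean distance(s), >= 0.
#' @param w transformed edge weight(s), > 0.
#' @param F1,F2 distance and inverse-weight gains (defaults 0.01 each).
#' @param S additive offset (default 1).
#' @export
distance_factor <- function(d, w, F1 = 0.01, F2 = 0.01, S = 1) {
  if (any(!is.finite(w)) || any(w <= 0))
    stop("transformed weight w must be > 0 (factor diverges at w = 0)")
  if (any(d < 0)) stop("distance d must be >= 0")
  F1 * d + F2 / w + S
}

#' Relay counts for all edges from centroid distances
#'
#' Evaluates \code{\link{distance_factor}} on every edge using the stored node
#' centroids and edge weights, and rounds to nonnegative integer relay counts.
#'
#' @param c a \code{connectome} whose nodes carry \code{x}, \code{y}, \code{z}.
#' @inheritParams distance_factor
#' @return integer vector, one count per edge row.
#' @export
relay_counts_from_distance <- function(c, F1 = 0.01, F2 = 0.01, S = 1) {
  stopifnot(inherits(c, "connectome"))
  if (!all(c("x", "y", "z") %in% names(c$nodes)))
    stop("nodes lack centroid coordinates x, y, z")
  xyz <- as.matrix(c$nodes[, c("x", "y", "z")])
  rownames(xyz) <- c$nodes$id
  d <- sqrt(rowSums((xyz[c$edges$source, , drop = FALSE] -
                     xyz[c$edges$target, , drop = FALSE])^2))
  pmax(0L, as.integer(round(distance_factor(d, c$edges$weight, F1, F2, S))))
}

#' Expand edges with distance-relay nodes
#'
#' Each edge with k >= 1 relays is replaced by a directed chain
#' source -> E1 -> ... -> Ek -> target. The chain realizes the linear relay
#' kinetics dA/dt = -D e1 A, dE/dt = D e1 A - Theta D e1 E,
#' dB/dt = Theta D e1 E (for k = 1): under the out-diffusion coupling operator
#' the expanded edge weights are D*e1 out of the source and Theta*D*e1 out of
#' each relay, where e1 is the original edge weight. Total mass along the
#' chain is conserved. Edges with k = 0 are left unchanged.
#'
#' The expanded graph is intended to be integrated with a unit diffusion
#' coefficient on the relay edges (the rates already carry D).
#'
#' @param c a \code{connectome}.
#' @param D diffusion constant, > 0.
#' @param theta relay leverage Theta, > 0; larger Theta drains relays faster
#'   (shorter effective delay).
#' @param relay_counts integer vector of relay counts, one per edge row
#'   (recycled if length 1); see \code{\link{relay_counts_from_distance}}.
#' @return list with \code{connectome} (the expanded graph) and
#'   \code{expansion}, a data frame recording per original edge the inserted
#'   relay identifiers, D, theta, the original weight \code{e1} and the count.
#' @export
insert_distance_nodes <- function(c, D, theta = 1, relay_counts) {
  stopifnot(inherits(c, "connectome"))
  if (!is.numeric(D) || D <= 0) stop("D must be > 0")
  if (!is.numeric(theta) || theta <= 0) stop("theta must be > 0")
  k <- as.integer(rep_len(relay_counts, nrow(c$edges)))
  if (any(k < 0)) stop("relay counts must be >= 0")
  nodes <- c$nodes
  keep <- c$edges[k == 0, , drop = FALSE]
  new_edges <- list(keep)
  relay_ids <- character(0)
  exp_rows <- list()
  for (e in which(k > 0)) {
    src <- c$edges$source[e]; tgt <- c$edges$target[e]
    e1 <- c$edges$weight[e]; kk <- k[e]
    rid <- sprintf("relay_%s_%s_%d", src, tgt, seq_len(kk))
    relay_ids <- c(relay_ids, rid)
    chain <- c(src, rid, tgt)
    w <- c(D * e1, rep(theta * D * e1, kk))
    new_edges[[length(new_edges) + 1L]] <-
      data.frame(source = chain[-length(chain)], target = chain[-1],
                 weight = w, stringsAsFactors = FALSE)
    exp_rows[[length(exp_rows) + 1L]] <-
      data.frame(source = src, target = tgt, e1 = e1, D = D, theta = theta,
                 relay_count = kk, relays = paste(rid, collapse = ";"),
                 stringsAsFactors = FALSE)
  }
  if (length(relay_ids)) {
    extra <- data.frame(id = relay_ids, stringsAsFactors = FALSE)
    for (col in setdiff(names(nodes), "id")) extra[[col]] <- NA
    nodes <- rbind(nodes, extra[names(nodes)])
  }
  edges <- do.call(rbind, new_edges)
  edges <- edges[, intersect(names(c$edges), names(edges)), drop = FALSE]
  rownames(edges) <- NULL
  list(connectome = connectome(nodes, edges,
                               name = paste0(c$name, "_expanded"),
                               allow_self_loops = c$allow_self_loops),
       expansion = if (length(exp_rows)) do.call(rbind, exp_rows)
                   else data.frame())
}
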
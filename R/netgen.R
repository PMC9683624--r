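#' 2D lattice specification
#'
#' @param width,height integers >= 2.
#' @param boundary \code{"reflecting"} (default) or \code{"periodic"}.
#' @param neighborhood 4 (von Neumann) or 8 (Moore).
#' @export
lattice_spec <- function(width, height, boundary = c("reflecting", "periodic"),
                         neighborhood = 4) {
  if (width < 2 || height < 2) stop("width and height must be >= 2")
  if (!neighborhood %in% c(4, 8)) stop("neighborhood must be 4 or 8")
  structure(list(width = as.integer(width), height = as.integer(height),
                 boundary = match.arg(boundary),
                 neighborhood = as.integer(neighborhood)),
            class = "lattice_spec")
}

#' Regular 2D lattice connectome
#'
#' Grid graph whose out-diffusion coupling operator discretizes the 2D
#' Laplacian: each undirected lattice bond becomes a pair of opposite
#' directed unit-weight edges, so interior nodes have 4 neighbours under the
#' 4-neighbourhood. Node ids are \code{"x_y"}; coordinates are stored.
#'
#' @param spec a \code{\link{lattice_spec}}.
#' @return a \code{\link{connectome}}.
#' @export
build_lattice <- function(spec) {
  stopifnot(inherits(spec, "lattice_spec"))
  w <- spec$width; h <- spec$height
  id <- function(i, j) paste0(i, "_", j)
  offs <- list(c(1, 0), c(0, 1))
  if (spec$neighborhood == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  src <- character(0); tgt <- character(0)
  for (j in seq_len(h)) for (i in seq_len(w)) {
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (spec$boundary == "periodic") {
        ii <- ((ii - 1) %% w) + 1; jj <- ((jj - 1) %% h) + 1
      } else if (ii < 1 || ii > w || jj < 1 || jj > h) next
      if (ii == i && jj == j) next
      src <- c(src, id(i, j)); tgt <- c(tgt, id(ii, jj))
    }
  }
  nodes <- data.frame(id = as.vector(outer(seq_len(w), seq_len(h), id)),
                      x = rep(seq_len(w), h), y = rep(seq_len(h), each = w),
                      z = 0, stringsAsFactors = FALSE)
  # each bond once in src->tgt; emit both directions, deduplicated
  key <- paste(src, tgt)
  keep <- !duplicated(key)
  edges <- data.frame(source = c(src[keep], tgt[keep]),
                      target = c(tgt[keep], src[keep]),
                      weight = 1, stringsAsFactors = FALSE)
  edges <- edges[!duplicated(paste(edges$source, edges$target)), ]
  connectome(nodes, edges, name = sprintf("lattice_%dx%d", w, h))
}

# Degree-preserving double-edge swaps on a directed edge list.
.rewire_directed <- function(edges, n_swaps, allow_self_loops = FALSE) {
  key <- function(s, t) paste(s, t, sep = "\r")
  have <- new.env(hash = TRUE)
  for (k in key(edges$source, edges$target)) assign(k, TRUE, envir = have)
  m <- nrow(edges)
  done <- 0; tries <- 0
  while (done < n_swaps && tries < 40 * n_swaps) {
    tries <- tries + 1
    ij <- sample.int(m, 2)
    a <- edges$source[ij[1]]; b <- edges$target[ij[1]]
    c_ <- edges$source[ij[2]]; d <- edges$target[ij[2]]
    if (!allow_self_loops && (a == d || c_ == b)) next
    k1 <- key(a, d); k2 <- key(c_, b)
    if (exists(k1, envir = have, inherits = FALSE) ||
        exists(k2, envir = have, inherits = FALSE) || k1 == k2) next
    rm(list = c(key(a, b), key(c_, d)), envir = have)
    assign(k1, TRUE, envir = have); assign(k2, TRUE, envir = have)
    edges$target[ij[1]] <- d; edges$target[ij[2]] <- b
    done <- done + 1
  }
  edges
}

# Klemm-Eguiluz growing scale-free graph with an active-node window.
.klemm_eguiluz <- function(n, m, mu) {
  edges <- t(utils::combn(seq_len(m), 2))
  active <- seq_len(m)
  deg <- rep(m - 1, m)
  for (v in (m + 1):n) {
    tgts <- integer(0)
    for (act in active) {
      if (stats::runif(1) < mu) {
        # attach to a random node preferentially by degree
        cand <- setdiff(seq_len(v - 1), c(tgts, v))
        tgt <- sample(cand, 1, prob = deg[cand] + 1)
      } else tgt <- act
      if (!tgt %in% tgts) tgts <- c(tgts, tgt)
    }
    edges <- rbind(edges, cbind(v, tgts))
    deg[tgts] <- deg[tgts] + 1
    deg <- c(deg, length(tgts))
    # new node becomes active; deactivate one with prob ~ 1/deg
    pool <- c(active, v)
    pd <- 1 / deg[pool]
    active <- setdiff(pool, sample(pool, 1, prob = pd / sum(pd)))
  }
  edges
}

# Add or remove random edges until the directed graph has exactly m edges.
.adjust_edge_count <- function(edges, ids, m, allow_self_loops = FALSE) {
  key <- function(s, t) paste(s, t, sep = "\r")
  while (nrow(edges) > m)
    edges <- edges[-sample.int(nrow(edges), 1), , drop = FALSE]
  have <- key(edges$source, edges$target)
  while (nrow(edges) < m) {
    s <- sample(ids, 1); t <- sample(ids, 1)
    if (!allow_self_loops && s == t) next
    if (key(s, t) %in% have) next
    edges <- rbind(edges, data.frame(source = s, target = t, weight = 1,
                                     stringsAsFactors = FALSE))
    have <- c(have, key(s, t))
  }
  rownames(edges) <- NULL
  edges
}

#' Generate a surrogate network
#'
#' Seed-deterministic random-graph generators used as structural null models:
#' Erdos-Renyi (uniform edges), Watts-Strogatz (small-world ring with
#' rewiring), Barabasi-Albert (scale-free preferential attachment),
#' degree-preserving rewiring of a template (directed double-edge swaps,
#' preserving every node's in- and out-degree exactly), and Klemm-Eguiluz
#' (growing scale-free with an active-node window). All surrogates are
#' directed, with unit weights; when \code{n_edges} is given (or a template
#' supplies it) the edge count is matched exactly by random trimming/addition
#' after generation (rewiring is exact by construction).
#'
#' @param kind generator name.
#' @param n_nodes node count (taken from the template for rewiring).
#' @param n_edges desired directed edge count; required for
#'   \code{erdos_renyi} unless \code{p} is given.
#' @param p Erdos-Renyi edge probability (alternative to \code{n_edges});
#'   Watts-Strogatz rewiring probability (default 0.1).
#' @param nei Watts-Strogatz out-neighbourhood radius (each node initially
#'   links to its \code{nei} clockwise neighbours).
#' @param m_per_node Barabasi-Albert edges added per new node; Klemm-Eguiluz
#'   active-window size.
#' @param mu Klemm-Eguiluz probability of preferential attachment to a random
#'   (possibly deactivated) node.
#' @param template a \code{\link{connectome}} (required for rewiring; used by
#'   other kinds to copy node and edge counts when given).
#' @param seed integer seed.
#' @return a \code{\link{connectome}}.
#' @export
generate_surrogate <- function(kind = c("erdos_renyi", "watts_strogatz",
                                        "barabasi_albert", "rewiring",
                                        "klemm_eguiluz"),
                               n_nodes = NULL, n_edges = NULL, p = NULL,
                               nei = 2, m_per_node = 3, mu = 0.1,
                               template = NULL, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (!is.null(template)) {
    if (is.null(n_nodes)) n_nodes <- nrow(template$nodes)
    if (is.null(n_edges)) n_edges <- nrow(template$edges)
  }
  if (kind == "rewiring") {
    if (is.null(template)) stop("rewiring requires a template connectome")
    edges <- .rewire_directed(template$edges, 10 * nrow(template$edges))
    return(connectome(template$nodes, edges,
                      name = paste0(template$name, "_rewired")))
  }
  if (is.null(n_nodes)) stop("n_nodes required")
  ids <- sprintf("n%03d", seq_len(n_nodes))
  edges <- switch(kind,
    erdos_renyi = {
      if (is.null(n_edges) && is.null(p))
        stop("erdos_renyi needs n_edges or p")
      g <- if (!is.null(p) && is.null(n_edges))
        igraph::sample_gnp(n_nodes, p, directed = TRUE)
      else igraph::sample_gnm(n_nodes, n_edges, directed = TRUE)
      el <- igraph::as_edgelist(g, names = FALSE)
      data.frame(source = ids[el[, 1]], target = ids[el[, 2]], weight = 1,
                 stringsAsFactors = FALSE)
    },
    watts_strogatz = {
      if (is.null(p)) p <- 0.1
      src <- integer(0); tgt <- integer(0)
      for (i in seq_len(n_nodes)) for (k in seq_len(nei)) {
        j <- ((i - 1 + k) %% n_nodes) + 1
        if (stats::runif(1) < p) {
          cand <- setdiff(seq_len(n_nodes), c(i, tgt[src == i]))
          j <- sample(cand, 1)
        }
        src <- c(src, i); tgt <- c(tgt, j)
      }
      e <- data.frame(source = ids[src], target = ids[tgt], weight = 1,
                      stringsAsFactors = FALSE)
      e[!duplicated(paste(e$source, e$target)) & e$source != e$target, ]
    },
    barabasi_albert = {
      g <- igraph::sample_pa(n_nodes, m = m_per_node, directed = TRUE)
      el <- igraph::as_edgelist(g, names = FALSE)
      data.frame(source = ids[el[, 1]], target = ids[el[, 2]], weight = 1,
                 stringsAsFactors = FALSE)
    },
    klemm_eguiluz = {
      el <- .klemm_eguiluz(n_nodes, m = m_per_node, mu = mu)
      # orient each undirected bond at random
      flip <- stats::runif(nrow(el)) < 0.5
      s <- ifelse(flip, el[, 2], el[, 1]); t <- ifelse(flip, el[, 1], el[, 2])
      e <- data.frame(source = ids[s], target = ids[t], weight = 1,
                      stringsAsFactors = FALSE)
      e[!duplicated(paste(e$source, e$target)), ]
    })
  if (!is.null(n_edges) && !(kind == "erdos_renyi" && !is.null(p) && is.null(n_edges)))
    edges <- .adjust_edge_count(edges, ids, n_edges)
  connectome(ids, edges, name = paste0("surrogate_", kind))
}

# The 20 bilateral mechanosensory regions (abbreviation = full name).
.mechano_regions <- c(
  AGl = "Lateral agranular prefrontal cortex",
  AGm = "Medial agranular prefrontal cortex",
  CERC = "Cerebellar cortex",
  Cu = "Cuneate nucleus",
  DCeN = "Cerebellar nuclei",
  DRGC1 = "Dorsal root ganglion of cervical segment 1",
  DRGC2 = "Dorsal root ganglion of cervical segment 2",
  DRGC3 = "Dorsal root ganglion of cervical segment 3",
  Gr = "Gracile nucleus principal part",
  ILN = "Intralaminar nuclei",
  IO = "Inferior olive",
  LTNG = "Lateral thalamic nuclear group",
  mPFC = "Medial prefrontal cortex",
  Pn = "Pontine nuclei",
  PTG = "Posterior group",
  S1 = "Primary somatosensory cortex",
  S2 = "Secondary somatosensory cortex",
  VL = "Ventrolateral thalamic nucleus",
  VNT = "Ventral thalamus",
  VPL = "Ventral posterolateral thalamic nucleus")

#' Bilateral mechanosensory fixture connectome
#'
#' A synthetic 40-node stand-in for the bilateral mechanosensory
#' subconnectome (20 named regions x two hemispheres, suffixes _L/_R). The
#' mechanosensitive pathway is wired anatomically: dorsal root ganglia
#' DRGC1-3 project ipsilaterally to the cuneate nucleus, the cuneate nucleus
#' to the contralateral VL and VPL thalamus, and the thalamic nuclei onward
#' to their ipsilateral S1 (so DRGC1_L -> Cu_L -> VL_R -> S1_R is a path).
#' DRG nodes have no afferents. The remaining cortico-cortical,
#' thalamo-cortical and cerebellar edges are drawn with a seeded RNG; all
#' weights derive from synthetic ordinal categories 1-4 through
#' \code{\link{weight_from_category}}. Contralateral edges are flagged.
#' Synthetic centroid coordinates (mm) are attached, mirrored across the
#' midline, so distance-relay expansion is applicable.
#'
#' @param seed integer seed for the random background edges.
#' @return a \code{\link{connectome}} with 40 nodes.
#' @export
mechanosensory_fixture <- function(seed = 42) {
  set.seed(seed)
  regions <- names(.mechano_regions)
  nodes <- data.frame(
    id = c(paste0(regions, "_L"), paste0(regions, "_R")),
    region = rep(regions, 2),
    hemisphere = rep(c("L", "R"), each = length(regions)),
    stringsAsFactors = FALSE)
  # synthetic centroids: caudal (spinal) to rostral (cortical) along y
  ypos <- c(AGl = 18, AGm = 18, mPFC = 19, S1 = 16, S2 = 15.5, CERC = 6,
            DCeN = 6.5, Pn = 8, IO = 5, Gr = 3, Cu = 3, VL = 12, VPL = 12,
            VNT = 11.5, ILN = 12.5, LTNG = 12.2, PTG = 11.8,
            DRGC1 = 0, DRGC2 = -1, DRGC3 = -2)
  nodes$x <- ifelse(nodes$hemisphere == "L", -2.5, 2.5) +
    stats::runif(nrow(nodes), -0.3, 0.3)
  nodes$y <- ypos[nodes$region] + stats::runif(nrow(nodes), -0.2, 0.2)
  nodes$z <- stats::runif(nrow(nodes), 0, 2)

  e <- list()
  add <- function(s, t, cat, contra = FALSE)
    e[[length(e) + 1L]] <<- data.frame(source = s, target = t,
                                       category = cat, contralateral = contra,
                                       stringsAsFactors = FALSE)
  for (h in c("L", "R")) {
    o <- if (h == "L") "R" else "L"
    sfx <- function(r, side = h) paste0(r, "_", side)
    # mechanosensitive chain
    for (d in c("DRGC1", "DRGC2", "DRGC3")) add(sfx(d), sfx("Cu"), 4)
    add(sfx("Cu"), sfx("VL", o), 4, TRUE)
    add(sfx("Cu"), sfx("VPL", o), 4, TRUE)
    add(sfx("VL"), sfx("S1"), 4)
    add(sfx("VPL"), sfx("S1"), 4)
    # gracile mirror pathway and brainstem-cerebellar loop
    add(sfx("Gr"), sfx("VPL", o), 3, TRUE)
    add(sfx("Cu"), sfx("CERC"), 2)
    add(sfx("Pn"), sfx("CERC", o), 3, TRUE)
    add(sfx("IO"), sfx("CERC", o), 3, TRUE)
    add(sfx("CERC"), sfx("DCeN"), 4)
    add(sfx("DCeN"), sfx("VL", o), 3, TRUE)
    # cortico-cortical and cortico-pontine backbone
    add(sfx("S1"), sfx("S2"), 4); add(sfx("S2"), sfx("S1"), 3)
    add(sfx("S1"), sfx("AGl"), 3); add(sfx("AGl"), sfx("AGm"), 3)
    add(sfx("AGm"), sfx("mPFC"), 2); add(sfx("S1"), sfx("Pn"), 3)
    add(sfx("S1"), sfx("S1", o), 2, TRUE)
    # diffuse thalamo-cortical projections
    add(sfx("ILN"), sfx("S1"), 2); add(sfx("ILN"), sfx("AGm"), 2)
    add(sfx("LTNG"), sfx("S2"), 2); add(sfx("PTG"), sfx("S2"), 2)
    add(sfx("VNT"), sfx("AGl"), 1)
  }
  # seeded random background (cortex/thalamus/brainstem only; never into DRG)
  pool <- setdiff(regions, c("DRGC1", "DRGC2", "DRGC3"))
  all_bg <- expand.grid(s = c(paste0(pool, "_L"), paste0(pool, "_R")),
                        t = c(paste0(pool, "_L"), paste0(pool, "_R")),
                        stringsAsFactors = FALSE)
  all_bg <- all_bg[all_bg$s != all_bg$t, ]
  pick <- all_bg[sample.int(nrow(all_bg), 60), ]
  for (i in seq_len(nrow(pick)))
    add(pick$s[i], pick$t[i], sample(1:3, 1),
        substring(pick$s[i], nchar(pick$s[i])) !=
          substring(pick$t[i], nchar(pick$t[i])))
  edges <- do.call(rbind, e)
  edges <- edges[!duplicated(paste(edges$source, edges$target)), ]
  edges$weight <- weight_from_category(edges$category)
  connectome(nodes, edges[, c("source", "target", "weight", "category",
                              "contralateral")],
             name = "mechanosensory_fixture")
}
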
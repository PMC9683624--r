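#' Read a connectome from a file
#'
#' Supported formats:
#' \describe{
#'   \item{\code{edgelist}}{CSV with header \code{source,target,weight}
#'     (optional \code{category}); \code{#} starts a comment line. A node
#'     CSV with columns \code{id,hemisphere,x,y,z} can supply node
#'     attributes via \code{nodes_path}.}
#'   \item{\code{adjacency}}{tab-separated square matrix with a header row
#'     and a leading id column of node names; entry [i, j] is the weight of
#'     edge i -> j.}
#'   \item{\code{graphml}}{GraphML, via \pkg{igraph}.}
#' }
#' Validation failures (wrong token count, negative weights, duplicate
#' edges, references to unknown nodes) raise errors naming the offending
#' line or entry.
#'
#' @param path file path.
#' @param format one of \code{"edgelist"}, \code{"adjacency"},
#'   \code{"graphml"}; guessed from the extension when missing.
#' @param nodes_path optional node-attribute CSV for the edgelist format.
#' @param name network name (defaults to the file name).
#' @return a \code{\link{connectome}}.
#' @export
read_connectome <- function(path, format = NULL, nodes_path = NULL,
                            name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "edgelist", tsv = "adjacency", txt = "adjacency",
                     graphml = "graphml",
                     stop("cannot guess format from extension: ", path))
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(connectome_from_igraph(g, name = name))
  }
  if (format == "adjacency") {
    M <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                     row.names = 1, check.names = FALSE,
                                     comment.char = "#"))
    if (nrow(M) != ncol(M) || !identical(rownames(M), colnames(M)))
      stop("adjacency matrix must be square with matching row/column ids")
    idx <- which(M != 0, arr.ind = TRUE)
    edges <- data.frame(source = rownames(M)[idx[, 1]],
                        target = colnames(M)[idx[, 2]],
                        weight = M[idx], stringsAsFactors = FALSE)
    return(connectome(rownames(M), edges, name = name))
  }
  # edgelist CSV with per-line validation
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (!length(body)) stop("empty edge list: ", path)
  hdr <- strsplit(body[1], ",")[[1]]
  hdr <- trimws(hdr)
  need <- c("source", "target", "weight")
  if (!all(need %in% hdr))
    stop("edge list header must contain source,target,weight (line ",
         lineno[1], ")")
  rows <- lapply(seq_along(body)[-1], function(i) {
    tok <- trimws(strsplit(body[i], ",")[[1]])
    if (length(tok) != length(hdr))
      stop("line ", lineno[i], ": expected ", length(hdr),
           " comma-separated tokens, found ", length(tok))
    tok
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- hdr
  tab$weight <- suppressWarnings(as.numeric(tab$weight))
  if (any(is.na(tab$weight)))
    stop("non-numeric weight at line ",
         lineno[-1][which(is.na(tab$weight))[1]])
  if ("category" %in% names(tab)) tab$category <- as.numeric(tab$category)
  if ("contralateral" %in% names(tab))
    tab$contralateral <- as.logical(tab$contralateral)
  if (!is.null(nodes_path)) {
    nodes <- utils::read.csv(nodes_path, stringsAsFactors = FALSE,
                             comment.char = "#")
    if (!"id" %in% names(nodes)) stop("node file lacks an 'id' column")
  } else {
    nodes <- data.frame(id = unique(c(tab$source, tab$target)),
                        stringsAsFactors = FALSE)
  }
  connectome(nodes, tab, name = name)
}

#' Write a connectome to a file
#'
#' @param c a \code{\link{connectome}}.
#' @param path output path.
#' @param format as in \code{\link{read_connectome}}; guessed from the
#'   extension when missing. The edgelist format writes a companion
#'   \code{*_nodes.csv} when node attributes are present.
#' @return \code{path}, invisibly.
#' @export
write_connectome <- function(c, path, format = NULL) {
  stopifnot(inherits(c, "connectome"))
  if (is.null(format))
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "edgelist", tsv = "adjacency",
                     graphml = "graphml",
                     stop("cannot guess format from extension: ", path))
  if (format == "graphml") {
    g <- as_igraph(c)
    # igraph cannot serialize NA logicals/characters; normalize
    for (a in igraph::vertex_attr_names(g)) {
      v <- igraph::vertex_attr(g, a)
      if (is.character(v) || is.factor(v))
        g <- igraph::set_vertex_attr(g, a,
                                     value = ifelse(is.na(v), "", as.character(v)))
    }
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "adjacency") {
    M <- as.matrix(c)
    df <- data.frame(id = rownames(M), M, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    cols <- intersect(c("source", "target", "weight", "category",
                        "contralateral"), names(c$edges))
    utils::write.csv(c$edges[, cols], path, row.names = FALSE, quote = FALSE)
    if (ncol(c$nodes) > 1) {
      npath <- file.path(dirname(path),
                         paste0(tools::file_path_sans_ext(basename(path)),
                                "_nodes.csv"))
      utils::write.csv(c$nodes, npath, row.names = FALSE, quote = FALSE)
    }
  }
  invisible(path)
}

#' Write a trajectory as long-format TSV with a JSON metadata sidecar
#'
#' Columns: time, node, species, value. The sidecar \code{<path>.json}
#' records model, parameters, solver, seed, schedule and noise.
#'
#' @param traj an \code{rd_trajectory}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(traj$metadata, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a similarity matrix as TSV with node-id header
#'
#' @param sim a \code{similarity_matrix} (or plain matrix).
#' @param path output path.
#' @export
write_similarity <- function(sim, path) {
  M <- as.matrix(sim)
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster assignment as a two-column CSV (node, cluster)
#'
#' @param cl a \code{\link{cluster_assignment}}.
#' @param path output path.
#' @export
write_clusters <- function(cl, path) {
  utils::write.csv(data.frame(node = names(cl$membership),
                              cluster = as.integer(cl$membership)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML)
#'
#' A run configuration resolves, without network access, everything needed
#' to reproduce a simulation: model name and parameter overrides, connectome
#' source (file path, generator spec or \code{"fixture"}), coupling mode,
#' solver settings, initial-condition spec (seeded regions and values),
#' optional schedule and noise, and the seed.
#'
#' @param path YAML file.
#' @return the configuration list, classed \code{run_config}.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

# Resolve the connectome referenced by a run config.
.resolve_connectome <- function(cfg) {
  src <- cfg$connectome
  if (is.null(src) || identical(src, "fixture"))
    return(mechanosensory_fixture(seed = cfg$seed %||% 42))
  if (is.character(src)) return(read_connectome(src))
  if (is.list(src) && !is.null(src$generator))
    return(do.call(generate_surrogate,
                   c(list(kind = src$generator),
                     src[setdiff(names(src), "generator")])))
  stop("unresolvable connectome source in config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Execute a run configuration
#'
#' Runs the configured simulation and writes trajectory, requested analysis
#' artifacts and a manifest (configuration, seed, package version, file
#' hashes) into the output directory.
#'
#' @param cfg a \code{run_config} (see \code{\link{read_run_config}}) or
#'   path to one.
#' @param outdir output directory (created if missing).
#' @return the trajectory, invisibly.
#' @export
run_from_config <- function(cfg, outdir) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  model <- switch(cfg$model %||% "gm",
                  gm = gm_model(), mm = mm_model(), gs = gs_model(),
                  wc = wc_model(),
                  stop("unknown model: ", cfg$model))
  if (!is.null(cfg$params)) model <- set_params(model, cfg$params)
  cn <- .resolve_connectome(cfg)
  sv <- do.call(solver_config, c(cfg$solver %||% list(),
                                 list(seed = cfg$seed %||% 1L)))
  init <- if (!is.null(cfg$init$regions))
    seeded_init(cn, model, cfg$init$regions, unlist(cfg$init$values),
                baseline = unlist(cfg$init$baseline %||% 0.1))
  else if (!is.null(cfg$init$values)) unlist(cfg$init$values)
  else if (!is.null(model$init)) model$init
  else stop("config lacks initial conditions")
  sched <- if (!is.null(cfg$schedule))
    do.call(modulation_schedule, cfg$schedule)
  noise <- if (!is.null(cfg$noise)) {
    if (identical(cfg$noise$kind, "ou"))
      do.call(ou_noise, cfg$noise[setdiff(names(cfg$noise), "kind")])
    else do.call(additive_noise, cfg$noise[setdiff(names(cfg$noise), "kind")])
  }
  tr <- rd_simulate(model, cn, init = init,
                    coupling = cfg$coupling %||% "out_diffusion",
                    solver = sv, schedule = sched, noise = noise)
  write_trajectory(tr, file.path(outdir, "trajectory.tsv"))
  for (an in cfg$analysis %||% character()) {
    if (an == "cross_correlation")
      write_similarity(cross_correlation_matrix(tr),
                       file.path(outdir, "cross_correlation.tsv"))
    else if (an == "kuramoto")
      jsonlite::write_json(kuramoto_order(tr),
                           file.path(outdir, "kuramoto.json"),
                           auto_unbox = TRUE, digits = NA)
    else if (an == "coactivation")
      write_similarity(coactivation_matrix(tr),
                       file.path(outdir, "coactivation.tsv"))
  }
  write_manifest(outdir, cfg)
  invisible(tr)
}

#' Write a reproducibility manifest
#'
#' Records the full configuration, seed, package version and the md5 of each
#' artifact in \code{outdir} into \code{manifest.json}; together these
#' suffice to reproduce the directory exactly.
#'
#' @param outdir artifact directory.
#' @param cfg the configuration list used.
#' @export
write_manifest <- function(outdir, cfg) {
  files <- setdiff(list.files(outdir), "manifest.json")
  jsonlite::write_json(
    list(config = unclass(cfg),
         seed = cfg$seed %||% NA,
         package = "rdconnectome",
         version = as.character(utils::packageVersion("rdconnectome")),
         files = as.list(stats::setNames(
           unname(tools::md5sum(file.path(outdir, files))), files))),
    file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(file.path(outdir, "manifest.json"))
}
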
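#' Solver configuration
#'
#' @param method one of \code{"euler"}, \code{"rk4"}, \code{"dopri_adaptive"}
#'   (step-controlled Dormand-Prince via \pkg{deSolve}), \code{"implicit_euler"}
#'   (backward Euler with damped Newton and finite-difference Jacobian, for
#'   stiff systems).
#' @param dt step size (dimensionless; the time axis is iteration-step based).
#' @param n_steps number of steps (>= 1).
#' @param abs_tol,rel_tol tolerances for the adaptive and implicit methods.
#' @param record_every thinning factor: every k-th state is stored.
#' @param seed integer seed for all randomness of the run (noise); recorded in
#'   the trajectory metadata.
#' @param v_floor optional epsilon floor applied to the Gierer-Meinhardt
#'   inhibitor before evaluating the reaction. By default V <= 0 is a hard
#'   domain error; the floor is the documented opt-in clamp.
#' @export
solver_config <- function(method = c("euler", "rk4", "dopri_adaptive",
                                     "implicit_euler"),
                          dt = 0.1, n_steps = 1000, abs_tol = 1e-8,
                          rel_tol = 1e-8, record_every = 1L, seed = NULL,
                          v_floor = NULL) {
  method <- match.arg(method)
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.numeric(n_steps) || n_steps < 1) stop("n_steps must be >= 1")
  structure(list(method = method, dt = dt, n_steps = as.integer(n_steps),
                 abs_tol = abs_tol, rel_tol = rel_tol,
                 record_every = as.integer(record_every), seed = seed,
                 v_floor = v_floor),
            class = "solver_config")
}

#' Connection-weight modulation schedule
#'
#' Describes how the weights of selected edges are multiplied over time,
#' modelling demyelination (weight loss) and remyelination (recovery) in the
#' coupling operator L(t). Kinds:
#' \describe{
#'   \item{\code{constant}}{multiplier 1 at every step.}
#'   \item{\code{step}}{1 before \code{onset}, \code{factor} from \code{onset}
#'     on (e.g. factor 0.1 = a 90\% weight reduction held constant).}
#'   \item{\code{damped_cosine}}{\code{max(floor, 1 - amplitude *
#'     exp(-damping*t) * (1 - cos(2*pi*t/period))/2)}: relapsing-remitting
#'     episodes of weight loss that plateau as damping accumulates; bounded
#'     in [floor, 1].}
#'   \item{\code{table}}{explicit lookup vector of per-step multipliers
#'     (recycled past the end).}
#' }
#'
#' @param kind schedule type.
#' @param edges edge selector: \code{NULL} (all edges), a data frame with
#'   \code{source}/\code{target} columns, or a predicate
#'   \code{function(edges)} returning a logical vector over edge rows.
#' @param factor step-kind multiplier after onset (> 0).
#' @param onset step index at which the step kind switches.
#' @param amplitude,floor,period,damping damped-cosine parameters (floor > 0).
#' @param table numeric vector of multipliers for the table kind (> 0).
#' @export
modulation_schedule <- function(kind = c("constant", "step", "damped_cosine",
                                         "table"),
                                edges = NULL, factor = 0.1, onset = 0L,
                                amplitude = 10, floor = 0.1, period = 2000,
                                damping = 1e-3, table = NULL) {
  kind <- match.arg(kind)
  if (kind == "step" && factor <= 0) stop("step factor must be > 0")
  if (kind == "damped_cosine" && floor <= 0)
    stop("damped-cosine floor must be > 0")
  if (kind == "table") {
    if (is.null(table) || any(table <= 0))
      stop("table kind requires a vector of positive multipliers")
  }
  structure(list(kind = kind, edges = edges, factor = factor,
                 onset = as.integer(onset), amplitude = amplitude,
                 floor = floor, period = period, damping = damping,
                 table = table),
            class = "modulation_schedule")
}

#' Evaluate a modulation schedule
#'
#' @param s a \code{\link{modulation_schedule}}.
#' @param step integer step index (>= 0); vectorized.
#' @return positive multiplier(s).
#' @export
schedule_multiplier <- function(s, step) {
  stopifnot(inherits(s, "modulation_schedule"))
  if (any(step < 0)) stop("step must be >= 0")
  switch(s$kind,
    constant = rep(1, length(step)),
    step = ifelse(step >= s$onset, s$factor, 1),
    damped_cosine = pmax(s$floor,
      1 - s$amplitude * exp(-s$damping * step) *
        (1 - cos(2 * pi * step / s$period)) / 2),
    table = s$table[(step %% length(s$table)) + 1L])
}

#' Ornstein-Uhlenbeck coupling noise
#'
#' A mean-reverting scalar process delta(t) applied additively to the
#' diffusion term after each deterministic update:
#' \code{U <- U + dt * delta * (L U)}. By default only the activator (first
#' species) receives the noisy diffusion kick.
#'
#' @param theta mean-reversion rate (>= 0).
#' @param sigma volatility (>= 0).
#' @param mu long-run mean.
#' @param delta0 initial value.
#' @param species \code{"activator"} (first species only) or \code{"all"}.
#' @export
ou_noise <- function(theta = 1, sigma = 0.1, mu = 0, delta0 = 0,
                     species = c("activator", "all")) {
  if (theta < 0 || sigma < 0) stop("theta and sigma must be >= 0")
  structure(list(kind = "ou", theta = theta, sigma = sigma, mu = mu,
                 delta0 = delta0, species = match.arg(species)),
            class = "noise_spec")
}

#' Additive Gaussian state noise
#'
#' @param sigma standard deviation scale; each step adds
#'   \code{sigma * sqrt(dt)} times standard normal deviates to every state.
#' @export
additive_noise <- function(sigma = 0.01) {
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(kind = "additive", sigma = sigma), class = "noise_spec")
}

#' One Euler-Maruyama step of the Ornstein-Uhlenbeck process
#'
#' \code{delta + theta*(mu - delta)*dt + sigma*sqrt(dt)*xi} with xi standard
#' normal from the current RNG stream.
#'
#' @param delta current value(s).
#' @param dt step size (> 0).
#' @param p an \code{\link{ou_noise}} spec (fields theta, sigma, mu).
#' @export
ou_step <- function(delta, dt, p) {
  if (dt <= 0) stop("dt must be > 0")
  delta + p$theta * (p$mu - delta) * dt +
    p$sigma * sqrt(dt) * stats::rnorm(length(delta))
}

# Resolve the logical edge selection of a schedule against an edge table.
.select_edges <- function(edges, sel) {
  if (is.null(sel)) return(rep(TRUE, nrow(edges)))
  if (is.function(sel)) return(as.logical(sel(edges)))
  if (is.data.frame(sel)) {
    key <- paste(edges$source, edges$target)
    return(key %in% paste(sel$source, sel$target))
  }
  stop("unsupported edge selector")
}

# Normalize user initial conditions to an N x nspecies matrix.
.init_matrix <- function(init, ids, species) {
  n <- length(ids)
  if (is.matrix(init)) {
    if (nrow(init) != n || ncol(init) != length(species))
      stop("init matrix must be ", n, " x ", length(species))
    S <- init
  } else if (is.list(init)) {
    S <- sapply(species, function(s) {
      v <- init[[s]]
      if (is.null(v)) stop("init lacks species '", s, "'")
      rep_len(v, n)
    })
    S <- matrix(S, nrow = n, dimnames = list(ids, species))
  } else if (is.numeric(init) && length(init) == length(species) && n == 1) {
    S <- matrix(init, nrow = 1, dimnames = list(ids, species))
  } else if (is.numeric(init) && length(init) == length(species)) {
    S <- matrix(rep(init, each = n), nrow = n, dimnames = list(ids, species))
  } else stop("cannot interpret 'init'")
  dimnames(S) <- list(ids, species)
  S
}

#' Simulate reaction-diffusion (or Wilson-Cowan) dynamics on a network
#'
#' Integrates \code{dU/dt = f(U) + D L(t) U} per species on the given
#' connectome, where L is the mass-conserving coupling operator of
#' \code{\link{build_coupling}} and f the model kinetics. A modulation
#' schedule rescales the weights of selected edges each step (L is linear in
#' the edge weights, so L(t) is assembled exactly from a fixed and a
#' modulated part). Ornstein-Uhlenbeck coupling noise is applied additively
#' after the deterministic update of each step. For the Wilson-Cowan model
#' the network term is \code{eta * W' E} inside the excitatory sigmoid
#' argument rather than Laplacian diffusion.
#'
#' Runs are bitwise reproducible given (seed, method, dt). A non-finite state
#' aborts with the offending step index; for explicit methods the error
#' suggests \code{implicit_euler}.
#'
#' @param model an \code{\link{gm_model}}, \code{\link{mm_model}},
#'   \code{\link{gs_model}} or \code{\link{wc_model}}.
#' @param connectome a \code{\link{connectome}}, or \code{NULL} for a single
#'   uncoupled node.
#' @param init initial conditions: an N x nspecies matrix, a named list of
#'   per-node vectors (one entry per species), or a length-nspecies vector
#'   applied to every node. See \code{\link{seeded_init}} for region-seeded
#'   initial conditions.
#' @param coupling coupling mode passed to \code{\link{build_coupling}}.
#' @param solver a \code{\link{solver_config}}.
#' @param schedule optional \code{\link{modulation_schedule}}.
#' @param noise optional \code{\link{ou_noise}} or \code{\link{additive_noise}}.
#' @param normalize row-normalize the adjacency before building L.
#' @return an \code{rd_trajectory}: list with \code{times}, \code{states}
#'   (named list of N x T matrices, one per species) and \code{metadata}.
#' @examples
#' tr <- rd_simulate(gm_model(), init = c(2, 4),
#'                   solver = solver_config(dt = 1, n_steps = 100))
#' tr
#' @export
rd_simulate <- function(model, connectome = NULL, init,
                        coupling = "out_diffusion",
                        solver = solver_config(), schedule = NULL,
                        noise = NULL, normalize = FALSE) {
  stopifnot(inherits(model, "rd_model"), inherits(solver, "solver_config"))
  if (missing(init) && !is.null(model$init)) init <- model$init
  ids <- if (is.null(connectome)) "node1" else connectome$nodes$id
  n <- length(ids)
  sp <- model$species
  S <- .init_matrix(init, ids, sp)
  if (model$kind == "gm" && any(S[, 2] <= 0))
    stop("Gierer-Meinhardt initial inhibitor values must be > 0")

  is_wc <- model$kind == "wc"
  # Split the operator into fixed and modulated parts; L(t) = Lf + m(t) Lm.
  modulated <- !is.null(schedule) && schedule$kind != "constant"
  op <- function(cn) {
    if (is_wc) Matrix::Matrix(t(as.matrix(cn)), sparse = TRUE)
    else build_coupling(cn, mode = coupling, normalize = normalize)$matrix
  }
  if (is.null(connectome) || nrow(connectome$edges) == 0) {
    Lf <- Matrix::Matrix(0, n, n, sparse = TRUE); Lm <- NULL
    modulated <- FALSE
  } else if (modulated) {
    if (normalize)
      stop("normalize = TRUE cannot be combined with an edge-modulation ",
           "schedule (the operator would no longer be linear in the weights)")
    sel <- .select_edges(connectome$edges, schedule$edges)
    sub <- function(rows) connectome(connectome$nodes,
                                     connectome$edges[rows, , drop = FALSE],
                                     allow_self_loops = connectome$allow_self_loops)
    Lf <- op(sub(!sel)); Lm <- op(sub(sel))
  } else {
    Lf <- op(connectome); Lm <- NULL
  }
  Lt <- function(step) {
    if (!modulated) Lf
    else Lf + schedule_multiplier(schedule, step) * Lm
  }

  p <- model$params
  clamped <- 0L
  deriv <- function(S, step) {
    if (!is.null(solver$v_floor) && model$kind == "gm") {
      low <- S[, 2] < solver$v_floor
      if (any(low)) { clamped <<- clamped + sum(low); S[low, 2] <- solver$v_floor }
    }
    L <- Lt(step)
    if (is_wc) {
      input <- p$eta * as.numeric(L %*% S[, 1])
      model$reaction(S, p, input)
    } else {
      R <- model$reaction(S, p)
      D <- model$diffusion
      for (s in seq_along(sp))
        if (D[[s]] != 0) R[, s] <- R[, s] + D[[s]] * as.numeric(L %*% S[, s])
      R
    }
  }

  if (!is.null(solver$seed)) set.seed(solver$seed)
  dt <- solver$dt; n_steps <- solver$n_steps; rec <- solver$record_every
  rec_idx <- seq(0L, n_steps, by = rec)
  out <- lapply(sp, function(s) matrix(NA_real_, n, length(rec_idx),
                                       dimnames = list(ids, NULL)))
  names(out) <- sp
  store <- function(S, slot) for (s in sp) out[[s]][, slot] <<- S[, s]
  store(S, 1L); slot <- 1L

  blowup <- function(i) stop("state became non-finite at step ", i,
    if (solver$method %in% c("euler", "rk4"))
      "; the system may be stiff - consider method = \"implicit_euler\" or a smaller dt"
    else "", call. = FALSE)
  apply_noise <- function(S, step) {
    if (is.null(noise)) return(S)
    if (noise$kind == "additive") {
      S + noise$sigma * sqrt(dt) * stats::rnorm(length(S))
    } else {
      .ou_delta <<- ou_step(.ou_delta, dt, noise)
      tgt <- if (noise$species == "all") seq_along(sp) else 1L
      L <- Lt(step)
      for (s in tgt) S[, s] <- S[, s] + dt * .ou_delta * as.numeric(L %*% S[, s])
      S
    }
  }
  .ou_delta <- if (!is.null(noise) && noise$kind == "ou") noise$delta0 else 0

  if (solver$method == "euler") {
    for (i in seq_len(n_steps)) {
      S <- S + dt * deriv(S, i - 1L)
      S <- apply_noise(S, i - 1L)
      if (any(!is.finite(S))) blowup(i)
      if (i %% rec == 0L) { slot <- slot + 1L; store(S, slot) }
    }
  } else if (solver$method == "rk4") {
    for (i in seq_len(n_steps)) {
      k1 <- deriv(S, i - 1L)
      k2 <- deriv(S + dt / 2 * k1, i - 1L)
      k3 <- deriv(S + dt / 2 * k2, i - 1L)
      k4 <- deriv(S + dt * k3, i - 1L)
      S <- S + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      S <- apply_noise(S, i - 1L)
      if (any(!is.finite(S))) blowup(i)
      if (i %% rec == 0L) { slot <- slot + 1L; store(S, slot) }
    }
  } else if (solver$method == "dopri_adaptive") {
    if (!is.null(noise))
      stop("stochastic noise requires a fixed-step method (euler or rk4)")
    func <- function(t, y, parms) {
      Sm <- matrix(y, nrow = n)
      list(as.numeric(deriv(Sm, min(floor(t / dt), n_steps - 1L))))
    }
    times <- rec_idx * dt
    sol <- deSolve::ode(y = as.numeric(S), times = times, func = func,
                        parms = NULL, method = "ode45",
                        atol = solver$abs_tol, rtol = solver$rel_tol)
    if (any(!is.finite(sol))) blowup(NA)
    for (j in seq_along(rec_idx)) {
      Sm <- matrix(sol[j, -1], nrow = n)
      for (s in seq_along(sp)) out[[sp[s]]][, j] <- Sm[, s]
    }
    slot <- length(rec_idx)
  } else { # implicit_euler: backward Euler, damped Newton, FD Jacobian
    if (!is.null(noise))
      stop("stochastic noise requires a fixed-step method (euler or rk4)")
    m <- n * length(sp)
    for (i in seq_len(n_steps)) {
      y0 <- as.numeric(S)
      G <- function(y) y - y0 - dt * as.numeric(deriv(matrix(y, nrow = n), i - 1L))
      y <- y0 + dt * as.numeric(deriv(S, i - 1L))  # explicit predictor
      for (it in 1:25) {
        g <- G(y)
        if (max(abs(g)) < solver$abs_tol) break
        J <- matrix(0, m, m)
        h <- pmax(1e-8, 1e-8 * abs(y))
        for (k in seq_len(m)) {
          yk <- y; yk[k] <- yk[k] + h[k]
          J[, k] <- (G(yk) - g) / h[k]
        }
        step_dir <- tryCatch(solve(J, -g), error = function(e) -g)
        lam <- 1
        repeat {
          ynew <- y + lam * step_dir
          if (max(abs(G(ynew))) <= max(abs(g)) || lam < 1 / 64) break
          lam <- lam / 2
        }
        y <- ynew
      }
      S <- matrix(y, nrow = n, dimnames = dimnames(S))
      if (any(!is.finite(S))) blowup(i)
      if (i %% rec == 0L) { slot <- slot + 1L; store(S, slot) }
    }
  }
  if (clamped > 0L)
    warning("inhibitor clamped at v_floor on ", clamped, " node-steps")

  structure(list(times = rec_idx * dt,
                 states = out,
                 metadata = list(model = model$kind, params = p,
                                 diffusion = model$diffusion,
                                 solver = solver$method, dt = dt,
                                 n_steps = n_steps, seed = solver$seed,
                                 coupling = if (is_wc) "wc_in" else coupling,
                                 schedule = if (is.null(schedule)) "none"
                                            else schedule$kind,
                                 noise = if (is.null(noise)) "none"
                                         else noise$kind)),
            class = "rd_trajectory")
}

#' Region-seeded initial conditions
#'
#' Builds an initial-condition matrix in which the named regions receive the
#' given per-species values and all other nodes the baseline, mirroring the
#' seeded-pathway initialization (e.g. V0 = 1, W0 = 1 on the left dorsal root
#' ganglia).
#'
#' @param connectome a \code{\link{connectome}}.
#' @param model an \code{rd_model} (for species names).
#' @param regions character vector of node ids to seed.
#' @param values numeric vector, one value per species, for seeded regions.
#' @param baseline numeric vector (or scalar) for the remaining nodes.
#' @export
seeded_init <- function(connectome, model, regions, values,
                        baseline = rep(0.1, length(model$species))) {
  ids <- connectome$nodes$id
  miss <- setdiff(regions, ids)
  if (length(miss)) stop("unknown regions: ", paste(miss, collapse = ", "))
  baseline <- rep_len(baseline, length(model$species))
  S <- matrix(rep(baseline, each = length(ids)), nrow = length(ids),
              dimnames = list(ids, model$species))
  S[regions, ] <- matrix(rep(values, each = length(regions)),
                         nrow = length(regions))
  S
}

#' @export
print.rd_trajectory <- function(x, ...) {
  cat("<rd_trajectory> model=", x$metadata$model,
      ", nodes=", nrow(x$states[[1]]),
      ", species=", paste(names(x$states), collapse = ","),
      ", samples=", length(x$times),
      " (t in [", x$times[1], ", ", x$times[length(x$times)], "])\n", sep = "")
  cat("  solver=", x$metadata$solver, " dt=", x$metadata$dt,
      " schedule=", x$metadata$schedule, " noise=", x$metadata$noise,
      "\n", sep = "")
  invisible(x)
}

#' @export
plot.rd_trajectory <- function(x, species = names(x$states)[1], nodes = NULL,
                               ...) {
  M <- x$states[[species]]
  if (!is.null(nodes)) M <- M[nodes, , drop = FALSE]
  graphics::matplot(x$times, t(M), type = "l", lty = 1,
                    xlab = "iteration time", ylab = species, ...)
  invisible(x)
}

#' @export
as.data.frame.rd_trajectory <- function(x, ...) {
  sp <- names(x$states)
  do.call(rbind, lapply(sp, function(s) {
    M <- x$states[[s]]
    data.frame(time = rep(x$times, each = nrow(M)),
               node = rep(rownames(M), ncol(M)),
               species = s, value = as.numeric(M),
               stringsAsFactors = FALSE)
  }))
}

#' Total per-species mass over time
#'
#' @param traj an \code{rd_trajectory}.
#' @param species species name (default first).
#' @return numeric vector, one total per stored sample.
#' @export
total_mass <- function(traj, species = names(traj$states)[1]) {
  colSums(traj$states[[species]])
}
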
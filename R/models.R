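#' Gierer-Meinhardt reaction rates
#'
#' Activator-inhibitor kinetics for activator U and inhibitor V:
#' \deqn{f(U,V) = r_u U^2 / ((1+\kappa U^2) V) - \mu_u U + \sigma_u}
#' \deqn{g(U,V) = r_v U^2 - \mu_v V + \sigma_v}
#' Autocatalytic activator production saturates at rate \code{kappa}; the
#' inhibitor provides long-range suppression through the division by V.
#'
#' The division by V makes V <= 0 a domain error. The error is deliberate (a
#' silent clamp would mask stiffness problems); integrators accept an optional
#' documented epsilon floor instead (see \code{\link{solver_config}}).
#'
#' @param U,V activator / inhibitor concentrations (vectors of equal length).
#' @param p parameter list with \code{rateA}, \code{rateI}, \code{muA},
#'   \code{muI}, \code{sigmaA}, \code{sigmaI}, \code{kappa}; see
#'   \code{\link{gm_model}}.
#' @return list with components \code{f} and \code{g}.
#' @examples
#' p <- gm_model()$params
#' gm_reaction(2, 4, p)  # the (2, 4) fixed point at a = b = 0.01: both zero
#' @export
gm_reaction <- function(U, V, p) {
  if (any(!is.finite(U)) || any(!is.finite(V))) stop("non-finite concentrations")
  if (any(V <= 0))
    stop("gm_reaction: inhibitor V must be > 0 (division by V); ",
         "use the v_floor solver option for a documented clamp")
  f <- p$rateA * U^2 / ((1 + p$kappa * U^2) * V) - p$muA * U + p$sigmaA
  g <- p$rateI * U^2 - p$muI * V + p$sigmaI
  list(f = f, g = g)
}

#' Mimura-Murray reaction rates
#'
#' Predator-prey kinetics generalizing Lotka-Volterra (adopted canonical
#' form): \deqn{f(u,v) = ((A + B u - u^2)/C - v) u}
#' \deqn{g(u,v) = (u - (1 + D v)) v}
#' Both rates carry a factor of their own state, so f(0, v) = 0 and
#' g(u, 0) = 0 identically.
#'
#' @param u,v prey / predator densities.
#' @param p parameter list with \code{A}, \code{B}, \code{C} (> 0), \code{D}.
#' @return list with components \code{f} and \code{g}.
#' @examples
#' p <- list(A = 35, B = 16, C = 9, D = 0.4)
#' mm_reaction(5, 10, p)  # coexistence equilibrium: both zero
#' @export
mm_reaction <- function(u, v, p) {
  if (p$C <= 0) stop("C must be > 0")
  list(f = ((p$A + p$B * u - u^2) / p$C - v) * u,
       g = (u - (1 + p$D * v)) * v)
}

#' Gray-Scott reaction rates
#'
#' Isothermal autocatalytic kinetics (adopted canonical form):
#' \deqn{f(u,v) = -u v^2 + F (1 - u)}
#' \deqn{g(u,v) = u v^2 - (F + k) v}
#' with feed rate F and kill rate k. (u, v) = (1, 0) is always an equilibrium.
#'
#' @param u,v substrate / activator concentrations.
#' @param p parameter list with \code{F} and \code{k}.
#' @return list with components \code{f} and \code{g}.
#' @export
gs_reaction <- function(u, v, p) {
  uvv <- u * v^2
  list(f = -uvv + p$F * (1 - u),
       g = uvv - (p$F + p$k) * v)
}

#' Wilson-Cowan population rates
#'
#' Classic excitatory/inhibitory neural-mass kinetics with the
#' offset-subtracted logistic response
#' \deqn{S_a(x) = 1/(1+e^{-a(x-\theta)}) - 1/(1+e^{a\theta}),}
#' so that S_a(0) = 0 and the resting state E = I = 0 is preserved at zero
#' drive:
#' \deqn{dE/dt = -E + (1-E) S_{aE}(c_{EE} E - c_{EI} I + P + input)}
#' \deqn{dI/dt = -I + (1-I) S_{aI}(c_{IE} E - c_{II} I)}
#' \code{external_input} carries the network coupling (scaled by eta in
#' \code{\link{rd_simulate}}).
#'
#' @param E,I excitatory / inhibitory activities in [0, 1].
#' @param external_input additional excitatory drive (vector or scalar).
#' @param p parameter list; see \code{\link{wc_model}}.
#' @return list with components \code{dE} and \code{dI}.
#' @export
wc_rates <- function(E, I, external_input = 0, p) {
  sig <- function(x, a, th) 1 / (1 + exp(-a * (x - th))) - 1 / (1 + exp(a * th))
  xe <- p$cEE * E - p$cEI * I + p$P + external_input
  xi <- p$cIE * E - p$cII * I
  list(dE = -E + (1 - E) * sig(xe, p$aE, p$thetaE),
       dI = -I + (1 - I) * sig(xi, p$aI, p$thetaI))
}

.check_nonneg <- function(p, nm) {
  for (f in nm) if (!is.numeric(p[[f]]) || !is.finite(p[[f]]) || p[[f]] < 0)
    stop("parameter '", f, "' must be a finite nonnegative number")
}

#' Gierer-Meinhardt model
#'
#' Constructs a Gierer-Meinhardt activator-inhibitor reaction-diffusion model
#' for use with \code{\link{rd_simulate}}. Defaults correspond to the
#' simplified bifurcation configuration (reaction constants 0.01, inhibitor
#' decay 0.01, a = sigmaA, b = muA), whose positive fixed point is
#' (u*, v*) = ((sigmaA + 0.01)/muA, u*^2); at sigmaA = muA = 0.01 that is
#' (2, 4) and stable.
#'
#' @param rateA,rateI activator / inhibitor reaction constants (r_u, r_v).
#' @param muA,muI decay rates (mu_u, mu_v); muI > 0 for a finite fixed point.
#' @param sigmaA,sigmaI base production rates (sigma_u, sigma_v).
#' @param kappa saturation of activator autocatalysis.
#' @param Du,Dv diffusion constants for activator and inhibitor.
#' @return object of class \code{c("gm_model", "rd_model")}.
#' @export
gm_model <- function(rateA = 0.01, rateI = 0.01, muA = 0.01, muI = 0.01,
                     sigmaA = 0.01, sigmaI = 0, kappa = 0,
                     Du = 0.01, Dv = 0.1) {
  p <- list(rateA = rateA, rateI = rateI, muA = muA, muI = muI,
            sigmaA = sigmaA, sigmaI = sigmaI, kappa = kappa)
  .check_nonneg(p, names(p))
  if (muI <= 0) stop("muI must be > 0 for a finite fixed point")
  structure(list(kind = "gm", species = c("u", "v"), params = p,
                 diffusion = c(u = Du, v = Dv),
                 reaction = function(S, p) {
                   r <- gm_reaction(S[, 1], S[, 2], p)
                   cbind(r$f, r$g)
                 }),
            class = c("gm_model", "rd_model"))
}

#' Mimura-Murray model
#'
#' @param A,B,C,D reaction parameters (C > 0).
#' @param dP,dQ diffusion constants for prey and predator.
#' @param P0,Q0 default initial values (the seeded-region initialization used
#'   on connectomes).
#' @return object of class \code{c("mm_model", "rd_model")}.
#' @export
mm_model <- function(A = 35, B = 16, C = 9, D = 0.4,
                     dP = 0.1, dQ = 0.01, P0 = 6, Q0 = 12) {
  if (C <= 0) stop("C must be > 0")
  if (dP < 0 || dQ < 0) stop("diffusion constants must be >= 0")
  structure(list(kind = "mm", species = c("p", "q"),
                 params = list(A = A, B = B, C = C, D = D),
                 diffusion = c(p = dP, q = dQ), init = c(p = P0, q = Q0),
                 reaction = function(S, p) {
                   r <- mm_reaction(S[, 1], S[, 2], p)
                   cbind(r$f, r$g)
                 }),
            class = c("mm_model", "rd_model"))
}

#' Gray-Scott model
#'
#' @param F feed rate.
#' @param k kill rate.
#' @param Du,Dv diffusion constants.
#' @return object of class \code{c("gs_model", "rd_model")}.
#' @export
gs_model <- function(F = 0.04, k = 0.06, Du = 0.16, Dv = 0.08) {
  if (F < 0 || k < 0) stop("F and k must be >= 0")
  structure(list(kind = "gs", species = c("u", "v"),
                 params = list(F = F, k = k),
                 diffusion = c(u = Du, v = Dv),
                 reaction = function(S, p) {
                   r <- gs_reaction(S[, 1], S[, 2], p)
                   cbind(r$f, r$g)
                 }),
            class = c("gs_model", "rd_model"))
}

#' Wilson-Cowan model
#'
#' Neural-mass baseline on the same networks as the reaction-diffusion
#' models. Defaults are the limit-cycle parameter set of a single oscillator
#' (aE 1.2, aI 2.0, cEE 5, cII 1, cIE 6, cEI 10, thetaE 2, thetaI 3.5,
#' eta 20, P 0.25, E0 = I0 = 0.1). The network term eta * (W' E) (weighted
#' in-coupling along edge direction) enters the excitatory sigmoid argument;
#' this adopted coupling form is documented rather than prescribed.
#'
#' @param aE,aI sigmoid slopes (> 0).
#' @param cEE,cII,cIE,cEI coupling gains.
#' @param thetaE,thetaI sigmoid thresholds.
#' @param eta network coupling scale.
#' @param P constant external drive to E.
#' @param E0,I0 default initial activities.
#' @return object of class \code{c("wc_model", "rd_model")}.
#' @export
wc_model <- function(aE = 1.2, aI = 2.0, cEE = 5.0, cII = 1.0, cIE = 6.0,
                     cEI = 10.0, thetaE = 2.0, thetaI = 3.5, eta = 20.0,
                     P = 0.25, E0 = 0.1, I0 = 0.1) {
  if (aE <= 0 || aI <= 0) stop("sigmoid slopes must be > 0")
  p <- list(aE = aE, aI = aI, cEE = cEE, cII = cII, cIE = cIE, cEI = cEI,
            thetaE = thetaE, thetaI = thetaI, eta = eta, P = P)
  structure(list(kind = "wc", species = c("E", "I"), params = p,
                 diffusion = NULL, init = c(E = E0, I = I0),
                 reaction = function(S, p, input = 0) {
                   r <- wc_rates(S[, 1], S[, 2], input, p)
                   cbind(r$dE, r$dI)
                 }),
            class = c("wc_model", "rd_model"))
}

#' @export
print.rd_model <- function(x, ...) {
  cat("<rd_model:", x$kind, "> species:", paste(x$species, collapse = ", "), "\n")
  cat("  params:", paste(names(x$params),
                         vapply(x$params, format, ""), sep = "=", collapse = " "), "\n")
  if (!is.null(x$diffusion))
    cat("  diffusion:", paste(names(x$diffusion), x$diffusion,
                              sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Update model parameters
#'
#' Returns a copy of the model with the named reaction parameters (or
#' diffusion constants) replaced; used by \code{\link{run_sweep}}.
#'
#' @param model an \code{rd_model}.
#' @param ... named scalar replacements.
#' @export
set_params <- function(model, ...) {
  repl <- list(...)
  if (length(repl) == 1 && is.list(repl[[1]]) && is.null(names(repl)[1]))
    repl <- repl[[1]]
  alias <- switch(model$kind,
                  gm = , gs = c(Du = "u", Dv = "v"),
                  mm = c(dP = "p", dQ = "q"),
                  character(0))
  for (nm in names(repl)) {
    if (nm %in% names(model$params)) model$params[[nm]] <- repl[[nm]]
    else if (!is.null(model$diffusion) && nm %in% names(alias))
      model$diffusion[[alias[[nm]]]] <- repl[[nm]]
    else if (!is.null(model$diffusion) && nm %in% names(model$diffusion))
      model$diffusion[[nm]] <- repl[[nm]]
    else stop("unknown parameter: ", nm)
  }
  model
}

#' Pure network diffusion (zero reaction)
#'
#' Single-species model with no reaction term, so the dynamics reduce to
#' \code{dU/dt = D L U}. Useful for conservation checks and as the control
#' against which pattern formation is judged.
#'
#' @param D diffusion constant (>= 0).
#' @return object of class \code{c("diffusion_model", "rd_model")}.
#' @export
diffusion_model <- function(D = 1) {
  if (D < 0) stop("D must be >= 0")
  structure(list(kind = "diffusion", species = "u", params = list(),
                 diffusion = c(u = D),
                 reaction = function(S, p) S * 0),
            class = c("diffusion_model", "rd_model"))
}

#' Named model presets
#'
#' Ships the default parameterizations used throughout the package:
#' \describe{
#'   \item{\code{gm_bifurcation}}{simplified Gierer-Meinhardt configuration
#'     (a = b = 0.01, fixed point (2, 4)); iteration-step time axis with
#'     dt = 2 over 5000 steps (10000 time units).}
#'   \item{\code{gm_turing}}{stable-kinetics, Turing-regime diffusion contrast
#'     (a = 0.005, b = 0.025, Du = 0.005, Dv = 0.5) for lattice patterns.}
#'   \item{\code{mm_sweep}}{Mimura-Murray mid-sweep parameters (A 12, B 15,
#'     C 9, D 0.4; dP 0.1, dQ 0.01; P0 6, Q0 12), 400 steps of 0.1.}
#'   \item{\code{mm_classic}}{the coexistence-equilibrium parameter set
#'     A 35, B 16, C 9, D 0.4 (fixed point (5, 10)).}
#'   \item{\code{gs_buric}}{Gray-Scott lattice configuration (F 0.04, k 0.06;
#'     adopted form).}
#'   \item{\code{wc_limit_cycle}}{Wilson-Cowan single-oscillator limit-cycle
#'     set, 1000 steps of 0.1.}
#' }
#'
#' @param name preset name.
#' @return list with elements \code{model} and \code{solver}.
#' @export
rd_preset <- function(name = c("gm_bifurcation", "gm_turing", "mm_sweep",
                               "mm_classic", "gs_buric", "wc_limit_cycle")) {
  name <- match.arg(name)
  switch(name,
    gm_bifurcation = list(model = gm_model(),
                          solver = solver_config(method = "euler", dt = 2,
                                                 n_steps = 5000)),
    gm_turing = list(model = gm_model(sigmaA = 0.005, muA = 0.025,
                                      Du = 0.005, Dv = 0.5),
                     solver = solver_config(method = "euler", dt = 0.2,
                                            n_steps = 12000)),
    mm_sweep = list(model = mm_model(A = 12, B = 15, C = 9, D = 0.4),
                    solver = solver_config(method = "euler", dt = 0.1,
                                           n_steps = 400)),
    mm_classic = list(model = mm_model(),
                      solver = solver_config(method = "euler", dt = 0.1,
                                             n_steps = 400)),
    gs_buric = list(model = gs_model(),
                    solver = solver_config(method = "euler", dt = 1,
                                           n_steps = 5000)),
    wc_limit_cycle = list(model = wc_model(),
                          solver = solver_config(method = "euler", dt = 0.1,
                                                 n_steps = 1000)))
}
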
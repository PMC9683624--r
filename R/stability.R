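#' Fixed point of the simplified uncoupled Gierer-Meinhardt system
#'
#' For the single-node system without coupling,
#' \deqn{du/dt = 0.01 u^2 / v - b u + a, \quad dv/dt = 0.01 u^2 - 0.01 v,}
#' the positive fixed point is available in closed form: the inhibitor
#' nullcline gives v* = u*^2, and substituting into the activator equation
#' yields u* = (0.01 + a)/b. At a = b = 0.01 the fixed point is (2, 4).
#'
#' @param a basal activator production (sigma_u), >= 0.
#' @param b activator decay rate (mu_u), > 0.
#' @return named numeric vector \code{c(u, v)}.
#' @examples
#' gm_fixed_point(0.01, 0.01)  # (2, 4)
#' @export
gm_fixed_point <- function(a, b) {
  if (!is.numeric(b) || b <= 0) stop("b must be > 0 (no finite fixed point)")
  if (!is.numeric(a) || a < 0) stop("a must be >= 0")
  u <- (0.01 + a) / b
  c(u = u, v = u^2)
}

# Analytic 2x2 Jacobian of the simplified system at its fixed point.
.gm_jacobian <- function(a, b) {
  fp <- gm_fixed_point(a, b)
  u <- fp[["u"]]; v <- fp[["v"]]
  matrix(c(0.02 * u / v - b, -0.01 * u^2 / v^2,
           0.02 * u,         -0.01),
         2, 2, byrow = TRUE,
         dimnames = list(c("du", "dv"), c("u", "v")))
}

#' Linear stability of the simplified Gierer-Meinhardt fixed point
#'
#' Evaluates the Jacobian of the simplified system at the fixed point of
#' \code{\link{gm_fixed_point}} and classifies the point by the eigenvalue
#' with the largest real part ("first eigenvalue"): \code{stable} if it is
#' negative, \code{oscillatory/unstable} if positive, \code{marginal} within
#' 1e-10 of zero. In the (a, b) plane a Hopf curve separates an oscillatory
#' region from a region of stable fixed points; see
#' \code{\link{gm_boundary_curve}}.
#'
#' @inheritParams gm_fixed_point
#' @return object of class \code{gm_stability}: list with
#'   \code{fixed_point}, \code{jacobian}, \code{eigenvalues},
#'   \code{max_re} and \code{classification}.
#' @examples
#' gm_stability(0.01, 0.01)  # stable; eigenvalues -0.005 +/- 0.00866i
#' @export
gm_stability <- function(a, b) {
  J <- .gm_jacobian(a, b)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  r <- max(Re(ev))
  cls <- if (abs(r) < 1e-10) "marginal"
         else if (r < 0) "stable" else "oscillatory/unstable"
  structure(list(fixed_point = gm_fixed_point(a, b), a = a, b = b,
                 jacobian = J, eigenvalues = ev, max_re = r,
                 classification = cls),
            class = "gm_stability")
}

#' @export
print.gm_stability <- function(x, ...) {
  cat("<gm_stability> a=", x$a, " b=", x$b, "\n", sep = "")
  cat("  fixed point: u*=", format(x$fixed_point[["u"]]),
      " v*=", format(x$fixed_point[["v"]]), "\n", sep = "")
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                              collapse = ", "), "\n")
  cat("  classification:", x$classification, "\n")
  invisible(x)
}

#' Hopf boundary curve of the simplified Gierer-Meinhardt system
#'
#' For each value of a, finds the decay rate b* at which the real part of the
#' leading Jacobian eigenvalue crosses zero, by bracketed root search (Brent,
#' \code{\link[stats]{uniroot}}) over b; the bracket comes from a coarse
#' logarithmic scan. Points with b below the curve are stable, points above
#' it oscillatory; equivalently, at fixed b, the region of small a (left of
#' the curve in the (a, b) plane) is oscillatory and the region of large a
#' stable. A boundary exists only for a < 0.01 (for a >= 0.01 the trace is
#' negative for every admissible b and the fixed point is always stable).
#'
#' @param a_grid positive, sorted vector of a values.
#' @param b_range search interval for b.
#' @param tol root tolerance on Re(lambda_max).
#' @return data frame with columns \code{a}, \code{b} (NA where no sign
#'   change exists in the bracket) and \code{max_re} at the root.
#' @export
gm_boundary_curve <- function(a_grid, b_range = c(1e-4, 10), tol = 1e-12) {
  if (any(a_grid <= 0)) stop("a_grid must be positive")
  if (is.unsorted(a_grid)) stop("a_grid must be sorted increasing")
  res <- lapply(a_grid, function(a) {
    f <- function(b) gm_stability(a, b)$max_re
    bs <- exp(seq(log(b_range[1]), log(b_range[2]), length.out = 60))
    vals <- vapply(bs, f, 0)
    sgn <- which(diff(sign(vals)) != 0)
    if (!length(sgn)) return(data.frame(a = a, b = NA_real_, max_re = NA_real_))
    root <- stats::uniroot(f, lower = bs[sgn[1]], upper = bs[sgn[1] + 1],
                           tol = tol)
    data.frame(a = a, b = root$root, max_re = f(root$root))
  })
  do.call(rbind, res)
}
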
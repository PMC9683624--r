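test_that("GM rates vanish at the (2, 4) fixed point and reduce to the simplified form", {
  p <- gm_model()$params  # a = b = 0.01, kappa = 0
  r <- gm_reaction(2, 4, p)
  expect_equal(r$f, 0)
  expect_equal(r$g, 0)
  # kappa = 0 kinetics agree entrywise with the simplified two-equation form
  set.seed(7)
  U <- runif(100, 0.1, 5); V <- runif(100, 0.1, 5)
  r <- gm_reaction(U, V, p)
  expect_equal(r$f, 0.01 * U^2 / V - 0.01 * U + 0.01, tolerance = 1e-12)
  expect_equal(r$g, 0.01 * U^2 - 0.01 * V, tolerance = 1e-12)
})

test_that("GM saturation limit and inhibitor domain guard", {
  p <- gm_model(kappa = 1e6)$params
  lim <- -p$muA * 1 + p$sigmaA  # kappa -> inf limit at U = V = 1
  expect_equal(gm_reaction(1, 1, p)$f, lim, tolerance = 1e-4)
  expect_error(gm_reaction(1, 0, gm_model()$params), "must be > 0")
  expect_error(gm_reaction(1, -2, gm_model()$params), "must be > 0")
})

test_that("MM kinetics have the expected zeros and monotonicity", {
  p <- list(A = 35, B = 16, C = 9, D = 0.4)
  expect_equal(mm_reaction(0, 0, p), list(f = 0, g = 0))
  r <- mm_reaction(5, 10, p)  # coexistence equilibrium of the adopted form
  expect_equal(r$f, 0)
  expect_equal(r$g, 0)
  # f strictly decreasing in v at fixed u > 0
  v <- seq(0, 20, length.out = 50)
  f <- mm_reaction(rep(2, 50), v, p)$f
  expect_true(all(diff(f) < 0))
  expect_error(mm_model(C = 0), "> 0")
})

test_that("GS kinetics match direct arithmetic and conserve the autocatalytic exchange", {
  expect_equal(gs_reaction(1, 0, list(F = 0.03, k = 0.1)), list(f = 0, g = 0))
  r <- gs_reaction(0.5, 0.25, list(F = 0.04, k = 0.06))
  expect_equal(r$f, -0.01125)
  expect_equal(r$g, 0.00625)
  r0 <- gs_reaction(0.7, 0.2, list(F = 0, k = 0))
  expect_equal(r0$f + r0$g, 0)
})

test_that("WC sigmoid offset keeps the resting state and the threshold identity", {
  p <- wc_model()$params
  sig <- function(x, a, th) 1 / (1 + exp(-a * (x - th))) - 1 / (1 + exp(a * th))
  expect_equal(sig(p$thetaE, p$aE, p$thetaE),
               0.5 - 1 / (1 + exp(p$aE * p$thetaE)))
  r <- wc_rates(0, 0, 0, set_params(wc_model(), P = 0)$params)
  expect_equal(r$dE, 0)
  expect_equal(r$dI, 0)
})

test_that("WC produces a sustained limit cycle in its oscillatory regime", {
  # canonical oscillatory parameter set of the classic formulation
  m <- wc_model(aE = 1.3, aI = 2.0, cEE = 16, cII = 3, cIE = 15, cEI = 12,
                thetaE = 4, thetaI = 3.7, P = 1.25, E0 = 0.1, I0 = 0.05)
  tr <- rd_simulate(m, init = c(0.1, 0.05),
                    solver = solver_config(dt = 0.1, n_steps = 3000))
  E <- tr$states$E[1, ]
  late <- E[2000:3001]
  expect_gt(diff(range(late)), 0.1)          # non-decaying oscillation
  expect_true(all(E >= 0 & E <= 1))          # bounded activity
})

test_that("model presets carry the documented parameterizations", {
  pr <- rd_preset("wc_limit_cycle")
  expect_equal(pr$model$params[c("aE", "aI", "cEE", "cII", "cIE", "cEI",
                                 "thetaE", "thetaI", "eta", "P")],
               list(aE = 1.2, aI = 2.0, cEE = 5.0, cII = 1.0, cIE = 6.0,
                    cEI = 10.0, thetaE = 2.0, thetaI = 3.5, eta = 20.0,
                    P = 0.25))
  expect_equal(pr$solver$n_steps, 1000L)
  expect_equal(pr$solver$dt, 0.1)
  gm <- rd_preset("gm_bifurcation")
  expect_equal(gm$solver$dt * gm$solver$n_steps, 10000)
  mm <- rd_preset("mm_sweep")
  expect_equal(mm$model$init, c(p = 6, q = 12))
  expect_equal(mm$solver$n_steps, 400L)
})

test_that("set_params rejects unknown names and reaches diffusion constants", {
  m <- set_params(gm_model(), rateA = 0.004, Du = 0.2)
  expect_equal(m$params$rateA, 0.004)
  expect_equal(unname(m$diffusion["u"]), 0.2)
  expect_error(set_params(gm_model(), nonsense = 1), "unknown parameter")
})

test_that("the shipped WC preset relaxes to a fixed point under the adopted form", {
  pr <- rd_preset("wc_limit_cycle")
  tr <- rd_simulate(pr$model, init = c(0.1, 0.1),
                    solver = solver_config(dt = 0.1, n_steps = 3000))
  late <- tr$states$E[1, 2500:3001]
  expect_lt(diff(range(late)), 1e-6)  # attracting equilibrium, no cycle
})
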
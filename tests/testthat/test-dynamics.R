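test_that("an uncoupled GM node initialized at its fixed point stays there", {
  tr <- rd_simulate(gm_model(), init = c(2, 4),
                    solver = solver_config(dt = 2, n_steps = 1000))
  expect_lt(max(abs(tr$states$u - 2)), 1e-6)
  expect_lt(max(abs(tr$states$v - 4)), 1e-6)
})

test_that("pure diffusion conserves mass and symmetric graphs equilibrate", {
  cn <- random_graph(n = 8, m = 20, seed = 5)
  set.seed(5)
  tr <- diffuse(cn, runif(8), solver_config(dt = 0.05, n_steps = 4000,
                                            record_every = 100))
  mass <- total_mass(tr)
  expect_lt(max(abs(mass - mass[1])), 1e-8)
  # two nodes, mutual unit edges: both converge to the mean
  sym <- connectome(c("A", "B"),
                    data.frame(source = c("A", "B"), target = c("B", "A"),
                               weight = 1))
  tr2 <- diffuse(sym, c(1, 0), solver_config(dt = 0.01, n_steps = 2000))
  expect_equal(unname(tr2$states$u[, 2001]), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("euler and rk4 agree on the relay chain and match the matrix exponential", {
  ch <- relay_chain(k = 1, D = 0.1, theta = 1)
  u0 <- as.numeric(ch$nodes$id == "A")
  L <- as.matrix(build_coupling(ch)$matrix)
  ref <- as.numeric(Matrix::expm(Matrix::Matrix(L * 10)) %*% u0)
  eu <- diffuse(ch, u0, solver_config("euler", dt = 1e-4, n_steps = 1e5,
                                      record_every = 1e5))
  rk <- diffuse(ch, u0, solver_config("rk4", dt = 1e-2, n_steps = 1e3,
                                      record_every = 1e3))
  expect_lt(max(abs(eu$states$u[, 2] - rk$states$u[, 2])), 1e-4)
  expect_lt(max(abs(rk$states$u[, 2] - ref)), 1e-8)
  expect_lt(max(abs(eu$states$u[, 2] - ref)), 1e-4)
})

test_that("euler shows first-order convergence against an rk4 reference", {
  ref <- rd_simulate(gm_model(), init = c(2.5, 4),
                     solver = solver_config("rk4", dt = 0.01, n_steps = 1000,
                                            record_every = 1000))
  final <- function(dt) {
    tr <- rd_simulate(gm_model(), init = c(2.5, 4),
                      solver = solver_config("euler", dt = dt,
                                             n_steps = 10 / dt,
                                             record_every = 10 / dt))
    tr$states$u[, 2]
  }
  e1 <- abs(final(0.1) - ref$states$u[, 2])
  e2 <- abs(final(0.05) - ref$states$u[, 2])
  expect_gt(e1 / e2, 1.7)
  expect_lt(e1 / e2, 2.3)
})

test_that("the adaptive Dormand-Prince solver tracks rk4 on the GM node", {
  rk <- rd_simulate(gm_model(), init = c(2.5, 4),
                    solver = solver_config("rk4", dt = 1e-3, n_steps = 10000,
                                           record_every = 10000))
  dp <- rd_simulate(gm_model(), init = c(2.5, 4),
                    solver = solver_config("dopri_adaptive", dt = 1,
                                           n_steps = 10, abs_tol = 1e-10,
                                           rel_tol = 1e-10,
                                           record_every = 10))
  expect_equal(dp$states$u[, 2], rk$states$u[, 2], tolerance = 1e-6)
})

test_that("implicit euler converges to the same trajectory on a stiff-capable setup", {
  ex <- rd_simulate(gm_model(), init = c(2.2, 4),
                    solver = solver_config("rk4", dt = 0.01, n_steps = 5000,
                                           record_every = 5000))
  im <- rd_simulate(gm_model(), init = c(2.2, 4),
                    solver = solver_config("implicit_euler", dt = 0.5,
                                           n_steps = 100, abs_tol = 1e-12,
                                           record_every = 100))
  expect_equal(im$states$u[, 2], ex$states$u[, 2], tolerance = 1e-2)
})

test_that("OU noise follows its noiseless decay, stationary variance and determinism", {
  p <- ou_noise(theta = 1, sigma = 0, mu = 0)
  d <- 1
  for (i in 1:1000) d <- ou_step(d, 1e-3, p)
  expect_equal(d, exp(-1), tolerance = 1e-3)
  # stationary variance sigma^2 / (2 theta) within 10%
  p2 <- ou_noise(theta = 1, sigma = 0.5)
  set.seed(1)
  v <- numeric(1e5); d <- 0
  for (i in seq_along(v)) { d <- ou_step(d, 0.01, p2); v[i] <- d }
  expect_equal(var(v[-(1:2000)]), 0.5^2 / 2, tolerance = 0.1)
  # identical seeds give identical paths
  path <- function() { set.seed(9); x <- 0
    vapply(1:100, function(i) x <<- ou_step(x, 0.01, p2), 0) }
  expect_identical(path(), path())
})

test_that("modulation schedules honour their bounds and onsets", {
  s <- modulation_schedule("step", factor = 0.1, onset = 100)
  expect_equal(schedule_multiplier(s, 99), 1)
  expect_equal(schedule_multiplier(s, 100), 0.1)
  dc <- modulation_schedule("damped_cosine", amplitude = 10, floor = 0.1,
                            period = 2000, damping = 1e-3)
  m <- schedule_multiplier(dc, 0:9999)
  expect_gte(min(m), 0.1)
  expect_lte(max(m), 1)
  expect_equal(schedule_multiplier(modulation_schedule("constant"), 0:50),
               rep(1, 51))
  expect_error(modulation_schedule("damped_cosine", floor = 0), "> 0")
  expect_error(schedule_multiplier(s, -1), ">= 0")
})

test_that("a constant schedule and no noise reproduce the unmodulated run bitwise", {
  cn <- mechanosensory_fixture(1)
  init <- seeded_init(cn, gm_model(), c("DRGC1_L", "DRGC2_L", "DRGC3_L"),
                      c(1, 1))
  sv <- solver_config(dt = 2, n_steps = 200, seed = 4)
  base <- rd_simulate(gm_model(), cn, init = init, solver = sv)
  same <- rd_simulate(gm_model(), cn, init = init, solver = sv,
                      schedule = modulation_schedule("constant"))
  expect_identical(base$states, same$states)
})

test_that("runs with a seed are reproducible and noise perturbs the dynamics", {
  cn <- random_graph(n = 5, m = 10, seed = 2)
  sv <- solver_config(dt = 0.5, n_steps = 300, seed = 11)
  args <- list(gm_model(), cn, init = list(u = rep(2, 5), v = rep(4, 5)),
               solver = sv, noise = ou_noise(theta = 0.5, sigma = 0.2))
  a <- do.call(rd_simulate, args)
  b <- do.call(rd_simulate, args)
  expect_identical(a$states, b$states)
  quiet <- rd_simulate(gm_model(), cn,
                       init = list(u = rep(2, 5), v = rep(4, 5)), solver = sv)
  expect_gt(max(abs(a$states$u - quiet$states$u)), 0)
  expect_equal(a$metadata$seed, 11)
})

test_that("blow-up aborts with the step index and a stiffness hint", {
  m <- gs_model(F = 0, k = 0)
  expect_error(
    rd_simulate(m, init = c(1, 1),
                solver = solver_config("euler", dt = 50, n_steps = 100)),
    "non-finite at step [0-9]+.*implicit_euler")
})

test_that("the GM inhibitor floor is an explicit opt-in with a warning", {
  cn <- two_node()
  init <- list(u = c(1, 1), v = c(1e-12, 1e-12))
  sv <- solver_config(dt = 0.5, n_steps = 10)
  expect_error(rd_simulate(gm_model(muI = 5), cn, init = init, solver = sv),
               "must be > 0")
  sv$v_floor <- 1e-6
  expect_warning(rd_simulate(gm_model(muI = 5), cn, init = init, solver = sv),
                 "clamped")
})

test_that("step weight reduction on DRG afferents alters downstream dynamics", {
  cn <- mechanosensory_fixture(42)
  init <- seeded_init(cn, gm_model(), c("DRGC1_L", "DRGC2_L", "DRGC3_L"),
                      c(1, 1))
  sv <- solver_config(dt = 2, n_steps = 1500)
  drg_edges <- data.frame(source = c("DRGC1_L", "DRGC2_L", "DRGC3_L"),
                          target = "Cu_L")
  base <- rd_simulate(gm_model(), cn, init = init, solver = sv)
  cut <- rd_simulate(gm_model(), cn, init = init, solver = sv,
                     schedule = modulation_schedule("step", edges = drg_edges,
                                                    factor = 0.3, onset = 0))
  expect_gt(max(abs(base$states$u["Cu_L", ] - cut$states$u["Cu_L", ])), 1e-6)
  # untouched contralateral DRG is identical (no inputs, unmodified outputs)
  expect_equal(base$states$u["DRGC1_R", ], cut$states$u["DRGC1_R", ])
})
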
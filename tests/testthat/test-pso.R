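make_state <- function(np = 5, q = 3, seed = 1) {
  set.seed(seed)
  P <- matrix(runif(np * q, -1, 1), np, q)
  V <- matrix(runif(np * q, -0.5, 0.5), np, q)
  pb <- P + matrix(rnorm(np * q, 0, 0.1), np, q)
  pf <- runif(np)
  g <- which.min(pf)
  swarm_state(P, V, pb, pf, pb[g, ], pf[g])
}

test_that("velocity update follows the inertia-weighted recursion", {
  cfg <- pso_config(5, 10, cbind(rep(-5, 3), rep(5, 3)))
  st <- make_state()
  zero <- matrix(0, 5, 3)

  # W = 1, r1 = r2 = 0: velocities unchanged
  up <- pso_velocity_update(st, cfg, inertia = 1, r1 = zero, r2 = zero)
  expect_equal(up$velocities, st$velocities)

  # W = 0, particle sitting at both bests: zero velocity
  st2 <- st
  st2$positions[1, ] <- st2$gbest_pos
  st2$pbest_pos[1, ] <- st2$gbest_pos
  up2 <- pso_velocity_update(st2, cfg, inertia = 0, r1 = zero + 1, r2 = zero + 1)
  expect_equal(unname(up2$velocities[1, ]), rep(0, 3))

  # random case matches an explicit componentwise loop
  set.seed(42)
  r1 <- matrix(runif(15), 5, 3)
  r2 <- matrix(runif(15), 5, 3)
  up3 <- pso_velocity_update(st, cfg, inertia = 0.7, r1 = r1, r2 = r2)
  expected <- st$velocities
  for (i in 1:5) for (j in 1:3) {
    v <- 0.7 * st$velocities[i, j] +
      2 * r1[i, j] * (st$pbest_pos[i, j] - st$positions[i, j]) +
      2 * r2[i, j] * (st$gbest_pos[j] - st$positions[i, j])
    expected[i, j] <- min(max(v, -2), 2)  # vmax = 0.2 * width = 2
  }
  expect_equal(up3$velocities, expected)
})

test_that("position update adds velocity and clamps to the box", {
  cfg <- pso_config(5, 10, cbind(rep(-1, 3), rep(1, 3)))
  st <- make_state()
  st$velocities[] <- 0
  expect_equal(pso_position_update(st, cfg)$positions, st$positions)

  st$velocities[] <- 10   # shoots past the upper bound everywhere
  up <- pso_position_update(st, cfg)
  expect_true(all(up$positions == 1))

  set.seed(3)
  st$velocities <- matrix(rnorm(15, 0, 0.1), 5, 3)
  up2 <- pso_position_update(st, cfg)
  expect_equal(up2$positions,
               pmin(pmax(st$positions + st$velocities, -1), 1))
})

test_that("PSO minimizes the sphere function", {
  cfg <- pso_config(30, 200, cbind(rep(-5, 3), rep(5, 3)), seed = 1)
  res <- run_pso(cfg, function(x) sum(x^2))
  expect_lt(res$best_fitness, 1e-4)
})

test_that("zero iterations returns the best of the initial swarm", {
  cfg <- pso_config(25, 0, cbind(rep(-5, 2), rep(5, 2)), seed = 3)
  res <- run_pso(cfg, function(x) sum(x^2))
  set.seed(3)
  P <- matrix(runif(50, -5, 5), 25, 2)
  expect_equal(res$best_fitness, min(rowSums(P^2)))
  expect_equal(res$evaluations, 25L)
})

test_that("PSO runs are reproducible and bounded with a non-increasing trace", {
  cfg <- pso_config(15, 60, cbind(c(0, -2), c(25, 2)), seed = 9)
  f <- function(x) (x[1] - 3)^2 + (x[2] + 1)^2
  r1 <- run_pso(cfg, f)
  r2 <- run_pso(cfg, f)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$fitness_trace) <= 0))
  expect_true(all(r1$best_vector >= c(0, -2) & r1$best_vector <= c(25, 2)))
  expect_equal(r1$best_fitness, r1$fitness_trace[length(r1$fitness_trace)])
  expect_equal(r1$evaluations, 15L * 61L)
})

test_that("DPSO phase 2 solves a separable quadratic in one sweep", {
  a <- c(1.3, -0.7, 2.9, 0.4)
  f <- function(x) sum((x - a)^2)
  bounds <- cbind(rep(-5, 4), rep(5, 4))
  # trivial phase 1 (no iterations), everything left to the sweeps
  p1 <- pso_config(10, 0, bounds, seed = 21)
  cfg <- dpso_config(p1, outer_iterations = 1,
                     inner = pso_config(15, 40, bounds), scatter_frac = 0.5)
  res <- run_dpso(cfg, f)
  expect_lt(res$best_fitness, 1e-6)
  expect_equal(res$best_vector, a, tolerance = 1e-3)
})

test_that("DPSO phase 2 matches per-dimension grid search on a separable objective", {
  a <- c(0.37, -1.22, 1.81)
  f <- function(x) sum(abs(x - a)^1.5)
  bounds <- cbind(rep(-2, 3), rep(2, 3))
  p1 <- pso_config(8, 0, bounds, seed = 5)
  cfg <- dpso_config(p1, outer_iterations = 2,
                     inner = pso_config(12, 30, bounds), scatter_frac = 0.5)
  res <- run_dpso(cfg, f)
  grid <- seq(-2, 2, by = 1e-3)
  for (j in 1:3) {
    gj <- grid[which.min(abs(grid - a[j])^1.5)]
    expect_equal(res$best_vector[j], gj, tolerance = 2e-3)
  }
})

test_that("a degenerate scatter radius leaves the incumbent unchanged", {
  f <- function(x) sum(x^2)
  bounds <- cbind(rep(-5, 3), rep(5, 3))
  p1 <- pso_config(10, 20, bounds, seed = 4)
  ref <- run_pso(p1, f)
  cfg <- dpso_config(p1, outer_iterations = 2,
                     inner = pso_config(5, 10, bounds),
                     scatter_radius = rep(0, 3))
  res <- run_dpso(cfg, f)
  expect_equal(res$best_vector, ref$best_vector)
  expect_equal(res$best_fitness, ref$best_fitness)
})

test_that("DPSO global best is monotone across dimension sweeps and reproducible", {
  ctx <- quick_ctx(seed = 5)
  f <- ss_fitness(ctx)
  b <- param_bounds(benchmark_mask())
  p1 <- pso_config(10, 30, b, seed = 2)
  cfg <- dpso_config(p1, outer_iterations = 1, inner = pso_config(5, 5, b))
  r1 <- run_dpso(cfg, f)
  r2 <- run_dpso(cfg, f)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$fitness_trace) <= 0))
  expect_true(all(r1$best_vector >= b[, 1] & r1$best_vector <= b[, 2]))
})
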
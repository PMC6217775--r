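test_that("rate evaluation reduces to alpha - beta at unit state", {
  m <- benchmark_model()
  expect_equal(ss_rates(m, rep(1, 4), inputs = 1), c(10, 5, 0, -4))

  # zero kinetic orders: rates are alpha - beta at any positive state
  m0 <- ss_model(alpha = c(3, 7), beta = c(1, 2),
                 G = matrix(0, 2, 2), H = matrix(0, 2, 2))
  for (x in list(c(0.2, 5), c(1, 1), c(10, 0.01)))
    expect_equal(ss_rates(m0, x), c(2, 5))
})

test_that("rate evaluation matches a brute-force product-of-powers loop", {
  for (seed in 1:5) {
    m <- random_model(N = 3, m = 1, seed = seed)
    set.seed(seed + 100)
    state <- runif(3, 0.2, 5)
    u <- runif(1, 0.2, 5)
    expect_equal(ss_rates(m, state, u), rates_oracle(m, state, u),
                 tolerance = 1e-12)
  }
})

test_that("zero rate coefficients force a zero derivative component", {
  m <- random_model(N = 3, m = 0, seed = 3)
  m$alpha[2] <- 0
  m$beta[2] <- 0
  expect_identical(ss_rates(m, c(0.7, 1.3, 2.1))[2], 0)
})

test_that("single-time simulation returns the initial state", {
  tr <- ss_simulate(benchmark_model(), rep(0.5, 4), times = 0, inputs = 1)
  expect_equal(nrow(tr$states), 1L)
  expect_equal(unname(tr$states[1, ]), rep(0.5, 4))
})

test_that("integrator reproduces the closed-form linear relaxation", {
  # dx/dt = 2 - x  =>  x(t) = 2 + (x0 - 2) exp(-t)
  m <- ss_model(alpha = 2, beta = 1, G = matrix(0, 1, 1), H = matrix(1, 1, 1))
  x0 <- 0.25
  times <- c(0, 0.5, 1, 2)
  tr <- ss_simulate(m, x0, times)
  expect_equal(unname(tr$states[, 1]), 2 + (x0 - 2) * exp(-times),
               tolerance = 1e-6)
})

test_that("integrator agrees with an independent fine-step RK4 oracle", {
  m <- benchmark_model()
  times <- seq(0, 5, length.out = 11)
  tr <- ss_simulate(m, rep(0.5, 4), times, inputs = 1)
  ref <- rk4_oracle(m, rep(0.5, 4), times, inputs = 1, substeps = 400)
  expect_equal(unname(tr$states), ref, tolerance = 1e-4)
})

test_that("integrator agrees with deSolve on the benchmark model", {
  m <- benchmark_model()
  times <- seq(0, 5, length.out = 21)
  deriv <- function(t, y, parms) list(ss_rates(m, y, inputs = 1))
  ref <- deSolve::lsoda(rep(0.5, 4), times, deriv, NULL,
                        rtol = 1e-9, atol = 1e-11)
  tr <- ss_simulate(m, rep(0.5, 4), times, inputs = 1)
  expect_equal(unname(tr$states), unname(ref[, -1]), tolerance = 1e-5)
})

test_that("halving the tolerance changes samples by less than the coarse tolerance", {
  m <- benchmark_model()
  times <- seq(0, 5, length.out = 26)
  coarse <- ss_simulate(m, rep(0.5, 4), times, inputs = 1,
                        rtol = 1e-5, atol = 1e-7)
  fine <- ss_simulate(m, rep(0.5, 4), times, inputs = 1,
                      rtol = 5e-6, atol = 5e-8)
  expect_lt(max(abs(coarse$states - fine$states)), 1e-5 * max(coarse$states))
})

test_that("simulation over a time prefix equals the prefix of the full run", {
  m <- benchmark_model()
  times <- seq(0, 5, length.out = 26)
  full <- ss_simulate(m, rep(0.4, 4), times, inputs = 1)
  pre <- ss_simulate(m, rep(0.4, 4), times[1:10], inputs = 1)
  expect_identical(pre$states, full$states[1:10, ])
})

test_that("integration failure is reported, not thrown", {
  # enormous positive feedback blows up quickly
  m <- ss_model(alpha = 25, beta = 0, G = matrix(8, 1, 1),
                H = matrix(0, 1, 1))
  tr <- ss_simulate(m, 5, times = seq(0, 10, 0.5), max_steps = 200L)
  expect_true(isTRUE(attr(tr, "failed")))
  expect_lt(length(tr$times), 21L)
  expect_true(all(is.finite(tr$states)))
})

test_that("trajectory CSV round-trips to 12 significant digits", {
  tr <- benchmark_truth(times = seq(0, 2, length.out = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$times, tr$times, tolerance = 1e-11)
  expect_equal(unname(back$states), unname(tr$states), tolerance = 1e-11)
  expect_equal(colnames(back$states), colnames(tr$states))
})

test_that("malformed trajectory headers are rejected with the offending name", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,x1,conc", "0,1,2", "1,2,3"), path)
  expect_error(read_trajectory(path), "conc")
  writeLines(c("t,x1", "0,1"), path)
  expect_error(read_trajectory(path), "time")
})

test_that("model constructor enforces its invariants", {
  expect_error(ss_model(alpha = -1, beta = 1, G = matrix(0, 1, 1),
                        H = matrix(0, 1, 1)), "non-negative")
  expect_error(ss_model(alpha = 1, beta = 1, G = matrix(NA, 1, 1),
                        H = matrix(0, 1, 1)), "finite")
  expect_error(ss_model(alpha = 1, beta = 1, G = matrix(0, 1, 3),
                        H = matrix(0, 1, 2)), "matrix")
})
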
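test_that("sigma points have the documented count and moments", {
  q <- 17
  set.seed(1)
  A <- matrix(rnorm(q * q, 0, 0.3), q)
  P <- crossprod(A) + diag(q) * 0.1
  st <- ukf_state(rnorm(q), P, Rr = 0, epsilon = 0.5, kappa = 0)
  sig <- sigma_points(st)
  expect_equal(dim(sig), c(q, 2L * q + 1L))
  # weights sum exactly to one: W0 + 2q * Wi = 1
  expect_equal(sum(st$weights_m), 1)
  expect_equal(st$weights_m[1], st$lambda / (st$lambda + q))
  expect_equal(st$weights_m[2], 1 / (2 * (st$lambda + q)))
  # weighted mean recovers the centre
  expect_equal(as.numeric(sig %*% st$weights_m), st$omega_hat)
  # weighted scatter recovers the predicted covariance
  centred <- sig - st$omega_hat
  Pr <- centred %*% (st$weights_c * t(centred))
  expect_equal(Pr, P, tolerance = 1e-8)
})

test_that("a meaningfully indefinite covariance is signaled", {
  st <- ukf_state(c(0, 0), diag(2), Rr = 0, epsilon = 0.5)
  st$P <- matrix(c(1, 2, 2, 1), 2)   # eigenvalues 3 and -1
  expect_error(sigma_points(st), "positive semi-definite")
})

test_that("one UKF step equals the analytic Kalman update on a linear map", {
  q <- 4
  set.seed(7)
  M <- matrix(rnorm(3 * q), 3, q)
  omega0 <- rnorm(q)
  A <- matrix(rnorm(q * q, 0, 0.2), q)
  P0 <- crossprod(A) + diag(q) * 0.5
  Re <- diag(3) * 0.04
  Rr <- diag(q) * 1e-4
  d <- as.numeric(M %*% rnorm(q)) + rnorm(3, 0, 0.2)

  st <- ukf_state(omega0, P0, Rr = Rr, Re = Re, epsilon = 0.9, kappa = 0)
  up <- ukf_step(st, d, function(sig) M %*% sig)

  # analytic Kalman filter on the same linear-Gaussian model
  Pm <- P0 + Rr
  S <- M %*% Pm %*% t(M) + Re
  K <- Pm %*% t(M) %*% solve(S)
  mean_ref <- omega0 + as.numeric(K %*% (d - M %*% omega0))
  P_ref <- Pm - K %*% S %*% t(K)
  expect_equal(up$omega_hat, mean_ref, tolerance = 1e-8)
  expect_equal(up$P, P_ref, tolerance = 1e-8)
})

test_that("a huge measurement-noise covariance freezes the estimate", {
  q <- 3
  st <- ukf_state(c(1, 2, 3), diag(q) * 0.3, Rr = 0, Re = 1e12,
                  epsilon = 0.5)
  up <- ukf_step(st, c(10, 10, 10), function(sig) sig)
  expect_equal(up$omega_hat, c(1, 2, 3), tolerance = 1e-6)
})

test_that("the projection clamps every updated component into its box", {
  q <- 3
  bounds <- cbind(rep(0, q), rep(1, q))
  st <- ukf_state(c(0.5, 0.5, 0.5), diag(q), Rr = 0, Re = 1e-6,
                  epsilon = 0.5, bounds = bounds)
  up <- ukf_step(st, c(50, -50, 50), function(sig) sig)
  expect_true(all(up$omega_hat >= 0 & up$omega_hat <= 1))
})

test_that("the stall rule triggers a covariance reset and the stop rule halts", {
  expect_true(ssfit:::iukf_should_reset(0.5, 0.5 - 1e-4 / 2, 1e-4))
  expect_false(ssfit:::iukf_should_reset(0.5, 0.3, 1e-4))
  expect_false(ssfit:::iukf_should_reset(Inf, 0.3, 1e-4))

  # data generated by the initial estimate: RMSE below delta_E at pass 1
  ctx <- quick_ctx(seed = 6)
  ctx$rtol <- 1e-6
  ctx$atol <- 1e-8
  truth <- ctx$data
  w <- ss_encode(benchmark_model(), benchmark_mask())
  b <- param_bounds(benchmark_mask())
  ukf0 <- ukf_state(w, P = 1e-6, Rr = 1e-10, Re = 1e-2, epsilon = 0.5,
                    bounds = b)
  res <- run_iukf(iukf_config(delta_E = 1e-3, max_outer = 5, proj_bounds = b,
                              seed = 1), ukf0, truth, ctx)
  expect_equal(length(res$pass_rmse), 1L)
  expect_lt(res$best_fitness, 1e-3)
})

test_that("a frozen filter accumulates stall resets", {
  # gain ~ 0 (huge Re) so consecutive pass RMSEs are equal -> resets fire
  ctx <- quick_ctx(seed = 7)
  w <- ss_encode(benchmark_model(), benchmark_mask()) + 0.3
  b <- param_bounds(benchmark_mask())
  ukf0 <- ukf_state(w, P = 1e-8, Rr = 0, Re = 1e12, epsilon = 0.5, bounds = b)
  res <- run_iukf(iukf_config(delta_E = 1e-9, delta_R = 1e-4, max_outer = 4,
                              proj_bounds = b, seed = 2), ukf0, ctx$data, ctx)
  expect_gte(res$resets, 1L)
  expect_equal(length(res$pass_rmse), 4L)
})

test_that("iterated passes improve on a single UKF pass on the benchmark", {
  b <- param_bounds(benchmark_mask())
  q <- 17
  wins <- 0
  n_seed <- 6
  for (s in seq_len(n_seed)) {
    ctx <- quick_ctx(seed = 300 + s)
    set.seed(s)
    omega0 <- runif(q, b[, 1], b[, 2])
    one <- run_iukf(iukf_config(max_outer = 1, proj_bounds = b, seed = s),
                    ukf_state(omega0, P = 0.5, Rr = 1e-5, Re = 1e-2,
                              epsilon = 0.5, bounds = b), ctx$data, ctx)
    many <- run_iukf(iukf_config(max_outer = 15, proj_bounds = b, seed = s),
                     ukf_state(omega0, P = 0.5, Rr = 1e-5, Re = 1e-2,
                               epsilon = 0.5, bounds = b), ctx$data, ctx)
    if (many$best_fitness < one$best_fitness) wins <- wins + 1
  }
  expect_gte(wins, ceiling(0.75 * n_seed))
})
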
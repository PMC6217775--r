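# Shared fixtures, all built in code.

# Random S-system with bounded orders/rates; always paired with a positive
# state so power laws stay tame.
random_model <- function(N = 3, m = 1, seed = 1) {
  set.seed(seed)
  ss_model(alpha = runif(N, 0.1, 20), beta = runif(N, 0.1, 20),
           G = matrix(runif(N * (N + m), -1, 2), N, N + m),
           H = matrix(runif(N * (N + m), -1, 2), N, N + m),
           n_independent = m)
}

# Direct product-of-powers evaluation, written independently of the package
# kernel (plain double loop over every variable).
rates_oracle <- function(model, state, inputs = numeric(model$n_independent)) {
  x <- pmax(c(state, inputs), 1e-9)
  out <- numeric(model$n_dependent)
  for (i in seq_len(model$n_dependent)) {
    pg <- 1
    ph <- 1
    for (j in seq_along(x)) {
      pg <- pg * x[j]^model$G[i, j]
      ph <- ph * x[j]^model$H[i, j]
    }
    out[i] <- model$alpha[i] * pg - model$beta[i] * ph
  }
  out
}

# Fixed-step classical RK4 integrator used as an independent oracle.
rk4_oracle <- function(model, x0, times, inputs = numeric(model$n_independent),
                       substeps = 200) {
  x <- x0
  out <- matrix(NA_real_, length(times), length(x0))
  out[1, ] <- x0
  for (r in seq_len(length(times) - 1)) {
    h <- (times[r + 1] - times[r]) / substeps
    for (s in seq_len(substeps)) {
      k1 <- rates_oracle(model, x, inputs)
      k2 <- rates_oracle(model, x + h / 2 * k1, inputs)
      k3 <- rates_oracle(model, x + h / 2 * k2, inputs)
      k4 <- rates_oracle(model, x + h * k3, inputs)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[r + 1, ] <- x
  }
  out
}

benchmark_truth <- function(x0 = rep(0.5, 4), times = seq(0, 5, length.out = 50)) {
  ss_simulate(benchmark_model(), x0, times, inputs = 1)
}

# Small, quick fitness context on the benchmark for optimizer tests.
quick_ctx <- function(seed = 1, times = seq(0, 5, length.out = 50),
                      snr_db = Inf) {
  set.seed(seed)
  x0 <- runif(4, 0.1, 1)
  truth <- ss_simulate(benchmark_model(), x0, times, inputs = 1)
  obs <- add_noise(truth, snr_db, seed = seed + 1000)
  fitness_context(obs, benchmark_model(), benchmark_mask(), x0 = x0,
                  inputs = 1, rtol = 1e-4, atol = 1e-6, max_steps = 300)
}
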
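# Tiny optimizer sizings keep these end-to-end tests fast; the scientific
# comparison at realistic sizing lives in the acceptance suite.
tiny_cfg <- function(...) {
  experiment_config(n_replicates = 2L, base_seed = 42L,
                    n_particles = 8L, n_iterations = 15L,
                    outer_iterations = 1L, inner_particles = 4L,
                    inner_iterations = 4L, iukf_max_outer = 2L, ...)
}

test_that("parameter bounds assign rate and order boxes by block", {
  b <- param_bounds(benchmark_mask())
  expect_equal(dim(b), c(17L, 2L))
  expect_true(all(b[1:8, 1] == 0 & b[1:8, 2] == 25))
  expect_true(all(b[9:17, 1] == -2 & b[9:17, 2] == 2))
})

test_that("experiment configuration is validated", {
  expect_error(experiment_config(algorithms = character(0)))
  expect_error(experiment_config(n_replicates = 0), "n_replicates")
  expect_error(experiment_config(scenario = "custom"), "snr_db")
  expect_equal(experiment_config(scenario = "snr20")$snr_db, 20)
  expect_equal(experiment_config(scenario = "noisefree")$snr_db, Inf)
})

test_that("a single-replicate experiment is exactly reproducible", {
  cfg <- tiny_cfg(algorithms = "pso")
  cfg$n_replicates <- 1L
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1, r2)
})

test_that("the reported mean equals the average of per-replicate values", {
  cfg <- tiny_cfg(algorithms = c("pso", "sa"))
  cfg$n_replicates <- 3L
  rep <- run_experiment(cfg)
  for (a in c("pso", "sa")) {
    expect_length(rep$rmse[[a]], 3L)
    expect_equal(rep$mean_rmse[[a]], mean(rep$rmse[[a]]))
  }
})

test_that("swarm and annealing budgets are equalized within one percent", {
  # feasibility screening adds a small symmetric overhead; switch it off to
  # check the equalization machinery itself
  cfg <- tiny_cfg(algorithms = c("dpso", "pso", "sa"), feasible_init = FALSE)
  rep <- run_experiment(cfg)
  ev <- vapply(rep$evaluations, mean, 0)
  expect_lt(abs(ev[["pso"]] - ev[["dpso"]]) / ev[["dpso"]], 0.01)
  expect_lt(abs(ev[["sa"]] - ev[["dpso"]]) / ev[["dpso"]], 0.01)
})

test_that("improvement percentages follow the definition", {
  expect_equal(improvement_pct(1, 1), 0)
  expect_equal(improvement_pct(1, 0), 100)
  expect_equal(improvement_pct(0.4040, 0.2291), 43.29, tolerance = 1e-3)
  expect_error(improvement_pct(0, 0.5), "positive")
})

test_that("reports round-trip to disk with the tabular layout", {
  cfg <- tiny_cfg(algorithms = c("pso", "dpso"))
  rep <- run_experiment(cfg)
  dir <- withr::local_tempdir()
  write_report(rep, dir)

  tab <- read.csv(file.path(dir, "params_pso.csv"))
  expect_equal(nrow(tab), 4L)
  expect_equal(ncol(tab), 11L)  # state, alpha, g1..g4, beta, h1..h4
  expect_equal(names(tab)[c(1, 2, 7)], c("state", "alpha", "beta"))

  rm <- read.csv(file.path(dir, "rmse_dpso.csv"))
  expect_equal(rm$rmse, rep$rmse$dpso)

  js <- jsonlite::read_json(file.path(dir, "summary.json"),
                            simplifyVector = TRUE)
  expect_equal(js$mean_rmse$pso, rep$mean_rmse[["pso"]])
  expect_equal(js$rmse$dpso, rep$rmse$dpso)
  expect_equal(js$base_seed, rep$config$base_seed)
  expect_equal(sort(js$algorithms), sort(rep$config$algorithms))
})

test_that("user-supplied data round-trips through fit_user_data", {
  # data generated from a known two-state model; the fit must recover it
  mod <- ss_model(alpha = c(3, 2), beta = c(2, 1.5),
                  G = rbind(c(0, 0.6), c(0.5, 0)), H = diag(c(0.6, 0.7)),
                  n_independent = 0L)
  mask <- param_mask(rep(TRUE, 2), rep(TRUE, 2), mod$G != 0, mod$H != 0)
  truth <- ss_simulate(mod, c(0.8, 0.6), seq(0, 4, length.out = 30))
  dir <- withr::local_tempdir()
  spec_path <- file.path(dir, "model.yaml")
  data_path <- file.path(dir, "traj.csv")
  write_model_spec(mod, mask, spec_path)
  write_trajectory(truth, data_path)

  fit <- fit_user_data(spec_path, data_path, algorithm = "dpso", seed = 5,
                       out_dir = dir, n_particles = 20L, n_iterations = 150L,
                       outer_iterations = 2L, inner_particles = 6L,
                       inner_iterations = 10L)
  expect_lt(fit$rmse, 0.2)
  expect_true(file.exists(file.path(dir, "params_dpso.csv")))
  expect_true(file.exists(file.path(dir, "fitted_trajectory.csv")))
  over <- read_trajectory(file.path(dir, "fitted_trajectory.csv"))
  expect_equal(over$times, truth$times)
})

test_that("the Cad structure keeps its absent terms out of a fit", {
  cad <- cad_model(alpha = c(2, 1.5, 0.8, 0), beta = c(1, 0.5, 0, 1.2),
                   orders = c(g12 = 0.4, h11 = 0.5, g31 = 0.6, h44 = 0.5,
                              g24 = 0.3, h22 = 0.4, h43 = 0.2))
  truth <- ss_simulate(cad$model, c(0.5, 0.5, 0.3, 2), seq(0, 3, length.out = 20),
                       inputs = 1)
  fit <- fit_user_data(list(model = cad$model, mask = cad$mask, inputs = 1),
                       truth, algorithm = "pso", seed = 2,
                       n_particles = 10L, n_iterations = 30L)
  # structurally absent terms stay exactly zero in the fitted model
  expect_identical(fit$model$alpha[4], 0)
  expect_identical(fit$model$beta[3], 0)
})

test_that("dimension mismatches name the offending columns", {
  mod <- random_model(N = 2, m = 0, seed = 2)
  mask <- param_mask(rep(TRUE, 2), rep(TRUE, 2),
                     matrix(TRUE, 2, 2), matrix(TRUE, 2, 2))
  tr3 <- ss_trajectory(0:5, matrix(runif(18, 0.5, 1.5), 6, 3))
  expect_error(fit_user_data(list(model = mod, mask = mask), tr3,
                             algorithm = "pso"), "x3")
})
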
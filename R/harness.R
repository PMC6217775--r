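#' Search box for masked parameters
#'
#' Builds the per-dimension `(low, high)` box the optimizers search, in the
#' flat encoding order: rate coefficients get `rate_bounds` and kinetic
#' orders get `order_bounds`. The defaults (`[0, 25]` for rates, `[-2, 2]`
#' for orders) enclose the benchmark truth with a wide margin.
#'
#' @param mask A [param_mask()].
#' @param rate_bounds,order_bounds Length-2 `(low, high)` vectors.
#' @return Numeric `q x 2` matrix.
#' @export
param_bounds <- function(mask, rate_bounds = c(0, 25), order_bounds = c(-2, 2)) {
  stopifnot(inherits(mask, "ss_param_mask"))
  n_rate <- sum(mask$free_alpha) + sum(mask$free_beta)
  n_ord <- mask$q - n_rate
  rbind(matrix(rate_bounds, n_rate, 2, byrow = TRUE),
        matrix(order_bounds, n_ord, 2, byrow = TRUE))
}

#' Benchmark experiment configuration
#'
#' Describes one replicated comparison on the synthetic cascade benchmark:
#' the noise scenario, replicate count, algorithm set, the optimizer sizing
#' (which fixes the common fitness-evaluation budget), and the base seed
#' from which every per-replicate and per-algorithm seed is derived.
#'
#' PSO and SA receive the same total number of fitness evaluations as DPSO
#' (PSO through its iteration count, SA through its per-temperature move
#' count); the iterated UKF's cost unit is filter passes, not fitness
#' evaluations, so it is capped by `iukf_max_outer` instead.
#'
#' @param scenario `"noisefree"`, `"snr20"`, or `"custom"` (then give
#'   `snr_db`).
#' @param n_replicates Number of independent replicates (each draws a fresh
#'   initial state and, in noisy scenarios, fresh noise).
#' @param algorithms Subset of `c("dpso", "pso", "sa", "iukf")`.
#' @param base_seed Integer base seed.
#' @param snr_db SNR in dB for `scenario = "custom"`.
#' @param times Sample-time grid of the generated data.
#' @param sampler An [initial_state_sampler()] for the random initial states.
#' @param n_particles,n_iterations Phase-1 swarm sizing (also the PSO swarm
#'   size).
#' @param outer_iterations,inner_particles,inner_iterations DPSO phase-2
#'   sizing.
#' @param iukf_max_outer Filter-pass cap for the iterated UKF.
#' @param vmax_frac Velocity clamp for both swarm algorithms, as a fraction
#'   of each dimension's box width.
#' @param feasible_init Use feasibility-screened swarm initialization for
#'   both swarm algorithms (see [pso_config()]).
#' @param rate_bounds,order_bounds Search box, see [param_bounds()].
#' @return An object of class `ss_experiment_config`.
#' @export
experiment_config <- function(scenario = c("noisefree", "snr20", "custom"),
                              n_replicates = 20L,
                              algorithms = c("dpso", "pso", "sa", "iukf"),
                              base_seed = 1L, snr_db = NULL,
                              times = seq(0, 5, length.out = 50L),
                              sampler = initial_state_sampler(),
                              n_particles = 40L, n_iterations = 1000L,
                              outer_iterations = 6L,
                              inner_particles = 7L, inner_iterations = 14L,
                              iukf_max_outer = 50L,
                              vmax_frac = 0.05, feasible_init = TRUE,
                              rate_bounds = c(0, 25), order_bounds = c(-2, 2)) {
  scenario <- match.arg(scenario)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  if (length(algorithms) < 1L) stop("'algorithms' must be non-empty")
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1")
  snr <- switch(scenario, noisefree = Inf, snr20 = 20,
                custom = snr_db %||% stop("'custom' scenario needs 'snr_db'"))
  structure(list(scenario = scenario, snr_db = snr,
                 n_replicates = as.integer(n_replicates),
                 algorithms = algorithms, base_seed = as.integer(base_seed),
                 times = times, sampler = sampler,
                 n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 outer_iterations = as.integer(outer_iterations),
                 inner_particles = as.integer(inner_particles),
                 inner_iterations = as.integer(inner_iterations),
                 iukf_max_outer = as.integer(iukf_max_outer),
                 vmax_frac = vmax_frac, feasible_init = isTRUE(feasible_init),
                 rate_bounds = rate_bounds, order_bounds = order_bounds),
            class = "ss_experiment_config")
}

# Total fitness evaluations DPSO consumes under `cfg` (initial swarms
# included); the equalization target for PSO and SA.
dpso_eval_budget <- function(cfg, q) {
  cfg$n_particles * (cfg$n_iterations + 1L) +
    cfg$outer_iterations * q * cfg$inner_particles * (cfg$inner_iterations + 1L)
}

run_one_algorithm <- function(alg, seed, fit, ctx_fit, bounds, cfg, q,
                              observed) {
  budget <- dpso_eval_budget(cfg, q)
  vmax <- cfg$vmax_frac %||% 0.05
  feas <- cfg$feasible_init %||% TRUE
  if (alg == "dpso") {
    phase1 <- pso_config(cfg$n_particles, cfg$n_iterations, bounds,
                         vmax_frac = vmax, feasible_init = feas, seed = seed)
    dcfg <- dpso_config(phase1, outer_iterations = cfg$outer_iterations,
                        inner = pso_config(cfg$inner_particles,
                                           cfg$inner_iterations, bounds))
    run_dpso(dcfg, fit)
  } else if (alg == "pso") {
    iters <- max(1L, as.integer(round(budget / cfg$n_particles)) - 1L)
    run_pso(pso_config(cfg$n_particles, iters, bounds, vmax_frac = vmax,
                       feasible_init = feas, seed = seed), fit)
  } else if (alg == "sa") {
    n_temps <- sa_n_temps(1, 1e-3, 0.95)
    moves <- max(1L, as.integer(ceiling((budget - 51L) / n_temps)))
    run_sa(sa_config(bounds, cooling_factor = 0.95, inner_moves = moves,
                     max_evaluations = budget, seed = seed), fit)
  } else {  # iukf
    omega0 <- with_seed(seed, stats::runif(q, bounds[, 1L], bounds[, 2L]))
    ukf0 <- ukf_state(omega0, P = 0.5, Rr = 1e-5, Re = 1e-2,
                      epsilon = 0.5, kappa = 0, bounds = bounds)
    # the filter's one-interval predictions tolerate a higher step cap than
    # the swarm objective: a failed propagation degrades the whole update
    ctx_iukf <- ctx_fit
    ctx_iukf$max_steps <- 300L
    run_iukf(iukf_config(max_outer = cfg$iukf_max_outer,
                         proj_bounds = bounds, P0 = 0.5, seed = seed),
             ukf0, observed, ctx_iukf)
  }
}

#' Run a replicated benchmark experiment
#'
#' For every replicate `r` (seed `base_seed + r`): draw a random initial
#' state, simulate the four-state cascade truth on the configured time grid,
#' apply the scenario's noise, and run every selected algorithm on the same
#' observed data with the same evaluation budget. Estimates are scored by
#' the normalized trajectory RMSE against the noise-free truth (the observed
#' data drive the fit; the truth is the reference, which is available here
#' because the data are synthetic). The whole experiment is deterministic
#' given `base_seed`.
#'
#' @param cfg An [experiment_config()].
#' @param progress Emit a per-replicate progress line on stderr.
#' @return An object of class `ss_benchmark_report`: per-algorithm RMSE
#'   vectors and means, mean decoded parameter estimates (as
#'   `ssystem_model` objects), evaluation counts, DPSO improvement
#'   percentages, and the per-replicate seeds.
#' @export
run_experiment <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "ss_experiment_config"))
  model <- benchmark_model()
  mask <- benchmark_mask()
  q <- n_free(mask)
  bounds <- param_bounds(mask, cfg$rate_bounds, cfg$order_bounds)
  algs <- cfg$algorithms
  rmse <- lapply(algs, function(a) numeric(cfg$n_replicates))
  names(rmse) <- algs
  evals <- rmse
  par_sum <- lapply(algs, function(a) numeric(q))
  names(par_sum) <- algs
  seeds <- integer(cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    seed_r <- cfg$base_seed + r
    seeds[r] <- seed_r
    sampler <- initial_state_sampler(cfg$sampler$low, cfg$sampler$high,
                                     seed = seed_r, n = model$n_dependent)
    x0 <- sample_initial_state(sampler)
    truth <- ss_simulate(model, x0, cfg$times, inputs = 1)
    if (isTRUE(attr(truth, "failed")))
      stop("truth simulation failed at replicate ", r)
    observed <- add_noise(truth, cfg$snr_db, seed = seed_r + 500000L)
    # candidates are scored against the observed data at search tolerances;
    # the final estimate is re-scored against the truth at tight tolerances
    ctx_fit <- fitness_context(observed, model, mask, x0 = x0, inputs = c(1),
                               rtol = 1e-4, atol = 1e-6, max_steps = 150L)
    ctx_truth <- fitness_context(truth, model, mask, x0 = x0, inputs = c(1))
    fit <- ss_fitness(ctx_fit)
    score <- ss_fitness(ctx_truth)
    for (a in algs) {
      seed_a <- seed_r * 1000L +
        c(dpso = 1L, pso = 1L, sa = 3L, iukf = 4L)[[a]]
      res <- run_one_algorithm(a, seed_a, fit, ctx_fit, bounds, cfg, q,
                               observed)
      rmse[[a]][r] <- score(res$best_vector)
      evals[[a]][r] <- res$evaluations
      par_sum[[a]] <- par_sum[[a]] + res$best_vector
    }
    if (progress)
      message(sprintf("replicate %d/%d done (%s)", r, cfg$n_replicates,
                      paste(sprintf("%s=%.4f", algs,
                                    vapply(rmse, `[`, 0, r)), collapse = " ")))
  }
  mean_rmse <- vapply(rmse, mean, 0)
  mean_params <- lapply(par_sum, function(s)
    ss_decode(s / cfg$n_replicates, mask, model))
  improvement <- NULL
  if ("dpso" %in% algs && length(algs) > 1L) {
    others <- setdiff(algs, "dpso")
    improvement <- vapply(others, function(a)
      improvement_pct(mean_rmse[[a]], mean_rmse[["dpso"]]), 0)
  }
  structure(list(config = cfg, seeds = seeds, rmse = rmse,
                 mean_rmse = mean_rmse, mean_params = mean_params,
                 evaluations = evals, improvement = improvement),
            class = "ss_benchmark_report")
}

#' @export
print.ss_benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark report: scenario %s, %d replicates\n",
              x$config$scenario, x$config$n_replicates))
  cat("mean normalized RMSE:\n")
  for (a in names(x$mean_rmse))
    cat(sprintf("  %-5s %.4f\n", a, x$mean_rmse[[a]]))
  if (!is.null(x$improvement)) {
    cat("DPSO improvement over:\n")
    for (a in names(x$improvement))
      cat(sprintf("  %-5s %.2f%%\n", a, x$improvement[[a]]))
  }
  invisible(x)
}

#' Percentage RMSE improvement of DPSO over a baseline
#'
#' `100 * (baseline - dpso) / baseline`.
#'
#' @param baseline_rmse Baseline mean RMSE (> 0).
#' @param dpso_rmse DPSO mean RMSE.
#' @return Percentage improvement.
#' @examples
#' improvement_pct(0.4040, 0.2291)
#' @export
improvement_pct <- function(baseline_rmse, dpso_rmse) {
  if (!(is.numeric(baseline_rmse) && baseline_rmse > 0))
    stop("'baseline_rmse' must be positive")
  100 * (baseline_rmse - dpso_rmse) / baseline_rmse
}

params_table <- function(model) {
  N <- model$n_dependent
  data.frame(state = paste0("x", seq_len(N)),
             alpha = model$alpha,
             stats::setNames(as.data.frame(model$G[, seq_len(N), drop = FALSE]),
                             paste0("g", seq_len(N))),
             beta = model$beta,
             stats::setNames(as.data.frame(model$H[, seq_len(N), drop = FALSE]),
                             paste0("h", seq_len(N))),
             check.names = FALSE)
}

#' Write a benchmark report to disk
#'
#' Emits, per algorithm, the mean-parameter table
#' (`params_<alg>.csv`; one row per state with columns
#' `state, alpha, g1..gN, beta, h1..hN`) and the per-replicate RMSE list
#' (`rmse_<alg>.csv`), plus a machine-readable `summary.json` carrying the
#' configuration, seeds, per-replicate RMSEs and means.
#'
#' @param report An `ss_benchmark_report`.
#' @param dir Output directory (created if missing).
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ss_benchmark_report"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory '", dir, "'")
  paths <- character(0)
  for (a in names(report$rmse)) {
    p1 <- file.path(dir, paste0("params_", a, ".csv"))
    utils::write.csv(params_table(report$mean_params[[a]]), p1,
                     row.names = FALSE)
    p2 <- file.path(dir, paste0("rmse_", a, ".csv"))
    utils::write.csv(data.frame(replicate = seq_along(report$rmse[[a]]),
                                rmse = report$rmse[[a]]), p2,
                     row.names = FALSE)
    paths <- c(paths, p1, p2)
  }
  cfg <- report$config
  summary <- list(
    scenario = cfg$scenario, snr_db = cfg$snr_db,
    n_replicates = cfg$n_replicates, algorithms = cfg$algorithms,
    base_seed = cfg$base_seed, seeds = report$seeds,
    mean_rmse = as.list(report$mean_rmse),
    rmse = report$rmse,
    evaluations = lapply(report$evaluations, as.numeric),
    improvement = as.list(report$improvement))
  pj <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, pj, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(c(paths, pj))
}

#' Fit a user-supplied model specification to trajectory data
#'
#' Runs one of the four estimators on arbitrary data: `spec` fixes the model
#' structure (template + free mask + inputs), `data` supplies the measured
#' time course, and the chosen algorithm searches the masked parameters
#' within the standard box. The fitted model is re-simulated at the data's
#' sample times for overlay comparison.
#'
#' @param spec Path to a model-specification file (see
#'   [write_model_spec()]) or the list returned by [read_model_spec()].
#' @param data Path to a trajectory CSV (see [read_trajectory()]) or an
#'   [ss_trajectory()].
#' @param algorithm One of `"dpso"`, `"pso"`, `"sa"`, `"iukf"`.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, the estimated parameter
#'   table and the fitted trajectory CSV are written there.
#' @param n_particles,n_iterations,outer_iterations,inner_particles,inner_iterations,iukf_max_outer
#'   Optimizer sizing, as in [experiment_config()].
#' @param rate_bounds,order_bounds Search box.
#' @return A list with `result` (the `ss_opt_result`), `model` (the fitted
#'   [ss_model()]), `fitted` (the re-simulated [ss_trajectory()]) and
#'   `rmse` (normalized RMSE of the fit against `data`).
#' @export
fit_user_data <- function(spec, data,
                          algorithm = c("dpso", "pso", "sa", "iukf"),
                          seed = 1L, out_dir = NULL,
                          n_particles = 40L, n_iterations = 300L,
                          outer_iterations = 5L, inner_particles = 15L,
                          inner_iterations = 40L, iukf_max_outer = 50L,
                          rate_bounds = c(0, 25), order_bounds = c(-2, 2)) {
  algorithm <- match.arg(algorithm)
  if (is.character(spec)) spec <- read_model_spec(spec)
  if (is.character(data)) data <- read_trajectory(data)
  stopifnot(inherits(data, "ss_trajectory"))
  model <- spec$model
  if (ncol(data$states) != model$n_dependent)
    stop("data has state columns ",
         paste(colnames(data$states), collapse = ", "),
         " but the model expects ", model$n_dependent,
         " dependent state(s)")
  mask <- spec$mask
  q <- n_free(mask)
  bounds <- param_bounds(mask, rate_bounds, order_bounds)
  inputs <- spec$inputs %||% numeric(model$n_independent)
  ctx <- fitness_context(data, model, mask, inputs = inputs)
  fit <- ss_fitness(ctx)
  cfg <- list(n_particles = n_particles, n_iterations = n_iterations,
              outer_iterations = outer_iterations,
              inner_particles = inner_particles,
              inner_iterations = inner_iterations,
              iukf_max_outer = iukf_max_outer)
  res <- run_one_algorithm(algorithm, seed, fit, ctx, bounds, cfg, q, data)
  fitted_model <- ss_decode(res$best_vector, mask, model)
  fitted <- ss_simulate(fitted_model, ctx$x0, data$times, inputs = inputs)
  rmse <- if (isTRUE(attr(fitted, "failed"))) NA_real_ else
    traj_rmse(data, fitted)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory '", out_dir, "'")
    utils::write.csv(params_table(fitted_model),
                     file.path(out_dir, paste0("params_", algorithm, ".csv")),
                     row.names = FALSE)
    if (!isTRUE(attr(fitted, "failed")))
      write_trajectory(fitted, file.path(out_dir, "fitted_trajectory.csv"))
  }
  list(result = res, model = fitted_model, fitted = fitted, rmse = rmse)
}
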
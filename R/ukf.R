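#' Unscented Kalman filter state for parameter estimation
#'
#' Joint parameter estimation treats the unknown S-system parameter vector
#' `omega` as the state of a random-walk process
#' `omega[k+1] = omega[k] + r[k]` observed through the one-step-ahead
#' measurement map `y[k] = F(x[k], u[k], omega) + e[k]`, where `F` predicts
#' the next measured concentration vector from the current one. The UKF
#' propagates `2q + 1` deterministically placed sigma points through `F`
#' instead of linearizing it.
#'
#' The sigma-point geometry follows the standard scaled unscented transform:
#' `lambda = epsilon^2 (q + kappa) - q`, spread `gamma = sqrt(q + lambda)`,
#' centre weight `W0 = lambda / (lambda + q)` and wing weights
#' `Wi = 1 / (2 (lambda + q))` (identical for mean and covariance), so the
#' weights sum to one exactly.
#'
#' @param omega_hat Initial parameter mean, length `q`.
#' @param P Initial `q x q` parameter covariance.
#' @param Rr Process-noise covariance (scalar = multiple of identity).
#' @param Re Measurement-noise covariance (scalar = multiple of identity,
#'   sized on first use).
#' @param epsilon Sigma-point spread constant, in `(1e-4, 1)`.
#' @param kappa Secondary scaling constant, conventionally `0` or `3 - q`.
#' @param bounds Optional `q x 2` projection box for the parameter update
#'   (componentwise clamp).
#' @return An object of class `ss_ukf_state`.
#' @export
ukf_state <- function(omega_hat, P, Rr = 1e-5, Re = 1e-2,
                      epsilon = 0.5, kappa = 0, bounds = NULL) {
  omega_hat <- as.numeric(omega_hat)
  q <- length(omega_hat)
  if (!(epsilon > 1e-4 && epsilon < 1))
    stop("'epsilon' must lie in (1e-4, 1)")
  if (is.null(dim(P))) P <- diag(as.numeric(P), q)
  if (is.null(dim(Rr))) Rr <- diag(as.numeric(Rr), q)
  if (!all(dim(P) == q) || !all(dim(Rr) == q))
    stop("'P' and 'Rr' must be q x q")
  lambda <- epsilon^2 * (q + kappa) - q
  wm <- c(lambda / (lambda + q), rep(1 / (2 * (lambda + q)), 2 * q))
  structure(list(omega_hat = omega_hat, P = unname(as.matrix(P)),
                 Rr = unname(as.matrix(Rr)), Re = Re,
                 epsilon = epsilon, kappa = kappa,
                 lambda = lambda, gamma = sqrt(q + lambda),
                 weights_m = wm, weights_c = wm,
                 bounds = bounds, q = q, pinv_count = 0L),
            class = "ss_ukf_state")
}

#' Sigma points of the predicted parameter distribution
#'
#' Forms the `2q + 1` sigma vectors
#' `[omega, omega + gamma * S_i, omega - gamma * S_i]` around the predicted
#' mean, where `S` is the symmetric (eigen) matrix square root of the
#' predicted covariance `P + Rr`. A covariance with a meaningfully negative
#' eigenvalue is signaled as an error; near-singular spectra get a `1e-10`
#' diagonal jitter.
#'
#' @param state An [ukf_state()].
#' @return Numeric `q x (2q + 1)` matrix of sigma columns.
#' @export
sigma_points <- function(state) {
  stopifnot(inherits(state, "ss_ukf_state"))
  q <- state$q
  Pm <- state$P + state$Rr
  Pm <- (Pm + t(Pm)) / 2
  eg <- eigen(Pm, symmetric = TRUE)
  tol <- 1e-8 * max(abs(eg$values), 1e-300)
  if (min(eg$values) < -tol)
    stop("predicted covariance is not positive semi-definite")
  d <- pmax(eg$values, 0)
  if (min(d) < 1e-12 * max(d, 1e-300)) d <- d + 1e-10
  S <- eg$vectors %*% (sqrt(d) * t(eg$vectors))
  om <- state$omega_hat
  cbind(om, om + state$gamma * S, om - state$gamma * S, deparse.level = 0)
}

proj_box <- function(x, bounds) {
  if (is.null(bounds)) x else clamp(x, bounds[, 1L], bounds[, 2L])
}

#' One UKF measurement update
#'
#' Performs a single sigma-point update of the parameter estimate: predict
#' (`P <- P + Rr`, mean unchanged under the random-walk process), transform
#' the sigma points through the measurement map, form the predicted
#' measurement mean and covariance (with `Re` added), the cross covariance,
#' the Kalman gain, and the projected state update with its covariance
#' downdate. A singular innovation covariance falls back to the
#' Moore-Penrose pseudo-inverse (counted in `pinv_count`).
#'
#' @param state An [ukf_state()].
#' @param measurement Observed vector `d[k]`.
#' @param measure_fn Measurement map: takes the `q x (2q+1)` sigma matrix
#'   and returns a `d x (2q+1)` matrix of predicted measurements (one
#'   column per sigma vector).
#' @return The updated `ss_ukf_state`.
#' @export
ukf_step <- function(state, measurement, measure_fn) {
  stopifnot(inherits(state, "ss_ukf_state"))
  q <- state$q
  sig <- sigma_points(state)
  Pm <- state$P + state$Rr
  D <- measure_fn(sig)
  if (is.null(dim(D))) D <- matrix(D, nrow = 1L)
  if (ncol(D) != 2L * q + 1L)
    stop("'measure_fn' must return one column per sigma vector")
  d_dim <- nrow(D)
  Re <- state$Re
  if (is.null(dim(Re))) Re <- diag(as.numeric(Re), d_dim)
  wc <- state$weights_c
  dhat <- as.numeric(D %*% state$weights_m)
  Dc <- D - dhat
  Pdd <- Dc %*% (wc * t(Dc)) + Re
  Wc <- sig - state$omega_hat
  Pwd <- Wc %*% (wc * t(Dc))
  K <- tryCatch(Pwd %*% solve(Pdd),
                error = function(e) {
                  state$pinv_count <<- state$pinv_count + 1L
                  Pwd %*% MASS::ginv(Pdd)
                })
  innov <- as.numeric(measurement) - dhat
  state$omega_hat <- proj_box(state$omega_hat + as.numeric(K %*% innov),
                              state$bounds)
  Pnew <- Pm - K %*% Pdd %*% t(K)
  Pnew <- (Pnew + t(Pnew)) / 2
  # the covariance downdate can leave a slightly indefinite matrix when the
  # centre sigma weight is negative; clamp the spectrum at zero
  eg <- eigen(Pnew, symmetric = TRUE)
  if (min(eg$values) < 0)
    Pnew <- eg$vectors %*% (pmax(eg$values, 1e-12) * t(eg$vectors))
  state$P <- Pnew
  state
}

#' Iterated UKF configuration
#'
#' @param delta_E Stop threshold on the post-pass trajectory RMSE.
#' @param delta_R Restart threshold: when two consecutive pass RMSEs differ
#'   by less than `delta_R`, the covariance is reset to `P0` to reopen the
#'   saturated filter gain.
#' @param max_outer Cap on full-data filter passes.
#' @param proj_bounds `q x 2` projection box applied inside every update.
#' @param P0 Initial covariance (scalar = multiple of identity); also the
#'   reset target.
#' @param seed Integer seed for the divergence-restart jitter, or `NULL`.
#' @return An object of class `ss_iukf_config`.
#' @export
iukf_config <- function(delta_E = 1e-3, delta_R = 1e-4, max_outer = 50L,
                        proj_bounds = NULL, P0 = 0.5, seed = NULL) {
  if (delta_E <= 0 || delta_R <= 0 || max_outer < 1L)
    stop("need delta_E > 0, delta_R > 0, max_outer >= 1")
  structure(list(delta_E = delta_E, delta_R = delta_R,
                 max_outer = as.integer(max_outer),
                 proj_bounds = proj_bounds, P0 = P0, seed = seed),
            class = "ss_iukf_config")
}

# Restart decision of the iterated filter: stalled consecutive RMSEs reopen
# the covariance.
iukf_should_reset <- function(rmse_prev, rmse, delta_R) {
  is.finite(rmse_prev) && is.finite(rmse) && abs(rmse - rmse_prev) < delta_R
}

#' Run the iterated UKF parameter estimator
#'
#' Repeats full-data UKF passes over the one-step-ahead measurement pairs
#' `(x[k] -> x[k+1])` of `data`. After each pass the trajectory RMSE of the
#' current estimate is computed through the fitness context; the loop stops
#' when it drops below `delta_E` or `max_outer` passes are reached. Each new
#' pass starts from the previous parameter estimate and covariance, which is
#' what lets the iteration escape the early gain saturation of a single UKF
#' run; when the RMSE stalls (consecutive difference below `delta_R`) the
#' covariance is reset to `P0`. A diverged pass (non-finite or penalty RMSE)
#' restarts from `P0` with a jittered parameter mean.
#'
#' @param cfg An [iukf_config()].
#' @param ukf0 Initial [ukf_state()] (its bounds are overridden by
#'   `cfg$proj_bounds` when supplied).
#' @param data Measured [ss_trajectory()] with at least two samples.
#' @param ctx An [fitness_context()] describing the model template, mask
#'   and RMSE convention.
#' @return An `ss_opt_result` with extra fields `pass_rmse` (per-pass RMSE),
#'   `resets` (covariance resets triggered) and `pinv_count`.
#' @export
run_iukf <- function(cfg, ukf0, data, ctx) {
  stopifnot(inherits(cfg, "ss_iukf_config"), inherits(ukf0, "ss_ukf_state"),
            inherits(data, "ss_trajectory"),
            inherits(ctx, "ss_fitness_context"))
  nt <- length(data$times)
  if (nt < 2L) stop("'data' must contain at least two samples")
  with_seed(cfg$seed, {
    state <- ukf0
    if (!is.null(cfg$proj_bounds)) state$bounds <- cfg$proj_bounds
    q <- state$q
    P0 <- if (is.null(dim(cfg$P0))) diag(as.numeric(cfg$P0), q) else cfg$P0
    fitness <- ss_fitness(ctx)
    idx <- mask_flat_idx(ctx$mask)
    tmpl <- model_flat(ctx$template)
    N <- ctx$template$n_dependent
    m <- ctx$template$n_independent
    Y <- data$states
    tt <- data$times
    measure_at <- function(k) {
      x_from <- pmax(Y[k, ], 1e-6)
      force(x_from)
      function(sig) {
        res <- .cpp_predict_batch(t(sig), idx, tmpl, N, m, x_from,
                                  ctx$inputs, tt[k], tt[k + 1L],
                                  ctx$rtol, ctx$atol, ctx$max_steps)
        pred <- res$pred
        if (any(!res$ok))  # failed propagation: neutral no-change prediction
          pred[!res$ok, ] <- matrix(x_from, sum(!res$ok), N, byrow = TRUE)
        t(pred)
      }
    }
    re_nominal <- state$Re
    best <- state$omega_hat
    best_f <- fitness(best)
    trace <- numeric(0)
    pass_rmse <- numeric(0)
    resets <- 0L
    evals <- 1L
    rmse_prev <- Inf
    # a pass whose RMSE exceeds the data's own root-mean-square scale by a
    # wide margin fits worse than predicting zero; treat it as divergence
    diverge_at <- min(ctx$penalty, 3 * sqrt(mean(Y^2)))
    for (pass in seq_len(cfg$max_outer)) {
      for (k in seq_len(nt - 1L)) {
        state <- ukf_step(state, Y[k + 1L, ], measure_at(k))
        evals <- evals + 2L * q + 1L
      }
      rmse <- fitness(state$omega_hat)
      evals <- evals + 1L
      pass_rmse <- c(pass_rmse, rmse)
      if (is.finite(rmse) && rmse < best_f) {
        best_f <- rmse
        best <- state$omega_hat
      }
      trace <- c(trace, best_f)
      if (!is.finite(rmse) || rmse >= diverge_at) {
        # diverged: restart around the best estimate seen so far, or from a
        # fresh prior draw when no usable estimate exists yet; every other
        # restart inflates the assumed measurement noise tenfold to damp
        # the gain on data where the nominal level overshoots
        state$P <- P0
        state$Re <- if (resets %% 2L == 0L) re_nominal * 10 else re_nominal
        state$omega_hat <- if (is.finite(best_f) && best_f < diverge_at) {
          proj_box(best + stats::rnorm(q, 0, 0.05), state$bounds)
        } else if (!is.null(state$bounds)) {
          stats::runif(q, state$bounds[, 1L], state$bounds[, 2L])
        } else {
          ukf0$omega_hat + stats::rnorm(q, 0, 1)
        }
        resets <- resets + 1L
        rmse_prev <- Inf
        next
      }
      if (rmse < cfg$delta_E) break
      if (iukf_should_reset(rmse_prev, rmse, cfg$delta_R)) {
        state$P <- P0
        resets <- resets + 1L
      }
      rmse_prev <- rmse
    }
    out <- new_opt_result(best, best_f, trace, evals, cfg$seed)
    out$pass_rmse <- pass_rmse
    out$resets <- resets
    out$pinv_count <- state$pinv_count
    out
  })
}
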
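#' Free-parameter mask of an S-system
#'
#' A structure mask records which model entries are estimated. The flat
#' encoding used throughout the optimizers orders the free entries as: all
#' free production rates `alpha` (by state), then free degradation rates
#' `beta`, then free production orders `G` row by row, then free degradation
#' orders `H` row by row. For a fully free model the count is
#' `q = N (2 + 2 (N + m))`.
#'
#' @param free_alpha,free_beta Logical vectors of length `N`.
#' @param free_G,free_H Logical `N x (N+m)` matrices.
#' @return An object of class `ss_param_mask`.
#' @export
param_mask <- function(free_alpha, free_beta, free_G, free_H) {
  free_alpha <- as.logical(free_alpha)
  free_beta <- as.logical(free_beta)
  free_G <- as.matrix(free_G)
  free_H <- as.matrix(free_H)
  N <- length(free_alpha)
  if (length(free_beta) != N || nrow(free_G) != N || nrow(free_H) != N ||
      !all(dim(free_G) == dim(free_H)))
    stop("mask dimensions are inconsistent")
  q <- sum(free_alpha) + sum(free_beta) + sum(free_G) + sum(free_H)
  if (q < 1L) stop("at least one parameter must be free")
  structure(list(free_alpha = free_alpha, free_beta = free_beta,
                 free_G = free_G, free_H = free_H, q = q),
            class = "ss_param_mask")
}

#' @export
print.ss_param_mask <- function(x, ...) {
  cat(sprintf("S-system parameter mask: %d free of %d entries\n",
              x$q, 2 * length(x$free_alpha) + 2 * length(x$free_G)))
  invisible(x)
}

#' Number of free parameters
#' @param mask An [param_mask()].
#' @return Integer count `q`.
#' @export
n_free <- function(mask) {
  stopifnot(inherits(mask, "ss_param_mask"))
  mask$q
}

check_mask_model <- function(mask, model) {
  if (length(mask$free_alpha) != model$n_dependent ||
      !all(dim(mask$free_G) ==
           c(model$n_dependent, model$n_dependent + model$n_independent)))
    stop("mask dimensions do not match the model")
}

# 0-based indices of the free entries inside the flat column-major layout
# c(alpha, beta, G, H), ordered alpha, beta, G row-major, H row-major --
# the same order encode()/decode() use. Consumed by the C++ batch kernels.
mask_flat_idx <- function(mask) {
  N <- length(mask$free_alpha)
  nc <- ncol(mask$free_G)
  rowmajor <- function(M, offset) {
    idx <- which(t(M))  # row-major enumeration
    ij <- arrayInd(idx, c(nc, N))  # (col, row) of the transposed matrix
    offset + (ij[, 2L] - 1L) + (ij[, 1L] - 1L) * N
  }
  c(which(mask$free_alpha) - 1L,
    N + which(mask$free_beta) - 1L,
    rowmajor(mask$free_G, 2L * N),
    rowmajor(mask$free_H, 2L * N + N * nc))
}

model_flat <- function(model) {
  c(model$alpha, model$beta, as.vector(model$G), as.vector(model$H))
}

#' Encode a model as a flat parameter vector
#'
#' Extracts the free entries of `model` selected by `mask` in the canonical
#' order (free `alpha`, free `beta`, free `G` row-major, free `H` row-major).
#' [ss_decode()] is its inverse on the free subspace.
#'
#' @param model An [ss_model()].
#' @param mask A matching [param_mask()].
#' @return Numeric vector of length `n_free(mask)`.
#' @export
ss_encode <- function(model, mask) {
  stopifnot(inherits(model, "ssystem_model"), inherits(mask, "ss_param_mask"))
  check_mask_model(mask, model)
  model_flat(model)[mask_flat_idx(mask) + 1L]
}

#' Decode a flat parameter vector into a model
#'
#' Overwrites the free entries of `template` with `values` (in the canonical
#' encoding order); fixed entries are untouched. Rate coefficients may decode
#' to any finite value during optimization, so the non-negativity invariant
#' of [ss_model()] is not re-enforced here beyond a floor at 0 applied to
#' negative rates.
#'
#' @param values Numeric vector of length `n_free(mask)`.
#' @param mask A [param_mask()].
#' @param template An [ss_model()] supplying the fixed entries.
#' @return An `ssystem_model`.
#' @export
ss_decode <- function(values, mask, template) {
  stopifnot(inherits(template, "ssystem_model"), inherits(mask, "ss_param_mask"))
  check_mask_model(mask, template)
  if (length(values) != mask$q)
    stop("'values' must have length ", mask$q)
  flat <- model_flat(template)
  flat[mask_flat_idx(mask) + 1L] <- values
  N <- template$n_dependent
  nc <- N + template$n_independent
  ss_model(alpha = pmax(flat[1:N], 0),
           beta = pmax(flat[(N + 1):(2 * N)], 0),
           G = matrix(flat[2 * N + seq_len(N * nc)], N, nc),
           H = matrix(flat[2 * N + N * nc + seq_len(N * nc)], N, nc),
           n_independent = template$n_independent)
}

#' Trajectory root-mean-square error
#'
#' Two variants of the trajectory discrepancy are supported. The summed
#' variant is \eqn{\sqrt{\sum_k \sum_i (y_{ki} - \hat y_{ki})^2}} over all
#' sample times and states; the normalized variant (the default reporting
#' metric) replaces the sum by the mean, so the two differ exactly by the
#' factor \eqn{\sqrt{nN}}. Both pool all states and times into one scalar.
#'
#' @param y,yhat [ss_trajectory()] objects with identical times and shapes.
#' @param normalized Use the mean-based variant (default `TRUE`).
#' @return Non-negative scalar.
#' @export
traj_rmse <- function(y, yhat, normalized = TRUE) {
  stopifnot(inherits(y, "ss_trajectory"), inherits(yhat, "ss_trajectory"))
  if (!all(dim(y$states) == dim(yhat$states)) ||
      length(y$times) != length(yhat$times) ||
      any(abs(y$times - yhat$times) > 1e-12))
    stop("trajectories must share shape and sample times")
  sq <- sum((y$states - yhat$states)^2)
  if (normalized) sqrt(sq / length(y$states)) else sqrt(sq)
}

#' Fitness context for parameter estimation
#'
#' Bundles everything needed to score a candidate parameter vector: the
#' measured trajectory, the model template with its fixed entries, the free
#' mask, the initial state candidate simulations start from, the constant
#' inputs, the failure penalty, and the RMSE variant.
#'
#' Candidate simulations start from `x0`; by default that is the first
#' sample of `data` (the noise-free value when the caller has it, otherwise
#' the observed first row) — the initial state is not estimated.
#'
#' @param data The measured [ss_trajectory()].
#' @param template [ss_model()] carrying fixed entries.
#' @param mask [param_mask()] of free entries.
#' @param x0 Initial state for candidate simulations.
#' @param inputs Constant independent-input values.
#' @param penalty Fitness assigned on simulation failure; must dominate any
#'   attainable RMSE (default `1e6`).
#' @param normalized RMSE variant flag (default `TRUE`).
#' @param rtol,atol Integration tolerances used when scoring candidates.
#' @param max_steps Integration-step cap per output interval when scoring a
#'   candidate; exceeding it counts as a simulation failure. The default
#'   (2000) is far above what any well-behaved candidate needs and bounds
#'   the cost of the near-stiff parameter regions optimizers explore.
#' @return An object of class `ss_fitness_context`.
#' @export
fitness_context <- function(data, template, mask,
                            x0 = pmax(data$states[1L, ], 1e-6),
                            inputs = data$inputs, penalty = 1e6,
                            normalized = TRUE, rtol = 1e-6, atol = 1e-8,
                            max_steps = 2000L) {
  stopifnot(inherits(data, "ss_trajectory"), inherits(template, "ssystem_model"),
            inherits(mask, "ss_param_mask"))
  check_mask_model(mask, template)
  if (ncol(data$states) != template$n_dependent)
    stop("data has ", ncol(data$states), " state columns but the model has ",
         template$n_dependent, " dependent states")
  if (length(inputs) != template$n_independent)
    stop("'inputs' must have length ", template$n_independent)
  if (penalty <= 0) stop("'penalty' must be positive")
  structure(list(data = data, template = template, mask = mask,
                 x0 = as.numeric(x0), inputs = as.numeric(inputs),
                 penalty = penalty, normalized = isTRUE(normalized),
                 rtol = rtol, atol = atol,
                 max_steps = as.integer(max_steps)),
            class = "ss_fitness_context")
}

#' Trajectory-RMSE fitness function
#'
#' Builds the scalar objective the optimizers minimize: decode the candidate
#' vector into a model, simulate it from `ctx$x0` at the data's sample
#' times, and return the RMSE against the data; a failed simulation scores
#' `ctx$penalty`. The returned function accepts a single parameter vector;
#' its `"batch"` attribute holds a matrix version (one candidate per row)
#' that the swarm optimizers use to score whole populations in one call.
#' Evaluation is deterministic: repeated calls are bit-identical.
#'
#' @param ctx An [fitness_context()].
#' @return A function `ParameterVector -> scalar` with attribute `"batch"`.
#' @examples
#' mod <- benchmark_model()
#' tr <- ss_simulate(mod, rep(0.5, 4), seq(0, 5, length.out = 50), inputs = 1)
#' f <- ss_fitness(fitness_context(tr, mod, benchmark_mask(), x0 = rep(0.5, 4)))
#' f(ss_encode(mod, benchmark_mask()))  # self-fit: integration error only
#' @export
ss_fitness <- function(ctx) {
  stopifnot(inherits(ctx, "ss_fitness_context"))
  idx <- mask_flat_idx(ctx$mask)
  tmpl <- model_flat(ctx$template)
  N <- ctx$template$n_dependent
  m <- ctx$template$n_independent
  data_mat <- ctx$data$states
  times <- ctx$data$times
  batch <- function(P) {
    .cpp_fitness_batch(P, idx, tmpl, N, m, data_mat, times, ctx$x0,
                       ctx$inputs, ctx$rtol, ctx$atol, ctx$max_steps,
                       ctx$penalty, ctx$normalized)
  }
  f <- function(values) batch(matrix(as.numeric(values), nrow = 1L))[1L]
  attr(f, "batch") <- batch
  attr(f, "context") <- ctx
  f
}
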
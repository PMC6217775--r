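#' Construct an S-system model
#'
#' An S-system describes each dependent state \eqn{x_i} of a biochemical
#' network by a difference of two power-law terms,
#' \deqn{\dot x_i = \alpha_i \prod_{j=1}^{N+m} x_j^{g_{ij}}
#'       - \beta_i \prod_{j=1}^{N+m} x_j^{h_{ij}},}
#' where the product runs over the \eqn{N} dependent states followed by the
#' \eqn{m} constant independent inputs. \eqn{\alpha_i, \beta_i \ge 0} are
#' production/degradation rate coefficients and the kinetic orders
#' \eqn{g_{ij}, h_{ij}} are real exponents (negative values encode
#' inhibition). A zero rate coefficient encodes a structurally absent term.
#'
#' @param alpha Numeric vector of length `N`, production rate coefficients
#'   (concentration/time). Must be non-negative.
#' @param beta Numeric vector of length `N`, degradation rate coefficients.
#'   Must be non-negative.
#' @param G,H Numeric `N x (N+m)` matrices of production/degradation kinetic
#'   orders (dimensionless). All entries must be finite.
#' @param n_independent Number `m >= 0` of constant independent inputs.
#'
#' @return An object of class `ssystem_model` with fields `alpha`, `beta`,
#'   `G`, `H`, `n_dependent`, `n_independent`.
#' @examples
#' # one-state linear system dx/dt = 2 - x
#' m <- ss_model(alpha = 2, beta = 1,
#'               G = matrix(0, 1, 1), H = matrix(1, 1, 1))
#' ss_rates(m, state = 1.5)
#' @export
ss_model <- function(alpha, beta, G, H, n_independent = ncol(G) - length(alpha)) {
  alpha <- as.numeric(alpha)
  beta <- as.numeric(beta)
  N <- length(alpha)
  G <- as.matrix(G)
  H <- as.matrix(H)
  m <- as.integer(n_independent)
  if (N < 1L) stop("an S-system needs at least one dependent state")
  if (N > 32L) stop("at most 32 dependent states are supported")
  if (m < 0L) stop("'n_independent' must be >= 0")
  if (length(beta) != N) stop("'alpha' and 'beta' must have equal length")
  if (any(alpha < 0) || any(beta < 0))
    stop("rate coefficients must be non-negative")
  for (nm in c("G", "H")) {
    M <- get(nm)
    if (!all(dim(M) == c(N, N + m)))
      stop(sprintf("'%s' must be a %d x %d matrix", nm, N, N + m))
    if (!all(is.finite(M))) stop(sprintf("'%s' must be finite", nm))
  }
  structure(
    list(alpha = alpha, beta = beta,
         G = unname(G), H = unname(H),
         n_dependent = N, n_independent = m),
    class = "ssystem_model")
}

#' @export
print.ssystem_model <- function(x, ...) {
  cat(sprintf("S-system model: %d dependent state(s), %d independent input(s)\n",
              x$n_dependent, x$n_independent))
  cat(sprintf("  nonzero kinetic orders: %d in G, %d in H\n",
              sum(x$G != 0), sum(x$H != 0)))
  invisible(x)
}

#' Evaluate S-system rates
#'
#' Computes the derivative vector \eqn{\dot x} of [ss_model()] at a given
#' state. States (and inputs) are clipped to a floor of `1e-9` before the
#' power laws are evaluated, so fractional and negative kinetic orders stay
#' defined when an optimizer wanders into a region where a trajectory touches
#' zero.
#'
#' @param model An `ssystem_model`.
#' @param state Numeric vector of length `n_dependent`, current concentrations.
#' @param inputs Numeric vector of length `n_independent` of constant input
#'   concentrations (omit when the model has none).
#' @return Numeric derivative vector of length `n_dependent`.
#' @export
ss_rates <- function(model, state, inputs = numeric(model$n_independent)) {
  stopifnot(inherits(model, "ssystem_model"))
  if (length(state) != model$n_dependent)
    stop("'state' must have length ", model$n_dependent)
  if (length(inputs) != model$n_independent)
    stop("'inputs' must have length ", model$n_independent)
  out <- .cpp_ss_rates(model$alpha, model$beta, model$G, model$H,
                       as.numeric(state), as.numeric(inputs))
  if (!all(is.finite(out)))
    stop("rate evaluation overflowed (non-finite derivative); ",
         "check kinetic orders", call. = FALSE)
  out
}

#' Construct a trajectory object
#'
#' A trajectory holds a sampled multivariate time course: a strictly
#' increasing time vector and one concentration column per dependent state,
#' plus the constant independent-input values the course was generated under.
#'
#' @param times Strictly increasing numeric vector of sample times.
#' @param states Numeric matrix, one row per time, one column per state.
#' @param inputs Optional numeric vector of independent-input values.
#' @return An object of class `ss_trajectory`.
#' @export
ss_trajectory <- function(times, states, inputs = numeric(0)) {
  times <- as.numeric(times)
  states <- as.matrix(states)
  if (nrow(states) != length(times))
    stop("'states' must have one row per entry of 'times'")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  if (!all(is.finite(states))) stop("trajectory states must be finite")
  if (is.null(colnames(states)))
    colnames(states) <- paste0("x", seq_len(ncol(states)))
  structure(list(times = times, states = states, inputs = as.numeric(inputs)),
            class = "ss_trajectory")
}

#' @export
print.ss_trajectory <- function(x, ...) {
  cat(sprintf("S-system trajectory: %d samples x %d states, t in [%g, %g]\n",
              length(x$times), ncol(x$states), min(x$times), max(x$times)))
  invisible(x)
}

#' Simulate an S-system model
#'
#' Integrates the model ODEs with an adaptive embedded Runge-Kutta 4(5)
#' (Cash-Karp) scheme and returns the solution sampled at `times`. The first
#' row of the result equals `x0` exactly.
#'
#' If the integration fails before the final sample (step-size collapse or a
#' non-finite state, which happens routinely for candidate parameters during
#' optimization), the returned trajectory is truncated at the last completed
#' sample and carries `attr(, "failed") = TRUE` together with
#' `attr(, "last_time")`; no error is thrown so the fitness layer can
#' penalize instead of crash.
#'
#' @param model An `ssystem_model`.
#' @param x0 Strictly positive initial state, length `n_dependent`.
#' @param times Strictly increasing sample times; by convention starting at 0.
#' @param inputs Constant independent-input vector.
#' @param rtol,atol Relative/absolute integration tolerances.
#' @param max_steps Cap on internal steps per output interval.
#' @return An [ss_trajectory()]; see Details for the failure contract.
#' @examples
#' m <- benchmark_model()
#' tr <- ss_simulate(m, x0 = rep(0.5, 4), times = seq(0, 5, length.out = 50))
#' @export
ss_simulate <- function(model, x0, times, inputs = numeric(model$n_independent),
                        rtol = 1e-6, atol = 1e-8, max_steps = 100000L) {
  stopifnot(inherits(model, "ssystem_model"))
  times <- as.numeric(times)
  if (length(times) < 1L || (length(times) > 1L && any(diff(times) <= 0)))
    stop("'times' must be non-empty and strictly increasing")
  if (length(x0) != model$n_dependent)
    stop("'x0' must have length ", model$n_dependent)
  if (any(x0 <= 0)) stop("'x0' must be strictly positive")
  if (length(inputs) != model$n_independent)
    stop("'inputs' must have length ", model$n_independent)
  res <- .cpp_ss_simulate(model$alpha, model$beta, model$G, model$H,
                          as.numeric(x0), as.numeric(inputs), times,
                          rtol, atol, as.integer(max_steps))
  if (isTRUE(res$success)) {
    st <- res$states
    colnames(st) <- paste0("x", seq_len(ncol(st)))
    return(ss_trajectory(times, st, inputs))
  }
  keep <- seq_len(res$last_row)
  st <- res$states[keep, , drop = FALSE]
  colnames(st) <- paste0("x", seq_len(ncol(st)))
  out <- ss_trajectory(times[keep], st, inputs)
  attr(out, "failed") <- TRUE
  attr(out, "last_time") <- times[res$last_row]
  out
}

#' Write / read a trajectory as delimited text
#'
#' The on-disk format is a plain CSV with header `time,x1,...,xN`; values are
#' printed with 12 significant digits so a write/read round trip is exact at
#' that precision.
#'
#' @param traj An [ss_trajectory()].
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns an `ss_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "ss_trajectory"))
  tab <- cbind(time = traj$times, traj$states)
  lines <- c(paste(colnames(tab), collapse = ","),
             apply(tab, 1L, function(r) paste(sprintf("%.12g", r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 2L || names(tab)[1L] != "time")
    stop("malformed trajectory file: expected header 'time,x1,...', got '",
         paste(names(tab), collapse = ","), "'")
  bad <- names(tab)[-1L][!grepl("^x[0-9]+$", names(tab)[-1L])]
  if (length(bad))
    stop("malformed trajectory file: unexpected state column(s) '",
         paste(bad, collapse = "', '"), "'")
  ss_trajectory(tab$time, as.matrix(tab[-1L]))
}
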
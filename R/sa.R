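#' Simulated annealing configuration
#'
#' Single-solution annealer with geometric cooling. The outer loop lowers
#' the temperature `T <- cooling_factor * T` from `t_initial` down to
#' `t_final`; the inner loop makes `inner_moves` Gaussian proposals per
#' temperature, clamped to the search box, accepting improvements always and
#' deteriorations `delta > 0` with the Metropolis probability
#' `exp(-delta / T)`. High early temperatures keep the walk from freezing
#' into a local minimum; late low temperatures turn it into a local refiner.
#'
#' @param bounds Numeric `q x 2` search box.
#' @param t_initial Starting temperature, or `NULL` to calibrate it at run
#'   time as the standard deviation of 50 uniform random fitness draws.
#' @param t_final Stopping temperature, or `NULL` for `1e-3 * t_initial`.
#' @param cooling_factor Geometric cooling ratio in (0, 1), default 0.95.
#' @param inner_moves Proposals per temperature level.
#' @param step_frac Proposal standard deviation as a fraction of each
#'   dimension's box width (default 0.1); or supply `step_scale` directly.
#' @param step_scale Optional per-dimension proposal SD vector.
#' @param max_evaluations Optional cap on total fitness evaluations
#'   (including the calibration probe); the run stops exactly there. Used by
#'   the comparison harness to equalize budgets across algorithms.
#' @param adaptive_step Scale the proposal SD with the annealing progress
#'   (`sqrt(T / t_initial)`, floored at 5% of the base scale): wide moves
#'   while hot, fine refinement when cold. Default `FALSE` (fixed scale).
#' @param seed Integer seed, or `NULL` for the ambient stream.
#' @return An object of class `ss_sa_config`.
#' @export
sa_config <- function(bounds, t_initial = NULL, t_final = NULL,
                      cooling_factor = 0.95, inner_moves = 50L,
                      step_frac = 0.1, step_scale = NULL,
                      max_evaluations = Inf, adaptive_step = FALSE,
                      seed = NULL) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || any(bounds[, 1L] >= bounds[, 2L]))
    stop("'bounds' must be a q x 2 matrix with low < high per dimension")
  if (!(cooling_factor > 0 && cooling_factor < 1))
    stop("'cooling_factor' must be in (0, 1)")
  if (!is.null(t_initial) && !is.null(t_final) &&
      !(t_initial > t_final && t_final > 0))
    stop("need t_initial > t_final > 0")
  if (inner_moves < 1L) stop("'inner_moves' must be >= 1")
  width <- bounds[, 2L] - bounds[, 1L]
  if (is.null(step_scale)) step_scale <- step_frac * width
  structure(list(bounds = unname(bounds), t_initial = t_initial,
                 t_final = t_final, cooling_factor = cooling_factor,
                 inner_moves = as.integer(inner_moves),
                 step_scale = rep_len(step_scale, nrow(bounds)),
                 max_evaluations = max_evaluations,
                 adaptive_step = isTRUE(adaptive_step), seed = seed),
            class = "ss_sa_config")
}

#' Metropolis acceptance probability
#'
#' Probability of accepting a move with fitness change `delta` at
#' temperature `temp`: 1 for improvements, `exp(-delta/temp)` otherwise.
#'
#' @param delta Fitness change (positive = worse).
#' @param temp Current temperature (> 0).
#' @return Acceptance probability in \[0, 1\].
#' @export
sa_accept_prob <- function(delta, temp) {
  ifelse(delta <= 0, 1, exp(-delta / temp))
}

#' Run simulated annealing
#'
#' Minimizes `fitness` over `cfg$bounds`; see [sa_config()] for the
#' schedule. Tracks the best-ever solution, so the reported trace is
#' non-increasing even though the walk itself may move uphill.
#'
#' @param cfg An [sa_config()].
#' @param fitness Scalar objective.
#' @return An `ss_opt_result`; `fitness_trace` holds the best-so-far value
#'   after each temperature level (preceded by the initial value).
#' @export
run_sa <- function(cfg, fitness) {
  stopifnot(inherits(cfg, "ss_sa_config"))
  with_seed(cfg$seed, {
    q <- nrow(cfg$bounds)
    lo <- cfg$bounds[, 1L]; hi <- cfg$bounds[, 2L]
    evals <- 0L
    t0 <- cfg$t_initial
    if (is.null(t0)) {
      probe <- matrix(stats::runif(50L * q, rep(lo, each = 50L),
                                   rep(hi, each = 50L)), 50L, q)
      pf <- eval_batch(fitness, probe)
      evals <- evals + 50L
      # calibrate on the informative probes: penalty values would inflate
      # the scale by orders of magnitude and turn the whole schedule into
      # an undirected random walk
      ok <- is.finite(pf) & pf < 1e6
      t0 <- if (sum(ok) >= 2L) stats::sd(pf[ok]) else stats::sd(pf)
      if (!is.finite(t0) || t0 <= 0) t0 <- 1
    }
    t_final <- cfg$t_final %||% (1e-3 * t0)
    x <- stats::runif(q, lo, hi)
    fx <- fitness(x)
    evals <- evals + 1L
    best <- x
    best_f <- fx
    trace <- best_f
    temp <- t0
    while (temp > t_final && evals < cfg$max_evaluations) {
      scale_t <- if (cfg$adaptive_step) {
        cfg$step_scale * max(sqrt(temp / t0), 0.05)
      } else {
        cfg$step_scale
      }
      for (k in seq_len(cfg$inner_moves)) {
        if (evals >= cfg$max_evaluations) break
        prop <- clamp(x + stats::rnorm(q, 0, scale_t), lo, hi)
        fp <- fitness(prop)
        evals <- evals + 1L
        delta <- fp - fx
        if (delta <= 0 || stats::runif(1) < exp(-delta / temp)) {
          x <- prop
          fx <- fp
          if (fx < best_f) {
            best_f <- fx
            best <- x
          }
        }
      }
      trace <- c(trace, best_f)
      temp <- temp * cfg$cooling_factor
    }
    new_opt_result(best, best_f, trace, evals, cfg$seed)
  })
}

# Number of temperature levels the schedule will visit; used by the harness
# to equalize evaluation budgets across algorithms.
sa_n_temps <- function(t_initial, t_final, cooling_factor) {
  as.integer(ceiling(log(t_final / t_initial) / log(cooling_factor)))
}
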
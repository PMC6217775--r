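#' Particle swarm configuration
#'
#' Canonical PSO with inertia-weighted velocity updates: each particle `i`
#' moves in dimension `j` according to
#' \deqn{V_{ij}(t) = W V_{ij}(t-1) + c_1 r_1 (P^*_{ij} - P_{ij})
#'       + c_2 r_2 (P^*_{gj} - P_{ij}),}
#' with fresh `r1, r2 ~ U[0,1]` per component, followed by
#' `P_ij(t) = P_ij(t-1) + V_ij(t)` with a clamp to the search box. The
#' inertia weight decays linearly from `inertia_start` (exploration) to
#' `inertia_end` (exploitation) over the run; the acceleration constants
#' default to the standard `c1 = c2 = 2`.
#'
#' @param n_particles,n_iterations Swarm size and iteration count.
#' @param bounds Numeric `q x 2` matrix, one `(low, high)` row per dimension.
#' @param inertia_start,inertia_end Linear inertia schedule endpoints
#'   (defaults 0.9 and 0.1).
#' @param c1,c2 Cognitive/social acceleration constants (default 2).
#' @param vmax_frac Velocity clamp as a fraction of each dimension's box
#'   width (default 0.2); prevents velocity explosion.
#' @param feasible_init Initialize the swarm by rejection sampling on
#'   finite fitness (candidates whose simulation fails are redrawn, up to 25
#'   rounds). On objectives with large undefined regions this stops the
#'   initial swarm from being dominated by penalty-valued particles; the
#'   rejected evaluations count toward the run's evaluation total.
#' @param seed Integer seed, or `NULL` for the ambient RNG stream.
#' @return An object of class `ss_pso_config`.
#' @export
pso_config <- function(n_particles, n_iterations, bounds,
                       inertia_start = 0.9, inertia_end = 0.1,
                       c1 = 2, c2 = 2, vmax_frac = 0.2,
                       feasible_init = FALSE, seed = NULL) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || any(bounds[, 1L] >= bounds[, 2L]))
    stop("'bounds' must be a q x 2 matrix with low < high per dimension")
  if (!(inertia_start >= inertia_end && inertia_end > 0))
    stop("need inertia_start >= inertia_end > 0")
  if (c1 <= 0 || c2 <= 0) stop("'c1' and 'c2' must be positive")
  if (n_particles < 1L || n_iterations < 0L)
    stop("need n_particles >= 1 and n_iterations >= 0")
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 bounds = unname(bounds),
                 inertia_start = inertia_start, inertia_end = inertia_end,
                 c1 = c1, c2 = c2, vmax_frac = vmax_frac,
                 feasible_init = isTRUE(feasible_init), seed = seed),
            class = "ss_pso_config")
}

#' Swarm state container
#'
#' Positions, velocities and the personal/global bests of a swarm; mainly of
#' interest for inspecting or unit-testing the update rules.
#'
#' @param positions,velocities Numeric `particles x q` matrices.
#' @param pbest_pos,pbest_fit Personal best positions/fitnesses.
#' @param gbest_pos,gbest_fit Global best position/fitness.
#' @param iteration Iteration counter.
#' @return An object of class `ss_swarm_state`.
#' @export
swarm_state <- function(positions, velocities, pbest_pos, pbest_fit,
                        gbest_pos, gbest_fit, iteration = 0L) {
  structure(list(positions = positions, velocities = velocities,
                 pbest_pos = pbest_pos, pbest_fit = pbest_fit,
                 gbest_pos = gbest_pos, gbest_fit = gbest_fit,
                 iteration = iteration),
            class = "ss_swarm_state")
}

#' PSO velocity update rule
#'
#' Applies the inertia-weighted velocity recursion componentwise, then clamps
#' each velocity to `vmax_frac` of its dimension's box width. The uniform
#' draws can be supplied explicitly (for testing); by default fresh
#' `U[0,1]` matrices are drawn.
#'
#' @param state An [swarm_state()].
#' @param cfg An [pso_config()].
#' @param inertia Current inertia weight `W`.
#' @param r1,r2 Optional `particles x q` matrices of uniform draws.
#' @return The state with updated `velocities`.
#' @export
pso_velocity_update <- function(state, cfg, inertia,
                                r1 = NULL, r2 = NULL) {
  P <- state$positions
  if (is.null(r1)) r1 <- matrix(stats::runif(length(P)), nrow(P), ncol(P))
  if (is.null(r2)) r2 <- matrix(stats::runif(length(P)), nrow(P), ncol(P))
  V <- inertia * state$velocities +
    cfg$c1 * r1 * (state$pbest_pos - P) +
    cfg$c2 * r2 * (sweep(-P, 2L, state$gbest_pos, "+"))
  vmax <- cfg$vmax_frac * (cfg$bounds[, 2L] - cfg$bounds[, 1L])
  state$velocities <- clamp(V, rep(-vmax, each = nrow(V)),
                            rep(vmax, each = nrow(V)))
  state
}

#' PSO position update rule
#'
#' Adds the (already updated) velocities to the positions and clamps the
#' result to the search box.
#'
#' @inheritParams pso_velocity_update
#' @return The state with updated `positions`.
#' @export
pso_position_update <- function(state, cfg) {
  P <- state$positions + state$velocities
  state$positions <- clamp(P, rep(cfg$bounds[, 1L], each = nrow(P)),
                           rep(cfg$bounds[, 2L], each = nrow(P)))
  state
}

eval_batch <- function(fitness, P) {
  b <- attr(fitness, "batch")
  if (!is.null(b)) as.numeric(b(P)) else apply(P, 1L, fitness)
}

new_opt_result <- function(best_vector, best_fitness, fitness_trace,
                           evaluations, seed) {
  structure(list(best_vector = as.numeric(best_vector),
                 best_fitness = best_fitness,
                 fitness_trace = fitness_trace,
                 evaluations = evaluations, seed = seed),
            class = "ss_opt_result")
}

#' @export
print.ss_opt_result <- function(x, ...) {
  cat(sprintf("optimizer result: best fitness %.6g after %d evaluations\n",
              x$best_fitness, x$evaluations))
  invisible(x)
}

# Core loop shared by run_pso and the DPSO inner searches. `active_dims`
# restricts updates to a subset of coordinates (all others stay frozen at
# their initial values); `init_positions` overrides the uniform random
# initialization.
pso_loop <- function(cfg, fitness, init_positions = NULL, active_dims = NULL) {
  q <- nrow(cfg$bounds)
  np <- cfg$n_particles
  lo <- cfg$bounds[, 1L]; hi <- cfg$bounds[, 2L]
  if (is.null(active_dims)) active_dims <- seq_len(q)
  evals <- 0L
  if (is.null(init_positions)) {
    P <- matrix(stats::runif(np * q, rep(lo, each = np), rep(hi, each = np)),
                np, q)
    fit <- eval_batch(fitness, P)
    evals <- evals + np
    if (cfg$feasible_init) {
      feasible <- is.finite(fit) & fit < 1e6
      rounds <- 0L
      while (any(!feasible) && rounds < 25L) {
        k <- sum(!feasible)
        C <- matrix(stats::runif(k * q, rep(lo, each = k), rep(hi, each = k)),
                    k, q)
        fc <- eval_batch(fitness, C)
        evals <- evals + k
        P[!feasible, ] <- C
        fit[!feasible] <- fc
        feasible <- is.finite(fit) & fit < 1e6
        rounds <- rounds + 1L
      }
    }
  } else {
    P <- init_positions
    fit <- eval_batch(fitness, P)
    evals <- evals + np
  }
  V <- matrix(0, np, q)
  pbest_pos <- P
  pbest_fit <- fit
  g <- which.min(pbest_fit)
  gbest_pos <- P[g, ]
  gbest_fit <- pbest_fit[g]
  trace <- numeric(cfg$n_iterations)
  st <- swarm_state(P, V, pbest_pos, pbest_fit, gbest_pos, gbest_fit)
  frozen <- setdiff(seq_len(q), active_dims)
  if (cfg$n_iterations > 0) {
    for (t in seq_len(cfg$n_iterations)) {
      W <- if (cfg$n_iterations == 1L) cfg$inertia_start else
        cfg$inertia_start + (cfg$inertia_end - cfg$inertia_start) *
          (t - 1) / (cfg$n_iterations - 1)
      st <- pso_velocity_update(st, cfg, W)
      if (length(frozen)) st$velocities[, frozen] <- 0
      st <- pso_position_update(st, cfg)
      fit <- eval_batch(fitness, st$positions)
      evals <- evals + np
      imp <- fit < st$pbest_fit  # strict: ties keep the incumbent
      st$pbest_fit[imp] <- fit[imp]
      st$pbest_pos[imp, ] <- st$positions[imp, , drop = FALSE]
      g <- which.min(st$pbest_fit)
      if (st$pbest_fit[g] < st$gbest_fit) {
        st$gbest_fit <- st$pbest_fit[g]
        st$gbest_pos <- st$pbest_pos[g, ]
      }
      st$iteration <- t
      trace[t] <- st$gbest_fit
    }
  }
  list(state = st, trace = trace, evaluations = evals)
}

#' Run canonical particle swarm optimization
#'
#' Minimizes `fitness` over the box `cfg$bounds`: uniform random
#' initialization, zero initial velocities, inertia decaying linearly from
#' `inertia_start` to `inertia_end`, velocity and position clamping. With
#' `n_iterations = 0` the result is the best member of the random initial
#' swarm. The best-so-far trace is non-increasing and the whole run is
#' reproducible under a fixed `cfg$seed`.
#'
#' @param cfg An [pso_config()].
#' @param fitness Scalar objective; if it carries a `"batch"` attribute
#'   (see [ss_fitness()]) populations are scored in one call.
#' @return An `ss_opt_result`: `best_vector`, `best_fitness`,
#'   `fitness_trace`, `evaluations`, `seed`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' cfg <- pso_config(20, 50, bounds = cbind(rep(-5, 3), rep(5, 3)), seed = 1)
#' run_pso(cfg, sphere)$best_fitness
#' @export
run_pso <- function(cfg, fitness) {
  stopifnot(inherits(cfg, "ss_pso_config"))
  with_seed(cfg$seed, {
    res <- pso_loop(cfg, fitness)
    trace <- if (cfg$n_iterations > 0) res$trace else res$state$gbest_fit
    new_opt_result(res$state$gbest_pos, res$state$gbest_fit, trace,
                   res$evaluations, cfg$seed)
  })
}

#' Decomposition PSO configuration
#'
#' @param phase1 An [pso_config()] for the global first phase.
#' @param outer_iterations Number of phase-2 sweeps over all dimensions.
#' @param inner An [pso_config()] template for each single-dimension search
#'   (its `bounds` are taken from `phase1`).
#' @param scatter_frac Re-scattering neighborhood half-width as a fraction
#'   of each dimension's box width (default 0.05); alternatively supply
#'   `scatter_radius` explicitly.
#' @param scatter_radius Optional per-dimension half-width vector overriding
#'   `scatter_frac`.
#' @return An object of class `ss_dpso_config`.
#' @export
dpso_config <- function(phase1, outer_iterations = 5L,
                        inner = pso_config(15L, 40L, phase1$bounds,
                                           seed = NULL),
                        scatter_frac = 0.05, scatter_radius = NULL) {
  stopifnot(inherits(phase1, "ss_pso_config"), inherits(inner, "ss_pso_config"))
  if (outer_iterations < 1L) stop("'outer_iterations' must be >= 1")
  width <- phase1$bounds[, 2L] - phase1$bounds[, 1L]
  if (is.null(scatter_radius)) scatter_radius <- scatter_frac * width
  if (any(scatter_radius < 0)) stop("'scatter_radius' must be non-negative")
  structure(list(phase1 = phase1, outer_iterations = as.integer(outer_iterations),
                 inner = inner, scatter_radius = rep_len(scatter_radius,
                                                         nrow(phase1$bounds)),
                 seed = phase1$seed),
            class = "ss_dpso_config")
}

#' Run the two-phase decomposition PSO
#'
#' Phase 1 is a canonical PSO over the full box. Phase 2 repeatedly sweeps
#' the dimensions: for each coordinate `j`, every particle is relocated to
#' the incumbent global best, scattered only in dimension `j` within
#' `scatter_radius[j]` of it (velocities reset to zero), and a PSO restricted
#' to that single coordinate is run; the global best is replaced only on
#' strict improvement. The sweep converts the swarm's multi-dimensional
#' exploration into one-dimensional exploitation near the solution at hand,
#' and the outer loop repeats the sweep to escape coordinate-wise traps.
#'
#' @param cfg An [dpso_config()].
#' @param fitness Scalar objective (see [run_pso()]).
#' @return An `ss_opt_result`; `fitness_trace` holds the phase-1 trace
#'   followed by the global-best fitness after each single-dimension search.
#' @export
run_dpso <- function(cfg, fitness) {
  stopifnot(inherits(cfg, "ss_dpso_config"))
  with_seed(cfg$seed, {
    p1 <- pso_loop(cfg$phase1, fitness)
    gbest <- p1$state$gbest_pos
    gfit <- p1$state$gbest_fit
    evals <- p1$evaluations
    trace <- if (cfg$phase1$n_iterations > 0) p1$trace else gfit
    q <- nrow(cfg$phase1$bounds)
    inner <- cfg$inner
    np <- inner$n_particles
    lo <- cfg$phase1$bounds[, 1L]; hi <- cfg$phase1$bounds[, 2L]
    for (outer in seq_len(cfg$outer_iterations)) {
      for (j in seq_len(q)) {
        P0 <- matrix(gbest, np, q, byrow = TRUE)
        P0[, j] <- clamp(gbest[j] + stats::runif(np, -cfg$scatter_radius[j],
                                                 cfg$scatter_radius[j]),
                         lo[j], hi[j])
        res <- pso_loop(inner, fitness, init_positions = P0, active_dims = j)
        evals <- evals + res$evaluations
        if (res$state$gbest_fit < gfit) {
          gfit <- res$state$gbest_fit
          gbest <- res$state$gbest_pos
        }
        trace <- c(trace, gfit)
      }
    }
    new_opt_result(gbest, gfit, trace, evals, cfg$seed)
  })
}
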
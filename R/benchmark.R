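#' The four-state cascade benchmark model
#'
#' Returns the synthetic benchmark S-system: a four-metabolite cascade with
#' one constant independent input, in which x1 production is inhibited by x3
#' (kinetic order -0.8), x2 and x4 are produced from x1, x3 is produced from
#' x2, and each state degrades as a power of itself (x3 degradation also
#' depends on x4). Rate coefficients are alpha = (20, 8, 3, 2) and
#' beta = (10, 3, 3, 6); the nonzero kinetic orders are
#' g13 = -0.8, g21 = 0.5, g32 = 0.75, g41 = 0.5 and
#' h11 = 0.5, h22 = 0.75, h33 = 0.5, h34 = 0.2, h44 = 0.8.
#'
#' The independent input x5 is held at 1 and its kinetic order on x1 is fixed
#' to 0, leaving the 17 free parameters of [benchmark_mask()] to estimate.
#' The function is pure: repeated calls return identical models.
#'
#' @return An [ss_model()] with `n_dependent = 4`, `n_independent = 1`.
#' @examples
#' ss_rates(benchmark_model(), state = rep(1, 4), inputs = 1)  # alpha - beta
#' @export
benchmark_model <- function() {
  G <- matrix(0, 4, 5)
  H <- matrix(0, 4, 5)
  G[1, 3] <- -0.8
  G[2, 1] <- 0.5
  G[3, 2] <- 0.75
  G[4, 1] <- 0.5
  H[1, 1] <- 0.5
  H[2, 2] <- 0.75
  H[3, 3] <- 0.5
  H[3, 4] <- 0.2
  H[4, 4] <- 0.8
  ss_model(alpha = c(20, 8, 3, 2), beta = c(10, 3, 3, 6),
           G = G, H = H, n_independent = 1L)
}

#' Free-parameter mask of the benchmark
#'
#' All eight rate coefficients plus the nine nonzero kinetic orders of
#' [benchmark_model()] are estimated (17 parameters); structural zeros and
#' the independent-input order are fixed.
#'
#' @return A [param_mask()] with 17 free entries.
#' @export
benchmark_mask <- function() {
  mod <- benchmark_model()
  param_mask(free_alpha = rep(TRUE, 4), free_beta = rep(TRUE, 4),
             free_G = mod$G != 0, free_H = mod$H != 0)
}

#' Uniform sampler for random initial states
#'
#' Each benchmark replicate starts the cascade from an i.i.d. uniform random
#' initial concentration vector; this constructor fixes the support and the
#' seed so replicates are reproducible.
#'
#' @param low,high Positive bounds of the uniform support
#'   (default `[0.1, 1]`).
#' @param seed Integer RNG seed, or `NULL` to use the ambient RNG stream.
#' @param n Number of states drawn per call (4 for the benchmark).
#' @return An object of class `ss_state_sampler`.
#' @export
initial_state_sampler <- function(low = 0.1, high = 1.0, seed = NULL, n = 4L) {
  if (!(is.numeric(low) && is.numeric(high) && low > 0 && high > low))
    stop("need 0 < low < high")
  structure(list(low = low, high = high, seed = seed, n = as.integer(n)),
            class = "ss_state_sampler")
}

#' @rdname initial_state_sampler
#' @param sampler An `ss_state_sampler`.
#' @export
sample_initial_state <- function(sampler) {
  stopifnot(inherits(sampler, "ss_state_sampler"))
  with_seed(sampler$seed, stats::runif(sampler$n, sampler$low, sampler$high))
}

#' Add white Gaussian noise at a target SNR
#'
#' Corrupts every state column with zero-mean Gaussian noise whose variance
#' is the column's mean signal power divided by `10^(snr_db/10)` (decibel
#' signal-to-noise convention). With `per_state = FALSE` a single noise
#' variance derived from the pooled signal power of all columns is used.
#' `snr_db = Inf` returns the trajectory unchanged.
#'
#' @param traj An [ss_trajectory()].
#' @param snr_db Signal-to-noise ratio in dB; must be finite and positive,
#'   or `Inf` for no noise.
#' @param seed Integer seed, or `NULL` for the ambient RNG stream.
#' @param per_state Enforce the SNR per state column (default) or globally.
#' @return A noisy `ss_trajectory` with identical times and inputs.
#' @export
add_noise <- function(traj, snr_db, seed = NULL, per_state = TRUE) {
  stopifnot(inherits(traj, "ss_trajectory"))
  if (!(is.numeric(snr_db) && length(snr_db) == 1L && snr_db > 0))
    stop("'snr_db' must be a positive scalar (Inf for noise-free)")
  if (is.infinite(snr_db)) return(traj)
  Y <- traj$states
  pow <- colMeans(Y^2)
  if (per_state) {
    if (any(pow == 0))
      stop("all-zero state column: noise scale undefined at finite SNR")
    sd_col <- sqrt(pow / 10^(snr_db / 10))
  } else {
    if (mean(pow) == 0)
      stop("all-zero signal: noise scale undefined at finite SNR")
    sd_col <- rep(sqrt(mean(pow) / 10^(snr_db / 10)), ncol(Y))
  }
  noise <- with_seed(seed, {
    matrix(stats::rnorm(length(Y)), nrow(Y), ncol(Y)) %*% diag(sd_col, ncol(Y))
  })
  ss_trajectory(traj$times, Y + noise, traj$inputs)
}

#' Acid-stress (Cad) module model structure
#'
#' Builds the S-system for the E. coli Cad acid-stress response over the
#' dependent states CadA, CadBA, cadaverine (Cadav) and lysine (Lys) with the
#' extracellular proton concentration H+ as constant independent input. The
#' term structure is fixed: CadA turns over via CadBA-driven production and
#' self-degradation; CadBA production depends on Lys and H+; cadaverine has
#' no degradation term (`beta[3] = 0`) and lysine no production term
#' (`alpha[4] = 0`), both being pure accumulation/consumption.
#'
#' The numeric parameter values are not built in; the caller supplies them.
#'
#' @param alpha,beta Length-4 rate coefficients; `alpha[4]` and `beta[3]`
#'   must be 0 (structurally absent terms).
#' @param orders Named numeric vector of kinetic orders; allowed names are
#'   `g12, g24, g25, h11, h22, g31, g33, g34, h41, h43, h44` (missing names
#'   default to 0). Any other name is rejected.
#' @return A list with elements `model` (the [ss_model()]) and `mask`
#'   (a [param_mask()] marking the structurally present entries free,
#'   with `beta[3]` and `alpha[4]` excluded).
#' @export
cad_model <- function(alpha, beta, orders = c(g12 = 0, g24 = 0, g25 = 0,
                                              h11 = 0, h22 = 0, g31 = 0,
                                              g33 = 0, g34 = 0, h41 = 0,
                                              h43 = 0, h44 = 0)) {
  if (length(alpha) != 4L || length(beta) != 4L)
    stop("'alpha' and 'beta' must have length 4")
  if (alpha[4] != 0)
    stop("lysine has no production term: 'alpha[4]' must be 0")
  if (beta[3] != 0)
    stop("cadaverine has no degradation term: 'beta[3]' must be 0")
  slots <- list(g12 = c("G", 1, 2), g24 = c("G", 2, 4), g25 = c("G", 2, 5),
                g31 = c("G", 3, 1), g33 = c("G", 3, 3), g34 = c("G", 3, 4),
                h11 = c("H", 1, 1), h22 = c("H", 2, 2), h41 = c("H", 4, 1),
                h43 = c("H", 4, 3), h44 = c("H", 4, 4))
  bad <- setdiff(names(orders), names(slots))
  if (length(bad))
    stop("kinetic order(s) outside the Cad term structure: ",
         paste(bad, collapse = ", "))
  G <- matrix(0, 4, 5)
  H <- matrix(0, 4, 5)
  fG <- matrix(FALSE, 4, 5)
  fH <- matrix(FALSE, 4, 5)
  for (nm in names(slots)) {
    s <- slots[[nm]]
    i <- as.integer(s[2]); j <- as.integer(s[3])
    if (s[1] == "G") {
      G[i, j] <- if (nm %in% names(orders)) orders[[nm]] else 0
      fG[i, j] <- TRUE
    } else {
      H[i, j] <- if (nm %in% names(orders)) orders[[nm]] else 0
      fH[i, j] <- TRUE
    }
  }
  model <- ss_model(alpha = alpha, beta = beta, G = G, H = H,
                    n_independent = 1L)
  mask <- param_mask(free_alpha = c(TRUE, TRUE, TRUE, FALSE),
                     free_beta = c(TRUE, TRUE, FALSE, TRUE),
                     free_G = fG, free_H = fH)
  list(model = model, mask = mask)
}

#' Write / read a model specification file
#'
#' Serializes a model plus its free-parameter mask (and optional input
#' values) to YAML or JSON, keyed `alpha`, `beta`, `G`, `H`, `mask`,
#' `inputs`. The format is chosen from the file extension
#' (`.yml`/`.yaml` vs `.json`).
#'
#' @param model An [ss_model()].
#' @param mask A [param_mask()] for `model`.
#' @param path Output file path.
#' @param inputs Optional independent-input values to record.
#' @return `write_model_spec` returns `path` invisibly; `read_model_spec`
#'   returns a list with `model`, `mask`, `inputs`.
#' @export
write_model_spec <- function(model, mask, path,
                             inputs = numeric(model$n_independent)) {
  stopifnot(inherits(model, "ssystem_model"), inherits(mask, "ss_param_mask"))
  obj <- list(
    n_dependent = model$n_dependent, n_independent = model$n_independent,
    alpha = model$alpha, beta = model$beta,
    G = apply(model$G, 1L, identity, simplify = FALSE),
    H = apply(model$H, 1L, identity, simplify = FALSE),
    mask = list(free_alpha = mask$free_alpha, free_beta = mask$free_beta,
                free_G = apply(mask$free_G, 1L, identity, simplify = FALSE),
                free_H = apply(mask$free_H, 1L, identity, simplify = FALSE)),
    inputs = as.numeric(inputs))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  }
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  need <- c("alpha", "beta", "G", "H", "mask")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("model spec is missing key(s): ", paste(miss, collapse = ", "))
  as_mat <- function(rows) {
    if (is.matrix(rows)) {
      matrix(as.numeric(rows), nrow(rows))
    } else {
      do.call(rbind, lapply(rows, as.numeric))
    }
  }
  model <- ss_model(alpha = as.numeric(obj$alpha), beta = as.numeric(obj$beta),
                    G = as_mat(obj$G), H = as_mat(obj$H))
  mask <- param_mask(free_alpha = as.logical(obj$mask$free_alpha),
                     free_beta = as.logical(obj$mask$free_beta),
                     free_G = as_mat(obj$mask$free_G) != 0,
                     free_H = as_mat(obj$mask$free_H) != 0)
  list(model = model, mask = mask,
       inputs = as.numeric(obj$inputs %||% numeric(model$n_independent)))
}
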
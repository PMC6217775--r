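`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# stream; seed = NULL uses (and advances) the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
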
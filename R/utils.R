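# Internal helpers shared across the package.

# Run `expr` under a fixed RNG seed, restoring the caller's random state
# afterwards so library code never perturbs a user's session RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Squared Euclidean distances between rows of x: n x n matrix, zero diagonal.
squared_distances <- function(x) {
  x <- as.matrix(x)
  ss <- rowSums(x^2)
  d2 <- outer(ss, ss, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

stop_ribotype <- function(...) stop(..., call. = FALSE)
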
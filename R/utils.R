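# Internal numerical helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded operations do not perturb the caller's
#' random stream.
#' @keywords internal
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## numerically stable softmax over a vector
stableSoftmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

## softmax within groups: x numeric length N, g integer group ids 1..B
groupedSoftmax <- function(x, g, nGroups) {
  gmax <- as.vector(tapply(x, g, max))
  e <- exp(x - gmax[g])
  s <- as.vector(rowsum(e, g, reorder = TRUE))
  as.vector(e / s[g])
}

sigmoid <- function(x) 1 / (1 + exp(-x))

reluGrad <- function(z) (z > 0) * 1

## clamp probabilities away from {0,1} before taking logs
clampProb <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

isBinaryVector <- function(y) {
  is.numeric(y) && length(y) >= 1L && all(is.finite(y)) && all(y %in% c(0, 1))
}

## derive a child seed (kept below 2^31) from a base seed and stream indices
deriveSeed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed)
  for (i in idx) s <- (s * 69069 + as.double(i) * 104729 + 7919) %% 2147483647
  as.integer(s)
}
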
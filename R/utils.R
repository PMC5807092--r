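#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## All generators draw their randomness from one master seed; component
## streams are derived by fixed offsets so stages can be re-run in isolation.
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.numeric(seed) + 104729 * offset) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## population-convention z-score (divide by sqrt(mean((x-mean)^2)))
zscore_pop <- function(x) {
  if (length(x) < 2L) stop("z-normalization needs at least 2 values")
  s <- sqrt(mean((x - mean(x))^2))
  if (s < .Machine$double.eps^0.5) stop("z-normalization with zero variance")
  (x - mean(x)) / s
}

minmax_norm <- function(x) {
  r <- range(x)
  if (diff(r) < .Machine$double.eps^0.5) return(rep(0.5, length(x)))
  (x - r[1]) / diff(r)
}
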
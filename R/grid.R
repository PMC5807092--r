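#' Logarithmically spaced viscosity grid
#'
#' Physical viscosities used throughout the stimulus designs are drawn from a
#' geometric progression spanning water (about 0.001 Pa s) to molten glass
#' (about 100 Pa s). The full stimulus scale has 64 steps; study designs use
#' subsets of it, selected by index.
#'
#' @param n_steps number of grid points (>= 2).
#' @param lo,hi positive endpoints in Pa s, `lo < hi`.
#' @return numeric vector of length `n_steps`, geometric from `lo` to `hi`
#'   inclusive.
#' @examples
#' viscosity_grid(3, 0.001, 100)  # middle value 10^-1.5
#' @export
viscosity_grid <- function(n_steps = 64L, lo = 0.001, hi = 100) {
  if (!(length(n_steps) == 1L && n_steps >= 2))
    stop("n_steps must be >= 2")
  if (!(lo > 0 && hi > 0)) stop("viscosity bounds must be positive")
  if (!(lo < hi)) stop("lo must be < hi")
  10^seq(log10(lo), log10(hi), length.out = n_steps)
}
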
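#' @importFrom rlang %||% .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# FWHM of a Gaussian relates to sigma by FWHM = 2 sqrt(2 ln 2) sigma
FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Discrete unit-mass Gaussian kernel
#'
#' Kernel weights on the bin grid, truncated at +/- 4 sigma and normalized to
#' sum to one, so smoothing conserves total spike mass away from edges.
#'
#' @param fwhm_ms Full width at half maximum in ms.
#' @param resolution_ms Bin width in ms.
#' @return Numeric vector of odd length.
#' @keywords internal
gaussian_kernel <- function(fwhm_ms, resolution_ms = 1) {
  stopifnot(fwhm_ms > 0)
  sigma <- fwhm_ms * FWHM_TO_SIGMA / resolution_ms # in bins
  half <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(seq(-half, half), sd = sigma)
  w / sum(w)
}

# Same-length zero-padded convolution with an odd-length centred kernel.
conv_same <- function(x, w) {
  n <- length(x)
  half <- (length(w) - 1L) %/% 2L
  full <- stats::convolve(x, rev(w), type = "open")
  full[(half + 1L):(half + n)]
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL runs in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
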
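#' Selection intensity for truncating the top fraction of a normal index
#'
#' For truncation selection keeping the upper fraction `p` of a normally
#' distributed index, the standardized selection differential (intensity) is
#' `i = phi(z) / p`, with `z` the upper-p quantile of the standard normal
#' and `phi` its density. This is the infinite-population result; an
#' optional first-order finite-population correction
#' `i_N = i - (1 - p) / (2 i p (N + 1))` is available for comparing against
#' simulations of modest size.
#'
#' @param p Selected fraction(s) in (0, 1).
#' @param N Population size; `Inf` (default) gives the classical formula.
#' @return Selection intensity (vectorized over `p`).
#' @export
intensity_from_fraction <- function(p, N = Inf) {
  p <- as.numeric(p)
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly in (0, 1)")
  z <- stats::qnorm(p, lower.tail = FALSE)
  i <- stats::dnorm(z) / p
  if (is.finite(N)) {
    i <- i - (1 - p) / (2 * i * p * (N + 1))
  }
  i
}

#' Selected fraction implied by a required selection intensity
#'
#' Inverts [intensity_from_fraction()] by bisection, valid because intensity
#' is strictly decreasing in the selected fraction. The bisection runs on
#' the normal truncation threshold `z` (a strictly monotone reparameterization
#' of `p`), which keeps full relative precision in `p` even for the very
#' small fractions implied by large intensities; the result satisfies
#' `|delta p| < tol`. Intensities below the everything-selected limit return
#' `p -> 1` with a warning.
#'
#' @param i Required selection intensity (positive scalar or vector).
#' @param tol Tolerance on `p` (default 1e-10).
#' @return Selected fraction(s) in (0, 1).
#' @export
fraction_from_intensity <- function(i, tol = 1e-10) {
  i <- as.numeric(i)
  if (any(i <= 0)) stop("intensity must be positive")
  i_of_z <- function(z) stats::dnorm(z) / stats::pnorm(z, lower.tail = FALSE)
  vapply(i, function(ii) {
    lo <- -37; hi <- 37  # p from ~1 down to ~1e-300
    z1 <- stats::qnorm(1e-12)  # p = 1 - 1e-12
    if (i_of_z(z1) >= ii) {
      warning("intensity ", ii, " is below the p -> 1 limit; returning ~1")
      return(stats::pnorm(z1, lower.tail = FALSE))
    }
    if (i_of_z(hi) <= ii) {
      stop("intensity ", ii, " exceeds the representable range")
    }
    # i_of_z strictly increases in z; a tight z-interval gives full relative
    # precision in p, and |delta p| <= |delta z| * phi(z) < tol
    iter <- 0L
    while (hi - lo > min(tol, 1e-12) && iter < 200L) {
      mid <- (lo + hi) / 2
      if (i_of_z(mid) < ii) lo <- mid else hi <- mid
      iter <- iter + 1L
    }
    stats::pnorm((lo + hi) / 2, lower.tail = FALSE)
  }, numeric(1))
}

#' Truncation point summary for a selected fraction
#'
#' @param p Selected fraction in (0, 1).
#' @return A list with `p`, the truncation threshold `z` (upper-p standard
#'   normal quantile) and the intensity `i`.
#' @export
truncation_point <- function(p) {
  stopifnot(length(p) == 1L, p > 0, p < 1)
  z <- stats::qnorm(p, lower.tail = FALSE)
  list(p = p, z = z, i = stats::dnorm(z) / p)
}
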
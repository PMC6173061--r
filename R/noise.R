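#' Negative-binomial parameters of the camera count distribution
#'
#' The photon counts of the imaging system are overdispersed: the variance
#' grows linearly with the mean, \eqn{\sigma^2 = g \mu} with gain factor
#' \eqn{g} (3 for the calibrated system). A negative binomial with size
#' \eqn{r = \mu^2 / (\sigma^2 - \mu) = \mu / (g - 1)} and success
#' probability \eqn{p = \mu / \sigma^2 = 1 / g} has exactly this mean and
#' variance. The size parameter is real-valued; sampling goes through the
#' gamma-Poisson mixture (see [sampleIntensity()]), which is well defined
#' for any \eqn{r > 0}.
#'
#' @param mu expected count(s), `> 0`.
#' @param gain gain factor \eqn{g > 1} (at \eqn{g \to 1} the distribution
#'   degenerates to Poisson and the size diverges).
#' @return a list with components `size` and `prob`.
#' @examples
#' nbParameters(2500, 3)  # size 1250, prob 1/3; variance 3 * 2500
#' @export
nbParameters <- function(mu, gain) {
  if (any(mu <= 0)) stop("mu must be positive")
  stopifnot(gain > 1)
  list(size = mu / (gain - 1), prob = 1 / gain)
}

#' Sample noisy camera counts
#'
#' Draws negative-binomial counts with mean `mu` and variance `gain * mu`
#' via [stats::rnbinom()] (a gamma-Poisson mixture, valid for real-valued
#' size). Uses R's global RNG stream: call [set.seed()] for reproducibility.
#'
#' @param mu expected count(s), `> 0`; recycled to length `n`.
#' @param gain gain factor \eqn{g > 1}.
#' @param n number of draws (default one per element of `mu`).
#' @return integer-valued counts `>= 0`, length `n`.
#' @examples
#' set.seed(1)
#' x <- sampleIntensity(2500, 3, 1e5)
#' c(mean(x), var(x) / mean(x))  # ~2500 and ~3
#' @export
sampleIntensity <- function(mu, gain, n = length(mu)) {
  p <- nbParameters(mu, gain)
  rnbinom(n, size = p$size, prob = p$prob)
}

#' Variance of the normalized light intensity
#'
#' Error propagation of the count noise \eqn{\sigma_I^2 = g I} through the
#' normalization [normalizeIntensity()], including the uncertainty of the
#' transmittance estimated from the \eqn{N_P} samples of the profile:
#' \deqn{\sigma_N^2 = \frac{g I_{ji}}{I_{jT}^2} +
#'   \frac{g I_{ji}^2}{N_P I_{jT}^3}.}
#' The reciprocal square roots of these variances are the ROFL fit weights.
#' Counts below `floor` are clamped to it so that zero-count pixels still
#' get a finite weight.
#'
#' @param I measured count(s) \eqn{I_{ji}}.
#' @param IT transmittance \eqn{I_{jT} > 0} (recycled along `I`).
#' @param gain gain factor \eqn{g}.
#' @param nPolarizer number of polarizer positions \eqn{N_P} entering the
#'   transmittance estimate.
#' @param floor minimum count substituted for smaller (or zero) intensities.
#' @return variance(s) of the normalized intensity, strictly positive.
#' @examples
#' normalizedVariance(1250, 2500, 3, 18)  # 6.1667e-4
#' @export
normalizedVariance <- function(I, IT, gain, nPolarizer, floor = 1) {
  if (any(IT <= 0)) stop("degenerate transmittance: IT must be positive")
  I <- pmax(I, floor)
  gain * I / IT^2 + gain * I^2 / (nPolarizer * IT^3)
}
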
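#' Extract the standard 3D-PLI modalities from a rotation profile
#'
#' The signal model contains only a DC component and the second harmonic in
#' the rotation angle, so a discrete harmonic projection recovers all three
#' standard modalities from one profile:
#' \itemize{
#'   \item transmittance \eqn{I_T = 2 a_0} with \eqn{a_0} the profile mean,
#'   \item retardation \eqn{|\sin\delta| = \sqrt{c^2 + s^2} / a_0} with
#'     \eqn{c = \frac{2}{N_P}\sum_i I_i \sin 2\rho_i},
#'     \eqn{s = \frac{2}{N_P}\sum_i I_i \cos 2\rho_i},
#'   \item direction \eqn{\varphi = \frac{1}{2}\,\mathrm{atan2}(-s, c)
#'     \bmod \pi} (the phase convention that makes the noise-free round trip
#'     with the \eqn{\sin(2(\rho - \varphi))} model exact).
#' }
#' The projection requires the \eqn{\rho_i} to be equally spaced so that
#' \eqn{2\rho} covers the circle uniformly. Noise can push the raw
#' retardation above 1; it is clamped with a warning (the ROFL fit refits
#' the raw profile anyway).
#'
#' @param profile numeric vector of \eqn{N_P \ge 5} intensities.
#' @param rho polarizer rotation angles in radians, same length.
#' @return a list with components `transmittance`, `direction` (radians in
#'   \eqn{[0, \pi)}) and `retardation` (\eqn{|\sin\delta| \in [0, 1]}).
#' @examples
#' acq <- pliAcquisition()
#' I <- intensityProfile(degToRad(101), degToRad(-60), 0.5, acq)
#' extractModalities(I["planar", ], rhoAngles(acq))
#' @export
extractModalities <- function(profile, rho) {
  np <- length(profile)
  if (np < 5L) stop("at least 5 profile samples are required")
  if (length(rho) != np) stop("profile and rho lengths differ")
  if (all(profile == 0)) stop("all-zero profile: no transmittance")
  a0 <- mean(profile)
  cc <- 2 / np * sum(profile * sin(2 * rho))
  ss <- 2 / np * sum(profile * cos(2 * rho))
  amp <- sqrt(cc^2 + ss^2)
  ret <- amp / a0
  if (ret > 1) {
    warning("retardation above 1 clamped (noisy profile)")
    ret <- 1
  }
  phi <- if (amp < .Machine$double.eps * abs(a0) * 8) 0
         else (0.5 * atan2(-ss, cc)) %% pi
  list(transmittance = 2 * a0, direction = phi, retardation = ret)
}

#' Modalities of every stage position of a series
#'
#' Applies [extractModalities()] row-wise to the intensity matrix of a
#' measurement series.
#'
#' @param series a [MeasurementSeries-class].
#' @return a data.frame with one row per stage position and columns `label`,
#'   `transmittance`, `direction`, `retardation`.
#' @export
seriesModalities <- function(series) {
  acq <- acquisition(series)
  I <- intensities(series)
  m <- lapply(seq_len(nrow(I)), function(j) extractModalities(I[j, ], acq@rho))
  data.frame(label = acq@tiltLabels,
             transmittance = vapply(m, `[[`, numeric(1), "transmittance"),
             direction = vapply(m, `[[`, numeric(1), "direction"),
             retardation = vapply(m, `[[`, numeric(1), "retardation"))
}
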
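## Internal fast path ---------------------------------------------------------
##
## Per-acquisition precomputation shared by the forward model, the fitter and
## the simulation harness. The second-harmonic decomposition
##   f_ji = sin(2(rho_i - phi_j)) sin(delta_j)
##        = sin(2 rho_i) [cos(2 phi_j) sin(delta_j)]
##        - cos(2 rho_i) [sin(2 phi_j) sin(delta_j)]
## lets every profile be assembled from two outer products; cos(2 phi_j) and
## sin(2 phi_j) come directly from the planar components (x, y) of the tilted
## unit vector, avoiding any trigonometric inversion:
##   cos^2(alpha_j) = x^2 + y^2,  cos(2 phi_j) = (x^2 - y^2) / (x^2 + y^2),
##   sin(2 phi_j) = 2 x y / (x^2 + y^2).
## All quantities are invariant under v -> -v, so no half-sphere folding is
## needed inside the hot loop.

.acqCore <- function(acq) {
  nt <- length(acq@tiltTau)
  RM <- do.call(rbind, lapply(seq_len(nt), function(j)
    tiltRotationMatrix(acq@tiltPsi[j], acq@tiltTau[j])))
  list(s2r = sin(2 * acq@rho), c2r = cos(2 * acq@rho),
       RM = RM, nt = nt, np = length(acq@rho),
       it = acq@transmittance, gain = acq@gain)
}

## Normalized model intensities f (nt x np) for one parameter set.
## pathScale multiplies d per stage position (path-length correction).
.modelNormalized <- function(phi, alpha, d, core, pathScale = 1) {
  ca <- cos(alpha)
  v <- c(ca * cos(phi), ca * sin(phi), sin(alpha))
  Vt <- core$RM %*% v
  dim(Vt) <- c(3L, core$nt)
  x <- Vt[1L, ]; y <- Vt[2L, ]
  r2 <- x * x + y * y
  sind <- sin(pi / 2 * abs(d) * pathScale * r2)
  den <- pmax(r2, 1e-300)
  A <- (x * x - y * y) / den * sind
  B <- (2 * x * y) / den * sind
  outer(A, core$s2r) - outer(B, core$c2r)
}

.pathScale <- function(acq, pathLengthCorrection) {
  if (pathLengthCorrection) 1 / cos(acq@tiltTau) else rep(1, length(acq@tiltTau))
}

#' Retardation of a birefringent fiber
#'
#' \eqn{\sin\delta} with \eqn{\delta = \frac{\pi}{2} d \cos^2\alpha}: the
#' relative amplitude of the sinusoidal rotation profile. It confounds the
#' inclination \eqn{\alpha} and the relative thickness \eqn{d}; for
#' \eqn{d \le 1} it is monotone in both, for \eqn{d > 1} the outer sine
#' wraps and the single-view inversion becomes ambiguous.
#'
#' @param alpha inclination angle, radians.
#' @param d relative thickness, `>= 0` (vectorized).
#' @return \eqn{\sin\delta \in [-1, 1]}.
#' @examples
#' retardation(0, 1)                 # 1: quarter-wave fiber
#' retardation(pi / 2, 0.7)          # 0: vertical fiber, no modulation
#' @export
retardation <- function(alpha, d) {
  stopifnot(all(d >= 0))
  sin(pi / 2 * d * cos(alpha)^2)
}

#' Noise-free intensity profiles of a tilting measurement
#'
#' For every stage position \eqn{j} the fiber orientation is rotated by the
#' stage ([tiltOrientation()]) and the sinusoidal signal model
#' \deqn{I_{ji} = \frac{I_T}{2}\left(1 + \sin(2(\rho_i - \varphi_j))
#'   \sin\delta_j\right)}
#' is evaluated at the polarizer angles, where \eqn{I_T/2} is the expected
#' profile mean (`transmittance(acq)`) and
#' \eqn{\sin\delta_j = \sin(\frac{\pi}{2} d_j \cos^2\alpha_j)}.
#'
#' @param phi,alpha fiber orientation, radians.
#' @param d relative thickness.
#' @param acq a [PLIAcquisition-class].
#' @param pathLengthCorrection logical; if `TRUE` the per-position thickness
#'   is scaled to \eqn{d_j = d / \cos\tau_j} to account for the longer light
#'   path through the tilted section. Off by default: tilting is modeled as
#'   changing only the orientation.
#' @return an \eqn{N_T \times N_P} matrix of expected counts.
#' @examples
#' acq <- pliAcquisition()
#' I <- intensityProfile(degToRad(45), degToRad(30), 0.5, acq)
#' rowMeans(I)  # the transmittance, identical for every stage position
#' @export
intensityProfile <- function(phi, alpha, d, acq, pathLengthCorrection = FALSE) {
  stopifnot(d >= 0)
  core <- .acqCore(acq)
  I <- acq@transmittance *
    (1 + .modelNormalized(phi, alpha, d, core, .pathScale(acq, pathLengthCorrection)))
  dimnames(I) <- list(acq@tiltLabels, NULL)
  I
}

#' Normalized model intensities
#'
#' The model prediction for the normalized data: \eqn{f_{ji} =
#' \sin(2(\rho_i - \varphi_j)) \sin(\frac{\pi}{2} d_j \cos^2\alpha_j)},
#' the quantity the ROFL fit matches against [normalizeIntensity()] of the
#' measured counts. Odd in \eqn{d}: \eqn{f(\varphi, \alpha, d) =
#' -f(\varphi, \alpha, -d)}.
#'
#' @inheritParams intensityProfile
#' @param d relative thickness (may be negative; the sign flips `f`).
#' @return an \eqn{N_T \times N_P} matrix with values in \eqn{[-1, 1]}.
#' @export
normalizedModel <- function(phi, alpha, d, acq, pathLengthCorrection = FALSE) {
  core <- .acqCore(acq)
  f <- sign(d) * .modelNormalized(phi, alpha, abs(d), core,
                                  .pathScale(acq, pathLengthCorrection))
  dimnames(f) <- list(acq@tiltLabels, NULL)
  f
}

#' Normalize measured intensities by the transmittance
#'
#' \eqn{I_N = 2 I / I_{jT} - 1}, mapping a profile into \eqn{[-1, 1]} and
#' removing the per-position transmittance (which absorbs the additional
#' absorption and refraction of tilted views that the model cannot capture).
#' \eqn{I_{jT}} is twice the profile mean, see [extractModalities()].
#'
#' @param I intensities (counts), any shape.
#' @param IT transmittance \eqn{I_{jT} > 0}; recycled along `I` (for an
#'   \eqn{N_T \times N_P} matrix pass one value per row).
#' @return normalized intensities of the same shape as `I`.
#' @export
normalizeIntensity <- function(I, IT) {
  if (any(IT <= 0)) stop("degenerate transmittance: IT must be positive")
  2 * I / IT - 1
}
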
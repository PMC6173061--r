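#' Acquisition geometry and camera model of a tilting 3D-PLI measurement
#'
#' A `PLIAcquisition` describes one standard measurement protocol: the
#' polarizer rotation angles \eqn{\rho_i}, the stage positions (the planar
#' view plus `nTilt` oblique views with tilting direction \eqn{\psi_j} and
#' tilting angle \eqn{\tau_j}), the expected mean light intensity of a
#' rotation profile (the transmittance \eqn{I_T/2}, in camera counts), the
#' camera gain factor \eqn{g} relating count variance to count mean
#' (\eqn{\sigma^2 = g\mu}), and the tissue refractive index used for the
#' Snell correction of the stage tilt.
#'
#' @slot rho numeric, polarizer rotation angles in radians (length
#'   \eqn{N_P}), equally spaced starting at 0.
#' @slot tiltPsi numeric, tilting direction angles \eqn{\psi_j} in radians,
#'   one per stage position including the planar view (length \eqn{N_T}).
#' @slot tiltTau numeric, tilting angles \eqn{\tau_j} in radians. The first
#'   position is the planar view with \eqn{\tau = 0}; these are the tilt
#'   angles *inside the tissue* as used by the signal model.
#' @slot tiltLabels character, stage position labels
#'   (`"planar"`, `"N"`, `"E"`, `"S"`, `"W"`, ...).
#' @slot transmittance numeric(1), expected mean intensity of a rotation
#'   profile in counts.
#' @slot gain numeric(1), camera gain factor \eqn{g > 1}.
#' @slot nTissue numeric(1), tissue refractive index (\eqn{\ge 1}).
#'
#' @seealso [pliAcquisition()] for the user constructor.
#' @export
setClass("PLIAcquisition",
  representation(
    rho = "numeric",
    tiltPsi = "numeric",
    tiltTau = "numeric",
    tiltLabels = "character",
    transmittance = "numeric",
    gain = "numeric",
    nTissue = "numeric"
  )
)

setValidity("PLIAcquisition", function(object) {
  msg <- character()
  np <- length(object@rho)
  nt <- length(object@tiltTau)
  if (np < 3L) msg <- c(msg, "at least 3 polarizer positions are required")
  if (np >= 2L) {
    steps <- diff(object@rho)
    if (object@rho[1] != 0 || any(abs(steps - steps[1]) > 1e-9))
      msg <- c(msg, "rho must be equally spaced angles starting at 0")
  }
  if (length(object@tiltPsi) != nt || length(object@tiltLabels) != nt)
    msg <- c(msg, "tiltPsi, tiltTau and tiltLabels must have equal length")
  if (sum(abs(object@tiltTau) < 1e-12) != 1L)
    msg <- c(msg, "exactly one stage position must be planar (tau = 0)")
  else if (abs(object@tiltTau[1]) > 1e-12)
    msg <- c(msg, "the planar position (tau = 0) must come first (index j = 0)")
  if (length(object@transmittance) != 1L || object@transmittance <= 0)
    msg <- c(msg, "transmittance must be a single positive count value")
  if (length(object@gain) != 1L || object@gain <= 1)
    msg <- c(msg, "gain must be a single value > 1")
  if (length(object@nTissue) != 1L || object@nTissue < 1)
    msg <- c(msg, "nTissue must be a single value >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a tilting 3D-PLI acquisition description
#'
#' Defaults reproduce the standard measurement protocol: 18 polarizer steps
#' of 10 degrees, a planar view plus four oblique views (N, E, S, W) whose
#' tilting directions span the circle equidistantly
#' (\eqn{\psi_j = 2\pi (j-1)/N_{Tilt}}), an in-tissue tilting angle of 5.51
#' degrees (the Snell-corrected angle for an 8 degree stage tilt at tissue
#' refractive index 1.45, see [snellInternalAngle()]), an expected profile
#' mean of 2500 counts and a camera gain factor of 3.
#'
#' @param nPolarizer integer, number of polarizer rotation angles \eqn{N_P}.
#' @param rhoStepDeg numeric, polarizer step in degrees.
#' @param nTilt integer, number of oblique stage positions.
#' @param tiltAngleDeg numeric, in-tissue tilting angle \eqn{\tau} in degrees
#'   applied at every oblique position. For experimental stacks convert the
#'   stage angle first: `radToDeg(snellInternalAngle(degToRad(8), 1.45))`.
#' @param transmittance numeric, expected mean profile intensity in counts.
#' @param gain numeric, camera gain factor \eqn{g}.
#' @param nTissue numeric, tissue refractive index.
#' @param tiltLabels character, labels of the oblique positions.
#' @return A [PLIAcquisition-class] object.
#' @examples
#' acq <- pliAcquisition()
#' acq
#' @export
pliAcquisition <- function(nPolarizer = 18L, rhoStepDeg = 10, nTilt = 4L,
                           tiltAngleDeg = 5.51, transmittance = 2500,
                           gain = 3, nTissue = 1.45,
                           tiltLabels = c("N", "E", "S", "W")) {
  nPolarizer <- as.integer(nPolarizer)
  nTilt <- as.integer(nTilt)
  stopifnot(nPolarizer >= 3L, nTilt >= 0L)
  if (length(tiltLabels) != nTilt)
    tiltLabels <- if (nTilt > 0L) paste0("T", seq_len(nTilt)) else character()
  psi <- if (nTilt > 0L) 2 * pi * (seq_len(nTilt) - 1) / nTilt else numeric()
  new("PLIAcquisition",
      rho = (seq_len(nPolarizer) - 1) * degToRad(rhoStepDeg),
      tiltPsi = c(0, psi),
      tiltTau = c(0, rep(degToRad(tiltAngleDeg), nTilt)),
      tiltLabels = c("planar", tiltLabels),
      transmittance = transmittance, gain = gain, nTissue = nTissue)
}

#' Per-pixel intensity series of a tilting measurement
#'
#' The raw data of one pixel: an \eqn{N_T \times N_P} matrix of light
#' intensities \eqn{I_{ji}} (stage position \eqn{j} in rows, polarizer
#' rotation angle \eqn{\rho_i} in columns), together with the acquisition
#' that produced it.
#'
#' @slot intensities numeric matrix, \eqn{N_T \times N_P}, counts
#'   (non-negative).
#' @slot acquisition a [PLIAcquisition-class].
#'
#' @seealso [measurementSeries()], [simulateSeries()], [fitPixel()].
#' @export
setClass("MeasurementSeries",
  representation(intensities = "matrix", acquisition = "PLIAcquisition")
)

setValidity("MeasurementSeries", function(object) {
  msg <- character()
  acq <- object@acquisition
  I <- object@intensities
  if (!is.numeric(I)) msg <- c(msg, "intensities must be numeric")
  if (nrow(I) != length(acq@tiltTau) || ncol(I) != length(acq@rho))
    msg <- c(msg, sprintf("intensities must be %d x %d (stage positions x polarizer angles)",
                          length(acq@tiltTau), length(acq@rho)))
  if (any(!is.finite(I)) || any(I < 0))
    msg <- c(msg, "intensities must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a per-pixel measurement series
#'
#' @param intensities numeric \eqn{N_T \times N_P} matrix of counts.
#' @param acquisition a [PLIAcquisition-class].
#' @return A [MeasurementSeries-class] object.
#' @examples
#' acq <- pliAcquisition()
#' I <- intensityProfile(degToRad(45), degToRad(30), 0.5, acq)
#' measurementSeries(I, acq)
#' @export
measurementSeries <- function(intensities, acquisition) {
  new("MeasurementSeries", intensities = intensities, acquisition = acquisition)
}

#' Result of a per-pixel ROFL fit
#'
#' Holds the fitted parameters in the standard 3D-PLI parameter space:
#' direction \eqn{\varphi \in [0, \pi)}, inclination
#' \eqn{\alpha \in [-\pi/2, \pi/2]} and relative thickness \eqn{d \ge 0}
#' (deliberately not capped at 1; values above 1 flag that the single-fiber
#' model does not describe the pixel, e.g. at fiber crossings), with the
#' weighted residual sum \eqn{\chi^2} and the diagnostic
#' \eqn{R^2 = 1 - \chi^2 / \sum (w I_N)^2}.
#'
#' @slot phi numeric(1), direction angle in radians.
#' @slot alpha numeric(1), inclination angle in radians.
#' @slot d numeric(1), relative thickness.
#' @slot chi2 numeric(1), weighted residual sum of squares.
#' @slot rsq numeric(1), coefficient of determination of the weighted fit.
#' @slot converged logical(1), optimizer convergence flag (a `FALSE` result
#'   is still the best point found, never an error).
#' @slot niter integer(1), number of optimizer iterations.
#' @export
setClass("PixelFit",
  representation(phi = "numeric", alpha = "numeric", d = "numeric",
                 chi2 = "numeric", rsq = "numeric",
                 converged = "logical", niter = "integer")
)

setValidity("PixelFit", function(object) {
  msg <- character()
  if (object@d < 0) msg <- c(msg, "d must be non-negative")
  if (object@phi < 0 || object@phi >= pi) msg <- c(msg, "phi must lie in [0, pi)")
  if (abs(object@alpha) > pi / 2 + 1e-12) msg <- c(msg, "alpha must lie in [-pi/2, pi/2]")
  if (object@chi2 < 0) msg <- c(msg, "chi2 must be non-negative")
  if (length(msg)) msg else TRUE
})
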
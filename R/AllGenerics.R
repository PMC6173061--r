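#' @name accessors
#' @title Accessors for acquisition, series and fit objects
#' @param object a [PLIAcquisition-class], [MeasurementSeries-class] or
#'   [PixelFit-class].
#' @description Slot access goes through these accessors; the slot layout is
#'   not part of the API.
NULL

#' @describeIn accessors polarizer rotation angles \eqn{\rho_i} (radians).
#' @export
setGeneric("rhoAngles", function(object) standardGeneric("rhoAngles"))

#' @describeIn accessors stage positions as a data.frame with columns
#'   `index` (0 = planar), `label`, `psi_deg`, `tau_deg`.
#' @export
setGeneric("tiltTable", function(object) standardGeneric("tiltTable"))

#' @describeIn accessors expected mean profile intensity (counts).
#' @export
setGeneric("transmittance", function(object) standardGeneric("transmittance"))

#' @describeIn accessors camera gain factor \eqn{g}.
#' @export
setGeneric("gain", function(object) standardGeneric("gain"))

#' @describeIn accessors number of polarizer positions \eqn{N_P}.
#' @export
setGeneric("nPolarizer", function(object) standardGeneric("nPolarizer"))

#' @describeIn accessors number of stage positions \eqn{N_T}
#'   (oblique views + planar).
#' @export
setGeneric("nPositions", function(object) standardGeneric("nPositions"))

#' @describeIn accessors intensity matrix \eqn{I_{ji}} of a series.
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @describeIn accessors the [PLIAcquisition-class] behind a series.
#' @export
setGeneric("acquisition", function(object) standardGeneric("acquisition"))

#' @describeIn accessors fitted parameters of a [PixelFit-class] as a named
#'   vector `c(phi, alpha, d, chi2, rsq)` (angles in radians).
#' @export
setGeneric("fitParams", function(object) standardGeneric("fitParams"))

#' Fit the 3D-PLI model to a measurement series (ROFL)
#'
#' @param series a [MeasurementSeries-class].
#' @param control a [roflControl()] list.
#' @return A [PixelFit-class].
#' @seealso [fitImage()] for whole image stacks.
#' @export
setGeneric("fitPixel", function(series, control = roflControl())
  standardGeneric("fitPixel"))

setMethod("rhoAngles", "PLIAcquisition", function(object) object@rho)
setMethod("transmittance", "PLIAcquisition", function(object) object@transmittance)
setMethod("gain", "PLIAcquisition", function(object) object@gain)
setMethod("nPolarizer", "PLIAcquisition", function(object) length(object@rho))
setMethod("nPositions", "PLIAcquisition", function(object) length(object@tiltTau))
setMethod("tiltTable", "PLIAcquisition", function(object)
  data.frame(index = seq_along(object@tiltTau) - 1L,
             label = object@tiltLabels,
             psi_deg = radToDeg(object@tiltPsi),
             tau_deg = radToDeg(object@tiltTau)))

setMethod("intensities", "MeasurementSeries", function(object) object@intensities)
setMethod("acquisition", "MeasurementSeries", function(object) object@acquisition)
setMethod("rhoAngles", "MeasurementSeries", function(object) object@acquisition@rho)
setMethod("gain", "MeasurementSeries", function(object) object@acquisition@gain)

setMethod("fitParams", "PixelFit", function(object)
  c(phi = object@phi, alpha = object@alpha, d = object@d,
    chi2 = object@chi2, rsq = object@rsq))

setMethod("show", "PLIAcquisition", function(object) {
  cat(sprintf("PLIAcquisition: %d polarizer angles (step %.4g deg), %d stage positions\n",
              nPolarizer(object), radToDeg(object@rho[2] - object@rho[1]),
              nPositions(object)))
  cat(sprintf("  transmittance %.4g counts, gain %.4g, refractive index %.4g\n",
              object@transmittance, object@gain, object@nTissue))
  tt <- tiltTable(object)
  cat(sprintf("  tilts: %s\n",
              paste(sprintf("%s(psi=%g,tau=%g)", tt$label, tt$psi_deg, tt$tau_deg),
                    collapse = " ")))
  invisible(NULL)
})

setMethod("show", "MeasurementSeries", function(object) {
  I <- object@intensities
  cat(sprintf("MeasurementSeries: %d x %d intensities, mean %.1f counts\n",
              nrow(I), ncol(I), mean(I)))
  invisible(NULL)
})

setMethod("show", "PixelFit", function(object) {
  cat(sprintf(
    "PixelFit: phi = %.2f deg, alpha = %.2f deg, d = %.4f (chi2 = %.2f, R2 = %.3f%s)\n",
    radToDeg(object@phi), radToDeg(object@alpha), object@d, object@chi2,
    object@rsq, if (object@converged) "" else ", NOT converged"))
  invisible(NULL)
})
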
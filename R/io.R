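## Stack and map I/O.
##
## On-disk layout of a measurement stack: one directory containing
##   meta.json                    acquisition + scaling metadata
##   stack_j<j>_<label>.tif       one multi-page TIFF per stage position
##                                (N_P pages of H x W), 32-bit samples
##                                normalized by meta$max_count
## Angles live in degrees on disk and in radians in memory.

.writeScaledTIFF <- function(pages, path, scale) {
  tiff::writeTIFF(lapply(pages, function(m) m / scale), path,
                  bits.per.sample = 32L, compression = "none", reduce = FALSE)
}

.readScaledTIFF <- function(path, scale) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(m) m * scale)
}

#' Write a measurement stack to a directory
#'
#' @param stack numeric array \eqn{N_T \times N_P \times H \times W} of
#'   counts.
#' @param acq the [PLIAcquisition-class] that produced it.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @seealso [readStack()] for the lossless inverse.
#' @export
writeStack <- function(stack, acq, dir) {
  stopifnot(length(dim(stack)) == 4L,
            dim(stack)[1] == nPositions(acq),
            dim(stack)[2] == nPolarizer(acq))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  maxCount <- max(stack, 1)
  tt <- tiltTable(acq)
  meta <- list(
    format = "rofl-stack-1",
    n_positions = nPositions(acq),
    n_polarizer = nPolarizer(acq),
    height = dim(stack)[3], width = dim(stack)[4],
    rho_step_deg = radToDeg(acq@rho[2] - acq@rho[1]),
    tilt_labels = tt$label, tilt_psi_deg = tt$psi_deg, tilt_tau_deg = tt$tau_deg,
    transmittance = transmittance(acq), gain = gain(acq),
    n_tissue = acq@nTissue, max_count = maxCount)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  for (j in seq_len(dim(stack)[1])) {
    pages <- lapply(seq_len(dim(stack)[2]), function(i)
      matrix(stack[j, i, , ], dim(stack)[3], dim(stack)[4]))
    .writeScaledTIFF(pages, file.path(dir, sprintf("stack_j%d_%s.tif",
                                                   j - 1L, tt$label[j])),
                     maxCount)
  }
  invisible(dir)
}

#' Read a measurement stack from a directory
#'
#' @param dir a directory written by [writeStack()].
#' @return a list with elements `stack` (4-d array) and `acq`
#'   (reconstructed [PLIAcquisition-class]).
#' @export
readStack <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath)) stop("missing required file: meta.json")
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  for (req in c("n_positions", "n_polarizer", "rho_step_deg", "tilt_psi_deg",
                "tilt_tau_deg", "tilt_labels", "gain", "max_count"))
    if (is.null(meta[[req]]))
      stop(sprintf("stack metadata is missing attribute '%s'", req))
  acq <- new("PLIAcquisition",
             rho = (seq_len(meta$n_polarizer) - 1) * degToRad(meta$rho_step_deg),
             tiltPsi = degToRad(meta$tilt_psi_deg),
             tiltTau = degToRad(meta$tilt_tau_deg),
             tiltLabels = meta$tilt_labels,
             transmittance = meta$transmittance %||% 2500,
             gain = meta$gain, nTissue = meta$n_tissue %||% 1.45)
  stack <- array(NA_real_, c(meta$n_positions, meta$n_polarizer,
                             meta$height, meta$width))
  for (j in seq_len(meta$n_positions)) {
    f <- file.path(dir, sprintf("stack_j%d_%s.tif", j - 1L, meta$tilt_labels[j]))
    if (!file.exists(f)) stop("missing stack file: ", basename(f))
    pages <- .readScaledTIFF(f, meta$max_count)
    if (length(pages) != meta$n_polarizer)
      stop(sprintf("%s: expected %d pages, found %d", basename(f),
                   meta$n_polarizer, length(pages)))
    for (i in seq_along(pages)) stack[j, i, , ] <- round(pages[[i]])
  }
  list(stack = stack, acq = acq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write fitted parameter maps to a directory
#'
#' Writes `direction.tif` (degrees, \eqn{[0, 180)}), `inclination.tif`
#' (degrees, \eqn{[-90, 90]}), `thickness.tif`, `chi2.tif` and `rsq.tif` as
#' 32-bit TIFFs. Sample values are stored normalized to an affine range
#' recorded per map in `maps.json` (32-bit resolution of the range, i.e.
#' lossless for all practical purposes); background `NA` pixels are encoded
#' through `mask.tif`.
#'
#' @param maps a list as returned by [fitImage()] (angles in radians).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeMaps <- function(maps, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  deg <- list(direction = radToDeg(maps$direction) %% 180,
              inclination = radToDeg(maps$inclination),
              thickness = maps$thickness,
              chi2 = maps$chi2, rsq = maps$rsq)
  ranges <- list()
  for (nm in names(deg)) {
    m <- deg[[nm]]
    if (is.null(m)) next
    lo <- min(m, 0, na.rm = TRUE)
    hi <- max(m, lo + 1, na.rm = TRUE)
    ranges[[nm]] <- c(lo, hi)
    m[is.na(m)] <- lo
    .writeScaledTIFF(list((m - lo)), file.path(dir, paste0(nm, ".tif")), hi - lo)
  }
  mask <- if (!is.null(maps$mask)) maps$mask else !is.na(deg$direction)
  tiff::writeTIFF(mask * 1, file.path(dir, "mask.tif"), bits.per.sample = 8L,
                  compression = "none")
  jsonlite::write_json(list(format = "rofl-maps-1", ranges = ranges),
                       file.path(dir, "maps.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read parameter maps written by [writeMaps()]
#'
#' @param dir the map directory.
#' @return a list of matrices (`direction`/`inclination` in radians, plus
#'   `thickness`, `chi2`, `rsq`, `mask`), `NA` outside the mask.
#' @export
readMaps <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "maps.json"), simplifyVector = TRUE)
  mask <- tiff::readTIFF(file.path(dir, "mask.tif")) > 0.5
  out <- list()
  for (nm in names(meta$ranges)) {
    rg <- meta$ranges[[nm]]
    m <- .readScaledTIFF(file.path(dir, paste0(nm, ".tif")), rg[2] - rg[1])[[1]] + rg[1]
    m[!mask] <- NA_real_
    out[[nm]] <- m
  }
  out$direction <- degToRad(out$direction)
  out$inclination <- degToRad(out$inclination)
  out$mask <- mask
  out
}
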
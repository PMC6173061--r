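#' Generate a synthetic measurement stack with known ground truth
#'
#' Builds an \eqn{H \times W} phantom from rectangular tissue regions, each
#' with its own fiber parameters (for example a dense white-matter region, a
#' weakly myelinated cortex-like region with small \eqn{d}, and a steep
#' fiber tract), simulates the full tilting measurement per pixel with
#' negative-binomial noise, and returns the stack together with the
#' ground-truth maps. Pixels covered by no region are background:
#' transmittance only (zero retardation) at `backgroundTransmittance`
#' counts.
#'
#' @param regions a list; each element a list with `rows`, `cols` (integer
#'   index vectors into the image) and `phi`, `alpha` (radians), `d`.
#'   Regions must not overlap.
#' @param height,width image size in pixels.
#' @param acq a [PLIAcquisition-class].
#' @param backgroundTransmittance expected profile mean of background
#'   pixels, counts (default: 40 percent of the tissue transmittance, since
#'   unobstructed glass transmits differently than tissue; set equal to
#'   `transmittance(acq)` for a flat field).
#' @param noise if `FALSE` the noise-free expected counts are returned
#'   (exact-recovery testing).
#' @param seed optional integer seed.
#' @return a list with elements `stack` (array \eqn{N_T \times N_P \times H
#'   \times W}), `truth` (list of `H x W` maps `direction`, `inclination`,
#'   `thickness`, with `NA` in the background) and `acq`.
#' @examples
#' ph <- generatePhantom(
#'   list(list(rows = 1:4, cols = 1:8, phi = 0, alpha = degToRad(10), d = 0.8),
#'        list(rows = 5:8, cols = 1:8, phi = 0, alpha = degToRad(65), d = 0.6)),
#'   height = 8, width = 8, seed = 1)
#' dim(ph$stack)
#' @export
generatePhantom <- function(regions, height, width, acq = pliAcquisition(),
                            backgroundTransmittance = 0.4 * transmittance(acq),
                            noise = TRUE, seed = NULL) {
  stopifnot(height >= 1, width >= 1, length(regions) >= 1)
  if (!is.null(seed)) set.seed(seed)
  covered <- matrix(0L, height, width)
  for (rg in regions) {
    stopifnot(all(c("rows", "cols", "phi", "alpha", "d") %in% names(rg)),
              all(rg$rows >= 1 & rg$rows <= height),
              all(rg$cols >= 1 & rg$cols <= width))
    covered[rg$rows, rg$cols] <- covered[rg$rows, rg$cols] + 1L
  }
  if (any(covered > 1L)) stop("phantom regions overlap")
  nt <- nPositions(acq); np <- nPolarizer(acq)
  stack <- array(backgroundTransmittance, c(nt, np, height, width))
  truth <- list(direction = matrix(NA_real_, height, width),
                inclination = matrix(NA_real_, height, width),
                thickness = matrix(NA_real_, height, width))
  for (rg in regions) {
    mu <- intensityProfile(rg$phi, rg$alpha, rg$d, acq)
    for (r in rg$rows) for (cl in rg$cols) stack[, , r, cl] <- mu
    truth$direction[rg$rows, rg$cols] <- rg$phi %% pi
    truth$inclination[rg$rows, rg$cols] <- rg$alpha
    truth$thickness[rg$rows, rg$cols] <- rg$d
  }
  if (noise) {
    n <- length(stack)
    stack[] <- rnbinom(n, size = pmax(stack, 1e-12) / (gain(acq) - 1),
                       prob = 1 / gain(acq))
  }
  list(stack = stack, truth = truth, acq = acq)
}
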
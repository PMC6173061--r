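## Monte-Carlo validation harness: simulate noisy tilting measurements for
## known ground-truth fibers, fit them back, and quantify orientation and
## thickness recovery.

#' Simulate noisy measurement series for one fiber configuration
#'
#' Generates the noise-free profiles of [intensityProfile()] for every stage
#' position and corrupts each intensity independently with negative-binomial
#' noise of mean \eqn{I} and variance \eqn{g I} ([sampleIntensity()]).
#'
#' @param phi,alpha,d ground-truth fiber parameters (radians / relative
#'   thickness).
#' @param acq a [PLIAcquisition-class]; its `transmittance` and `gain` set
#'   the signal and noise level.
#' @param n number of independent noisy replicates.
#' @param seed optional integer seed (`NULL` leaves the RNG stream alone).
#' @return a list of `n` [MeasurementSeries-class] objects.
#' @examples
#' acq <- pliAcquisition()
#' s <- simulateSeries(degToRad(45), degToRad(30), 0.5, acq, n = 2, seed = 1)
#' s[[1]]
#' @export
simulateSeries <- function(phi, alpha, d, acq, n = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- intensityProfile(phi, alpha, d, acq)
  X <- .simulateCounts(as.vector(mu), acq@gain, n)
  lapply(seq_len(n), function(r)
    measurementSeries(matrix(X[, r], nrow(mu), ncol(mu)), acq))
}

## all replicates in one rnbinom call: (nt*np) x n matrix of counts
.simulateCounts <- function(mu, gain, n) {
  matrix(rnbinom(length(mu) * n, size = rep(mu, n) / (gain - 1), prob = 1 / gain),
         nrow = length(mu))
}

#' Compare a fitted parameter set against the ground truth
#'
#' The orientation error is the acute angle \eqn{\gamma =
#' \arccos(|v_r \cdot v_g|)} between the fitted and true fiber axes; the
#' thickness error is the absolute relative error
#' \eqn{\sigma_d = |d_r - d_g| / d_g}.
#'
#' @param truth,estimate named vectors or lists with elements `phi`, `alpha`,
#'   `d` (angles in radians); `estimate` may be a [PixelFit-class].
#' @return a named vector `c(gamma_deg, sigma_d)`.
#' @examples
#' evaluateFit(list(phi = 0, alpha = 0, d = 0.5),
#'             list(phi = pi / 2, alpha = 0, d = 1))  # gamma 90, sigma_d 1
#' @export
evaluateFit <- function(truth, estimate) {
  if (is(estimate, "PixelFit")) estimate <- fitParams(estimate)
  truth <- as.list(truth); estimate <- as.list(estimate)
  if (truth$d == 0) stop("ground-truth d must be non-zero for a relative error")
  vg <- orientationToVector(truth$phi, truth$alpha)
  vr <- orientationToVector(estimate$phi, estimate$alpha)
  c(gamma_deg = radToDeg(acuteAngle(vg, vr)),
    sigma_d = abs(estimate$d - truth$d) / truth$d)
}

## one (alpha, d) cell: n replicates simulated, fitted, summarized.
## Returns c(mean gamma deg, mean sigma_d).
.accuracyCell <- function(phi, alpha, d, core, control, n) {
  mu <- pmax(core$it * (1 + .modelNormalized(phi, alpha, d, core)), 1e-12)
  X <- .simulateCounts(as.vector(mu), core$gain, n)
  nt <- nrow(mu); np <- ncol(mu)
  vg <- orientationToVector(phi, alpha)
  gam <- sig <- numeric(n)
  for (r in seq_len(n)) {
    est <- .fitCore(matrix(X[, r], nt, np), core, control)
    vr <- orientationToVector(est[["phi"]], est[["alpha"]])
    gam[r] <- acos(min(1, abs(sum(vg * vr))))
    sig[r] <- abs(est[["d"]] - d) / d
  }
  c(radToDeg(mean(gam)), mean(sig))
}

#' Orientation/thickness accuracy surface of the ROFL fit
#'
#' For every combination of ground-truth inclination and relative thickness,
#' simulates `reps` noisy tilting measurements at a fixed direction angle
#' (default 45 degrees, the worst case for the four-point tilting scheme,
#' where the fiber azimuth bisects neighboring tilting directions), fits
#' each with ROFL and records the mean acute-angle error
#' \eqn{\langle\gamma\rangle} and the mean relative thickness error
#' \eqn{\langle\sigma_d\rangle}.
#'
#' @param alphaDeg numeric vector of ground-truth inclinations, degrees.
#' @param d numeric vector of ground-truth relative thicknesses (`> 0`).
#' @param reps replicates per configuration.
#' @param phiDeg ground-truth direction angle, degrees.
#' @param acq a [PLIAcquisition-class].
#' @param control a [roflControl()] list.
#' @param seed optional integer seed.
#' @param verbose print one progress line per inclination row.
#' @return a data.frame with columns `alpha_deg`, `d`, `mean_gamma_deg`,
#'   `mean_sigma_d`, `n`.
#' @examples
#' runAccuracyStudy(alphaDeg = c(0, 60), d = 0.5, reps = 50, seed = 1)
#' @export
runAccuracyStudy <- function(alphaDeg = seq(0, 90, 10),
                             d = seq(0.1, 0.9, 0.1),
                             reps = 500, phiDeg = 45,
                             acq = pliAcquisition(),
                             control = roflControl(),
                             seed = NULL, verbose = FALSE) {
  stopifnot(reps >= 1, length(alphaDeg) >= 1, length(d) >= 1, all(d > 0))
  if (!is.null(seed)) set.seed(seed)
  core <- .acqCore(acq)
  grid <- expand.grid(alpha_deg = alphaDeg, d = d,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$alpha_deg, grid$d), , drop = FALSE]
  rownames(grid) <- NULL
  out <- matrix(NA_real_, nrow(grid), 2)
  for (k in seq_len(nrow(grid))) {
    out[k, ] <- .accuracyCell(degToRad(phiDeg), degToRad(grid$alpha_deg[k]),
                              grid$d[k], core, control, reps)
    if (verbose && (k == nrow(grid) || grid$alpha_deg[k + 1] != grid$alpha_deg[k]))
      message(sprintf("alpha = %g deg done", grid$alpha_deg[k]))
  }
  grid$mean_gamma_deg <- out[, 1]
  grid$mean_sigma_d <- out[, 2]
  grid$n <- reps
  grid
}

#' Sample fiber orientations uniformly on the sphere
#'
#' Normalized iid Gaussian triples, folded to the half-sphere parameter
#' space. The resulting inclination density is proportional to
#' \eqn{\cos\alpha} (the circumference of the sphere's cross-section at
#' height \eqn{\sin\alpha}).
#'
#' @param n number of orientations.
#' @param seed optional integer seed.
#' @return a data.frame with columns `phi`, `alpha` (radians).
#' @export
sampleUniformOrientations <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(rnorm(3 * n), ncol = 3)
  o <- vectorToOrientation(v)
  data.frame(phi = o$phi, alpha = o$alpha)
}

#' Inclination histogram with density normalization
#'
#' Bins inclination angles into bins of `binWidthDeg` degrees covering
#' \eqn{[-90, 90]} and normalizes to a density per degree (so the densities
#' integrate to 1 over the range and are invariant under bin-width changes).
#'
#' @param alphaDeg inclination angles in degrees.
#' @param binWidthDeg bin width in degrees (must divide 180).
#' @return a data.frame with columns `alpha_deg` (bin midpoints) and
#'   `density` (per degree).
#' @export
inclinationHistogram <- function(alphaDeg, binWidthDeg = 0.25) {
  nb <- round(180 / binWidthDeg)
  if (abs(nb * binWidthDeg - 180) > 1e-9) stop("binWidthDeg must divide 180")
  br <- seq(-90, 90, length.out = nb + 1)
  cnt <- tabulate(findInterval(pmin(pmax(alphaDeg, -90), 90 - 1e-12), br,
                               rightmost.closed = TRUE), nbins = nb)
  data.frame(alpha_deg = (br[-1] + br[-(nb + 1)]) / 2,
             density = cnt / sum(cnt) / binWidthDeg)
}

#' Fit a cosine law to an inclination histogram
#'
#' Least-squares fit of \eqn{a \cos\alpha} to the per-degree bin densities.
#' For inclinations of orientations uniform on the sphere the density is
#' exactly \eqn{\frac{\pi}{360}\cos\alpha} per degree, i.e.
#' \eqn{a = \pi/360 \approx 0.008727}.
#'
#' @param hist a data.frame from [inclinationHistogram()] (columns
#'   `alpha_deg`, `density`).
#' @return the fitted proportionality factor `a` (per degree).
#' @examples
#' o <- sampleUniformOrientations(20000, seed = 1)
#' fitCosine(inclinationHistogram(radToDeg(o$alpha)))
#' @export
fitCosine <- function(hist) {
  stopifnot(all(c("alpha_deg", "density") %in% names(hist)))
  unname(coef(lm(density ~ 0 + cos(degToRad(alpha_deg)), data = hist))[1])
}

#' Inclination-bias study on uniformly distributed orientations
#'
#' Samples `n` fiber orientations uniformly on the sphere, simulates a noisy
#' tilting measurement for each at fixed relative thickness, fits it, and
#' returns true and estimated parameters. Comparing the inclination
#' histograms of truth and estimate reveals systematic inclination biases
#' (an unbiased fitter reproduces the \eqn{\cos\alpha} law without a
#' depletion dip at \eqn{\alpha = 0}).
#'
#' @param n number of orientations.
#' @param d relative thickness of all simulated fibers.
#' @param acq a [PLIAcquisition-class].
#' @param control a [roflControl()] list.
#' @param fit if `FALSE`, only the ground-truth orientations are generated
#'   (fast path for studying the sampling law itself).
#' @param seed optional integer seed.
#' @param solver per-pixel solver: a `function(series) -> PixelFit` (or a
#'   named vector with `phi`, `alpha`, `d`). Defaults to the ROFL fit;
#'   the hook exists so alternative inclination solvers can be benchmarked
#'   on identical data.
#' @return a data.frame with columns `phi_g`, `alpha_g` (truth, radians)
#'   and, when fitted, `phi_r`, `alpha_r`, `d_r`, `gamma_deg`, `sigma_d`.
#' @export
runUniformStudy <- function(n = 500000L, d = 0.5, acq = pliAcquisition(),
                            control = roflControl(), fit = TRUE, seed = NULL,
                            solver = NULL) {
  if (!is.null(seed)) set.seed(seed)
  o <- sampleUniformOrientations(n)
  out <- data.frame(phi_g = o$phi, alpha_g = o$alpha)
  if (!fit) return(out)
  core <- .acqCore(acq)
  est <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    mu <- core$it * (1 + .modelNormalized(o$phi[k], o$alpha[k], d, core))
    I <- matrix(.simulateCounts(as.vector(mu), core$gain, 1L), core$nt, core$np)
    if (is.null(solver)) {
      r <- .fitCore(I, core, control)
      est[k, ] <- r[c("phi", "alpha", "d")]
    } else {
      r <- solver(measurementSeries(I, acq))
      if (is(r, "PixelFit")) r <- fitParams(r)
      est[k, ] <- r[c("phi", "alpha", "d")]
    }
  }
  out$phi_r <- est[, 1]; out$alpha_r <- est[, 2]; out$d_r <- est[, 3]
  vg <- orientationToVector(out$phi_g, out$alpha_g)
  vr <- orientationToVector(out$phi_r, out$alpha_r)
  out$gamma_deg <- radToDeg(acuteAngle(vg, vr))
  out$sigma_d <- abs(out$d_r - d) / d
  out
}
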
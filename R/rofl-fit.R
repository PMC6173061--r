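#' Control parameters of the ROFL fit
#'
#' @param gridAlpha,gridD integers `>= 2`: size of the brute-force
#'   initialization grid over inclination and relative thickness. The grid
#'   nodes sit at the centers of equal bins over \eqn{[-\pi/2, \pi/2]} and
#'   \eqn{(0, }`dGridMax`\eqn{]}, avoiding the degenerate edges
#'   \eqn{\alpha = \pm 90} degrees and \eqn{d = 0}.
#' @param dGridMax upper bound of the initialization grid in \eqn{d}. Only
#'   the *initialization* is bounded; the optimizer itself leaves \eqn{d}
#'   free, and \eqn{d > 1} in the result signals that the single-fiber model
#'   does not describe the data (e.g. crossing fibers).
#' @param maxIter maximum Levenberg-Marquardt iterations.
#' @param tol step/gradient tolerance of the optimizer. The fit has 3
#'   parameters on at most a few dozen data points, so tight tolerances are
#'   cheap.
#' @param weightFloor minimum count used in the weight formula
#'   ([normalizedVariance()]).
#' @return a list of class `roflControl`.
#' @export
roflControl <- function(gridAlpha = 6L, gridD = 6L, dGridMax = 1,
                        maxIter = 200L, tol = 1e-10, weightFloor = 1) {
  stopifnot(gridAlpha >= 2L, gridD >= 2L, dGridMax > 0, maxIter >= 1L,
            tol > 0, weightFloor > 0)
  structure(list(gridAlpha = as.integer(gridAlpha), gridD = as.integer(gridD),
                 dGridMax = dGridMax, maxIter = as.integer(maxIter),
                 tol = tol, weightFloor = weightFloor),
            class = "roflControl")
}

#' Weights of the ROFL least-squares problem
#'
#' \eqn{w_{ji} = \sigma_{N,ji}^{-1}} from [normalizedVariance()], evaluated
#' at the *measured* intensities (the weights must be fixed before the
#' optimization) with the per-position transmittance estimated as twice the
#' profile mean.
#'
#' @param series a [MeasurementSeries-class].
#' @param weightFloor minimum count in the variance formula.
#' @return an \eqn{N_T \times N_P} matrix of finite positive weights.
#' @export
buildWeights <- function(series, weightFloor = 1) {
  I <- intensities(series)
  IT <- 2 * rowMeans(I)
  if (any(IT <= 0)) stop("degenerate transmittance in series")
  1 / sqrt(normalizedVariance(I, IT, gain(series), ncol(I), floor = weightFloor))
}

#' Weighted residual sum of the 3D-PLI model
#'
#' \eqn{\chi^2 = \sum_{j=0}^{N_T - 1} \sum_i \left((f_{ji} - I_{N,ji})
#' w_{ji}\right)^2}, the ROFL objective; the sum includes the planar
#' measurement \eqn{j = 0} with the same weight formula as the tilted views.
#'
#' @param phi,alpha,d model parameters (any values; the model is evaluated
#'   through the fit parameterization, which folds \eqn{d} to \eqn{|d|} as
#'   the optimizer does, so \eqn{\chi^2} is invariant under
#'   [symmetrizeOrientation()]).
#' @param series a [MeasurementSeries-class].
#' @param weights optional weight matrix; defaults to [buildWeights()].
#' @return the scalar \eqn{\chi^2 \ge 0}.
#' @export
chiSquared <- function(phi, alpha, d, series, weights = NULL) {
  if (is.null(weights)) weights <- buildWeights(series)
  acq <- acquisition(series)
  core <- .acqCore(acq)
  I <- intensities(series)
  IN <- normalizeIntensity(I, 2 * rowMeans(I))
  f <- .modelNormalized(phi, alpha, abs(d), core)
  sum(((f - IN) * weights)^2)
}

## chi^2 of all initialization grid nodes at once.
##
## With f = s2r * A - c2r * B (A = cos(2 phi_j) sin(delta_j),
## B = sin(2 phi_j) sin(delta_j)) the residual sum is quadratic in (A, B)
## per stage position; precomputing the weighted moments of the data makes
## the brute-force scan over all grid nodes a handful of matrix operations.
.gridInitCore <- function(IN, w, phi0, core, control) {
  nt <- core$nt
  al <- -pi / 2 + (seq_len(control$gridAlpha) - 0.5) * pi / control$gridAlpha
  dk <- (seq_len(control$gridD) - 0.5) / control$gridD * control$dGridMax
  ca <- cos(al)
  v <- rbind(ca * cos(phi0), ca * sin(phi0), sin(al))
  Vt <- core$RM %*% v                      # (3 nt) x nAlpha
  dim(Vt) <- c(3L, nt, length(al))
  x <- matrix(Vt[1L, , ], nt); y <- matrix(Vt[2L, , ], nt)
  r2 <- x * x + y * y
  den <- pmax(r2, 1e-300)
  c2p <- (x * x - y * y) / den
  s2p <- (2 * x * y) / den
  w2 <- w * w
  Sss <- as.vector(w2 %*% core$s2r^2)
  Scc <- as.vector(w2 %*% core$c2r^2)
  Ssc <- as.vector(w2 %*% (core$s2r * core$c2r))
  P <- as.vector((w2 * IN) %*% core$s2r)
  Q <- as.vector((w2 * IN) %*% core$c2r)
  K <- sum(w2 * IN * IN)
  best <- c(chi2 = Inf, alpha = al[1], d = dk[1])
  for (d0 in dk) {
    sind <- sin(pi / 2 * d0 * r2)
    A <- c2p * sind
    B <- s2p * sind
    chi <- colSums(A * A * Sss + B * B * Scc - 2 * A * B * Ssc -
                     2 * A * P + 2 * B * Q) + K
    m <- which.min(chi)
    if (chi[m] < best[1]) best <- c(chi[m], al[m], d0)
  }
  list(phi = phi0, alpha = best[[2]], d = best[[3]], chi2 = best[[1]], ssTot = K)
}

#' Brute-force initialization of the ROFL fit
#'
#' Scans a `gridAlpha x gridD` grid over \eqn{(\alpha, d)} at the direction
#' angle \eqn{\varphi_0} extracted from the planar profile, and returns the
#' node with minimal \eqn{\chi^2}. The tilted profiles break the
#' \eqn{\pm\alpha} degeneracy of the planar view, so the scan covers both
#' signs of the inclination.
#'
#' @inheritParams chiSquared
#' @param control a [roflControl()] list.
#' @return a list with components `phi`, `alpha`, `d` and `chi2` of the best
#'   grid node.
#' @export
gridInit <- function(series, control = roflControl(), weights = NULL) {
  if (is.null(weights)) weights <- buildWeights(series, control$weightFloor)
  acq <- acquisition(series)
  core <- .acqCore(acq)
  I <- intensities(series)
  IN <- normalizeIntensity(I, 2 * rowMeans(I))
  phi0 <- extractModalities(I[1, ], acq@rho)$direction
  g <- .gridInitCore(IN, weights, phi0, core, control)
  g[c("phi", "alpha", "d", "chi2")]
}

## The per-pixel fit on raw matrices; everything above S4 funnels into this.
## Returns c(phi, alpha, d, chi2, rsq, converged, niter).
.fitCore <- function(I, core, control) {
  IT <- 2 * rowMeans(I)
  if (any(IT <= 0)) stop("degenerate transmittance in series")
  IN <- 2 * I / IT - 1
  If <- pmax(I, control$weightFloor)
  w <- 1 / sqrt(core$gain * If / IT^2 + core$gain * If^2 / (core$np * IT^3))
  a0 <- mean(I[1L, ])
  cc <- 2 / core$np * sum(I[1L, ] * core$s2r)
  ss <- 2 / core$np * sum(I[1L, ] * core$c2r)
  phi0 <- (0.5 * atan2(-ss, cc)) %% pi
  ini <- .gridInitCore(IN, w, phi0, core, control)

  s2r <- core$s2r; c2r <- core$c2r; RM <- core$RM; nt <- core$nt
  resFun <- function(p) {
    ca <- cos(p[2L])
    v <- c(ca * cos(p[1L]), ca * sin(p[1L]), sin(p[2L]))
    Vt <- RM %*% v
    dim(Vt) <- c(3L, nt)
    x <- Vt[1L, ]; y <- Vt[2L, ]
    r2 <- x * x + y * y
    sind <- sin(pi / 2 * abs(p[3L]) * r2)
    den <- pmax(r2, 1e-300)
    A <- (x * x - y * y) / den * sind
    B <- (2 * x * y) / den * sind
    as.vector((outer(A, s2r) - outer(B, c2r) - IN) * w)
  }
  fit <- nls.lm(par = c(ini$phi, ini$alpha, ini$d), fn = resFun,
                control = nls.lm.control(maxiter = control$maxIter,
                                         ftol = control$tol,
                                         ptol = control$tol, gtol = 0))
  converged <- fit$info %in% 1:4
  if (fit$deviance <= ini$chi2 + 1e-12) {
    sym <- symmetrizeOrientation(fit$par[1L], fit$par[2L], fit$par[3L])
    chi2 <- fit$deviance
  } else {
    # optimizer never reports a point worse than its initialization
    sym <- symmetrizeOrientation(ini$phi, ini$alpha, ini$d)
    chi2 <- ini$chi2
    converged <- FALSE
  }
  c(phi = sym$phi, alpha = sym$alpha, d = sym$d, chi2 = chi2,
    rsq = 1 - chi2 / ini$ssTot, converged = as.numeric(converged),
    niter = fit$niter)
}

#' @describeIn fitPixel Robust Orientation Fitting via Least Squares for one
#'   pixel: normalizes the measured profiles per stage position, builds the
#'   \eqn{\sigma_N^{-1}} weights, locates a starting point by brute force
#'   ([gridInit()]), then runs an unbounded Levenberg-Marquardt fit over
#'   \eqn{(\varphi_u, \alpha_u, d)} whose model evaluation folds the
#'   parameters through [symmetrizeOrientation()]. The result is
#'   symmetrized back into the standard parameter space. Non-convergence
#'   returns the best point found (flagged), never an error.
#' @examples
#' acq <- pliAcquisition()
#' set.seed(1)
#' series <- simulateSeries(degToRad(101), degToRad(-60), 0.5, acq)[[1]]
#' fitPixel(series)
#' @export
setMethod("fitPixel", "MeasurementSeries", function(series, control = roflControl()) {
  acq <- acquisition(series)
  r <- .fitCore(intensities(series), .acqCore(acq), control)
  new("PixelFit", phi = r[["phi"]], alpha = r[["alpha"]], d = r[["d"]],
      chi2 = r[["chi2"]], rsq = r[["rsq"]],
      converged = r[["converged"]] > 0, niter = as.integer(r[["niter"]]))
})

#' Fit every pixel of a measurement stack
#'
#' Applies the ROFL fit to an \eqn{N_T \times N_P \times H \times W} stack
#' and returns per-pixel maps. Pixels whose planar transmittance falls below
#' `maskFraction` times the stack's robust maximum (0.99 quantile) are
#' treated as background and set to `NA`.
#'
#' The fit is deterministic, so results are bit-identical for any number of
#' workers.
#'
#' @param stack numeric 4-d array `[stage position, polarizer angle, row,
#'   column]`.
#' @param acq a [PLIAcquisition-class] matching the first two dimensions.
#' @param control a [roflControl()] list.
#' @param maskFraction background threshold as a fraction of the robust
#'   transmittance maximum; 0 disables masking.
#' @param workers number of worker processes ([parallel::mclapply()]; forked,
#'   so on Windows this falls back to a single process).
#' @return a list of `H x W` matrices: `direction` and `inclination`
#'   (radians), `thickness`, `chi2`, `rsq`, plus logical `mask` (`TRUE` =
#'   fitted foreground) and `converged`.
#' @export
fitImage <- function(stack, acq, control = roflControl(), maskFraction = 0.1,
                     workers = 1L) {
  stopifnot(length(dim(stack)) == 4L)
  d <- dim(stack)
  if (d[1] != nPositions(acq) || d[2] != nPolarizer(acq))
    stop("stack dimensions do not match the acquisition")
  h <- d[3]; wdt <- d[4]
  core <- .acqCore(acq)
  planarIT <- 2 * apply(stack[1, , , , drop = FALSE], c(3, 4), mean)
  dim(planarIT) <- c(h, wdt)
  mask <- matrix(TRUE, h, wdt)
  if (maskFraction > 0) {
    thr <- maskFraction * quantile(planarIT, 0.99, names = FALSE)
    mask <- planarIT >= thr
  }
  idx <- which(mask)
  fitOne <- function(k) {
    rc <- arrayInd(k, c(h, wdt))
    .fitCore(matrix(stack[, , rc[1], rc[2]], d[1], d[2]), core, control)
  }
  res <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(idx, fitOne, mc.cores = workers)
  } else {
    lapply(idx, fitOne)
  }
  maps <- list()
  for (nm in c("phi", "alpha", "d", "chi2", "rsq", "converged")) {
    m <- matrix(NA_real_, h, wdt)
    m[idx] <- vapply(res, `[[`, numeric(1), nm)
    maps[[nm]] <- m
  }
  nFail <- sum(maps$converged[idx] == 0)
  if (nFail > 0)
    message(sprintf("fitImage: %d of %d pixels did not converge (kept best point)",
                    nFail, length(idx)))
  list(direction = maps$phi, inclination = maps$alpha, thickness = maps$d,
       chi2 = maps$chi2, rsq = maps$rsq, mask = mask,
       converged = maps$converged > 0)
}
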
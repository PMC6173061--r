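# Independent oracles and shared fixtures for the test suite.

# Closed-form tilting rotation written out entry by entry (independent of the
# package's composed Rz Ry Rz product).
closedFormRotation <- function(psi, tau) {
  cp <- cos(psi); sp <- sin(psi); ct <- cos(tau); st <- sin(tau)
  matrix(c(
    ct * cp^2 + sp^2,      (ct - 1) * sp * cp,  cp * st,
    (ct - 1) * sp * cp,    ct * sp^2 + cp^2,    sp * st,
    -cp * st,              -sp * st,            ct
  ), nrow = 3, byrow = TRUE)
}

# Dense brute-force chi^2 minimum over (phi, alpha, d) for one series.
# Vectorized via the second-harmonic decomposition f = s2r * A - c2r * B,
# which makes chi^2 quadratic in (A, B) per stage position.
bruteForceChi2Min <- function(series, nPhi = 91, nAlpha = 46, nD = 90, dMax = 1) {
  acq <- acquisition(series)
  I <- intensities(series)
  w <- buildWeights(series)
  IN <- normalizeIntensity(I, 2 * rowMeans(I))
  nt <- nrow(I)
  s2r <- sin(2 * acq@rho); c2r <- cos(2 * acq@rho)
  RM <- do.call(rbind, lapply(seq_len(nt), function(j)
    tiltRotationMatrix(acq@tiltPsi[j], acq@tiltTau[j])))
  phis <- seq(0, pi, length.out = nPhi + 1)[-(nPhi + 1)]
  alphas <- seq(-pi / 2, pi / 2, length.out = nAlpha)
  ds <- seq(dMax / nD, dMax, length.out = nD)
  g <- expand.grid(phi = phis, alpha = alphas)
  v <- rbind(cos(g$alpha) * cos(g$phi), cos(g$alpha) * sin(g$phi), sin(g$alpha))
  Vt <- RM %*% v
  dim(Vt) <- c(3, nt, nrow(g))
  x <- matrix(Vt[1, , ], nt); y <- matrix(Vt[2, , ], nt)
  r2 <- x * x + y * y
  den <- pmax(r2, 1e-300)
  c2p <- (x * x - y * y) / den
  s2p <- (2 * x * y) / den
  w2 <- w * w
  Sss <- as.vector(w2 %*% s2r^2); Scc <- as.vector(w2 %*% c2r^2)
  Ssc <- as.vector(w2 %*% (s2r * c2r))
  P <- as.vector((w2 * IN) %*% s2r); Q <- as.vector((w2 * IN) %*% c2r)
  K <- sum(w2 * IN^2)
  best <- Inf
  for (d0 in ds) {
    sind <- sin(pi / 2 * d0 * r2)
    A <- c2p * sind; B <- s2p * sind
    chi <- colSums(A * A * Sss + B * B * Scc - 2 * A * B * Ssc -
                     2 * A * P + 2 * B * Q) + K
    best <- min(best, min(chi))
  }
  best
}

# Random valid fiber parameters, away from degenerate corners.
randomTruth <- function(n, dMin = 0.05, dMax = 1, alphaMaxDeg = 85) {
  data.frame(phi = runif(n, 0, pi),
             alpha = runif(n, -degToRad(alphaMaxDeg), degToRad(alphaMaxDeg)),
             d = runif(n, dMin, dMax))
}

# Wrap a direction-angle difference into (-pi/2, pi/2].
wrapDirection <- function(x) ((x + pi / 2) %% pi) - pi / 2
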
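test_that("degree/radian conversion round-trips", {
  expect_equal(degToRad(180), pi)
  expect_equal(radToDeg(pi / 2), 90)
  x <- runif(20, -720, 720)
  expect_equal(radToDeg(degToRad(x)), x)
})

test_that("orientationToVector matches direct trigonometry", {
  expect_equal(orientationToVector(0, 0), c(x = 1, y = 0, z = 0))
  expect_equal(orientationToVector(pi / 2, 0), c(x = 0, y = 1, z = 0))
  expect_equal(orientationToVector(0, pi / 2), c(x = 0, y = 0, z = 1))
  v <- orientationToVector(pi / 4, pi / 3)
  expect_equal(unname(v), c(0.35355339, 0.35355339, 0.86602540), tolerance = 1e-7)
  # always a unit vector
  set.seed(11)
  m <- orientationToVector(runif(100, -10, 10), runif(100, -10, 10))
  expect_equal(rowSums(m^2), rep(1, 100))
})

test_that("vectorToOrientation inverts orientationToVector up to axis sign", {
  set.seed(12)
  tr <- randomTruth(200)
  v <- orientationToVector(tr$phi, tr$alpha)
  # randomly flip half of the vectors: same axis, same orientation expected
  fl <- sample(c(-1, 1), 200, replace = TRUE)
  o <- vectorToOrientation(v * fl)
  expect_equal(o$phi, tr$phi, tolerance = 1e-12)
  expect_equal(o$alpha, tr$alpha, tolerance = 1e-12)
  expect_true(all(o$phi >= 0 & o$phi < pi))
  expect_true(all(abs(o$alpha) <= pi / 2))
})

test_that("vectorToOrientation handles poles and degenerate inputs", {
  expect_equal(vectorToOrientation(c(0, 0, 1)), list(phi = 0, alpha = pi / 2))
  expect_equal(vectorToOrientation(c(0, 0, -5)), list(phi = 0, alpha = -pi / 2))
  # near-pole vectors snap deterministically
  o <- vectorToOrientation(c(1e-12, -1e-12, 1))
  expect_equal(o$phi, 0)
  expect_equal(o$alpha, pi / 2)
  # antipode of the x axis is still phi = 0
  expect_equal(vectorToOrientation(c(-1, 0, 0)), list(phi = 0, alpha = 0))
  expect_error(vectorToOrientation(c(0, 0, 0)), "zero vector")
})

test_that("tiltRotationMatrix is a proper rotation and matches the closed form", {
  expect_equal(tiltRotationMatrix(1.2, 0), diag(3))
  set.seed(13)
  for (k in 1:50) {
    psi <- runif(1, -2 * pi, 2 * pi); tau <- runif(1, -pi / 2, pi / 2)
    R <- tiltRotationMatrix(psi, tau)
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(R, closedFormRotation(psi, tau), tolerance = 1e-12)
  }
  # psi = 0 reduces to a rotation about the y axis
  tau <- degToRad(5.51)
  expect_equal(tiltRotationMatrix(0, tau) %*% c(0, 0, 1),
               matrix(c(sin(tau), 0, cos(tau))), tolerance = 1e-12)
})

test_that("snellInternalAngle reproduces the standard tilt correction", {
  expect_equal(radToDeg(snellInternalAngle(degToRad(8), 1.45)), 5.51,
               tolerance = 0.005)
  expect_equal(snellInternalAngle(0, 1.45), 0)
  expect_equal(snellInternalAngle(degToRad(8), 1), degToRad(8))
  # always reduces the angle for n > 1
  tau <- degToRad(seq(1, 80, 7))
  expect_true(all(snellInternalAngle(tau, 1.45) < tau))
  expect_error(snellInternalAngle(pi / 2, 1.45))
})

test_that("tiltOrientation agrees with the brute-force matrix application", {
  # planar stage position leaves the orientation unchanged
  o <- tiltOrientation(degToRad(123), degToRad(-34), degToRad(90), 0)
  expect_equal(o$phi, degToRad(123))
  expect_equal(o$alpha, degToRad(-34))
  # a vertical fiber tilted by tau has inclination 90 deg - tau
  tau <- degToRad(5.51)
  o <- tiltOrientation(0, pi / 2, 0, tau)
  expect_equal(o$alpha, pi / 2 - tau, tolerance = 1e-12)
  set.seed(14)
  for (k in 1:50) {
    tr <- randomTruth(1)
    psi <- runif(1, 0, 2 * pi)
    o <- tiltOrientation(tr$phi, tr$alpha, psi, tau)
    vref <- closedFormRotation(psi, tau) %*% orientationToVector(tr$phi, tr$alpha)
    oref <- vectorToOrientation(as.vector(vref))
    expect_equal(o$phi, oref$phi, tolerance = 1e-12)
    expect_equal(o$alpha, oref$alpha, tolerance = 1e-12)
    # the inverse tilt recovers the original orientation
    back <- tiltOrientation(o$phi, o$alpha, psi, -tau)
    expect_equal(back$phi, tr$phi, tolerance = 1e-9)
    expect_equal(back$alpha, tr$alpha, tolerance = 1e-9)
  }
})

test_that("symmetrizeOrientation folds into the parameter space and is idempotent", {
  expect_equal(symmetrizeOrientation(0.3, 0.2, 0.5),
               list(phi = 0.3, alpha = 0.2, d = 0.5))
  # antipodal azimuth flips the inclination sign
  s <- symmetrizeOrientation(0.3 + pi, 0.2)
  expect_equal(s$phi, 0.3)
  expect_equal(s$alpha, -0.2)
  expect_equal(symmetrizeOrientation(1, 1, -0.7)$d, 0.7)
  set.seed(15)
  phiU <- runif(300, -20, 20); alphaU <- runif(300, -20, 20)
  dU <- runif(300, -2, 2)
  s <- symmetrizeOrientation(phiU, alphaU, dU)
  expect_true(all(s$phi >= 0 & s$phi < pi))
  expect_true(all(abs(s$alpha) <= pi / 2))
  expect_true(all(s$d >= 0))
  s2 <- symmetrizeOrientation(s$phi, s$alpha, s$d)
  expect_equal(s2$phi, s$phi, tolerance = 1e-12)
  expect_equal(s2$alpha, s$alpha, tolerance = 1e-12)
  expect_equal(s2$d, s$d)
})

test_that("symmetrizeOrientation leaves the signed model value unchanged", {
  acq <- pliAcquisition()
  set.seed(16)
  for (k in 1:40) {
    phiU <- runif(1, -10, 10); alphaU <- runif(1, -10, 10); dU <- runif(1, -1.5, 1.5)
    s <- symmetrizeOrientation(phiU, alphaU, dU)
    expect_equal(normalizedModel(phiU, alphaU, dU, acq),
                 sign(dU) * normalizedModel(s$phi, s$alpha, s$d, acq),
                 tolerance = 1e-12)
  }
})

test_that("acuteAngle is an axis metric", {
  expect_equal(radToDeg(acuteAngle(c(1, 0, 0), c(0, 1, 0))), 90)
  expect_equal(acuteAngle(c(1, 0, 0), c(-1, 0, 0)), 0)
  expect_equal(acuteAngle(c(1, 0, 0), c(1, 0, 0)), 0)
  set.seed(17)
  v1 <- orientationToVector(runif(50, 0, pi), runif(50, -pi / 2, pi / 2))
  v2 <- orientationToVector(runif(50, 0, pi), runif(50, -pi / 2, pi / 2))
  g <- acuteAngle(v1, v2)
  expect_true(all(g >= 0 & g <= pi / 2 + 1e-12))
  expect_equal(acuteAngle(v2, v1), g)              # symmetric
  expect_equal(acuteAngle(-v1, v2), g)             # sign-invariant
  # no NaN from rounding: collinear vectors with norm slightly above 1
  expect_equal(acuteAngle(c(1, 0, 0) * (1 + 1e-15), c(1, 0, 0)), 0)
})
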
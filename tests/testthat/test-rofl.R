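acq <- pliAcquisition()

test_that("buildWeights matches the variance formula and the hand value", {
  # homogeneous counts at 1250 with transmittance 2500: w = 1/sqrt(6.16667e-4)
  I <- matrix(1250, 5, 18)
  s <- measurementSeries(I, acq)
  w <- buildWeights(s)
  expect_equal(dim(w), c(5L, 18L))
  expect_equal(unname(w[1, 1]), 40.2694, tolerance = 1e-4)
  expect_true(all(w == w[1, 1]))
  # consistency with normalizedVariance on an inhomogeneous series
  set.seed(51)
  s2 <- simulateSeries(degToRad(10), degToRad(20), 0.8, acq)[[1]]
  I2 <- intensities(s2)
  ref <- 1 / sqrt(normalizedVariance(I2, 2 * rowMeans(I2), 3, 18))
  expect_equal(buildWeights(s2), ref)
  expect_true(all(is.finite(buildWeights(s2))))
})

test_that("chiSquared is zero at the truth of noise-free data", {
  set.seed(52)
  for (k in 1:10) {
    tr <- randomTruth(1)
    I <- intensityProfile(tr$phi, tr$alpha, tr$d, acq)
    s <- measurementSeries(I, acq)
    expect_lt(chiSquared(tr$phi, tr$alpha, tr$d, s), 1e-18)
    # and positive away from it
    expect_gt(chiSquared(tr$phi + 0.3, tr$alpha, tr$d + 0.05, s), 1)
  }
})

test_that("chiSquared is invariant under symmetrizeOrientation", {
  set.seed(53)
  s <- simulateSeries(degToRad(80), degToRad(40), 0.6, acq)[[1]]
  w <- buildWeights(s)
  for (k in 1:50) {
    phiU <- runif(1, -10, 10); alphaU <- runif(1, -10, 10); dU <- runif(1, -1.5, 1.5)
    sym <- symmetrizeOrientation(phiU, alphaU, dU)
    expect_equal(chiSquared(phiU, alphaU, dU, s, w),
                 chiSquared(sym$phi, sym$alpha, sym$d, s, w),
                 tolerance = 1e-10)
  }
})

test_that("gridInit returns the best node and exact grid-node truths", {
  ctrl <- roflControl()
  # ground truth placed exactly on a grid node: alpha = -45 deg, d = 0.75
  # (bin centers of the default 6 x 6 grid), phi irrelevant for node choice
  I <- intensityProfile(degToRad(45), degToRad(-45), 0.75, acq)
  s <- measurementSeries(I, acq)
  g <- gridInit(s, ctrl)
  expect_equal(radToDeg(g$alpha), -45)
  expect_equal(g$d, 0.75)
  expect_equal(g$phi, degToRad(45), tolerance = 1e-9)
  expect_lt(g$chi2, 1e-12)
  # the reported chi2 matches chiSquared and is minimal over all 36 nodes
  set.seed(54)
  s2 <- simulateSeries(degToRad(100), degToRad(55), 0.4, acq)[[1]]
  w <- buildWeights(s2)
  g2 <- gridInit(s2, ctrl, w)
  expect_equal(g2$chi2, chiSquared(g2$phi, g2$alpha, g2$d, s2, w),
               tolerance = 1e-8)
  alphas <- degToRad(seq(-75, 75, by = 30))
  ds <- (seq_len(6) - 0.5) / 6
  for (a in alphas) for (d0 in ds)
    expect_gte(chiSquared(g2$phi, a, d0, s2, w), g2$chi2 - 1e-8)
})

test_that("grid initialization resolves the inclination sign", {
  set.seed(55)
  for (k in 1:40) {
    alpha <- sample(c(-1, 1), 1) * runif(1, degToRad(20), degToRad(75))
    tr <- randomTruth(1, dMin = 0.3)
    I <- intensityProfile(tr$phi, alpha, tr$d, acq)
    g <- gridInit(measurementSeries(I, acq))
    expect_equal(sign(g$alpha), sign(alpha))
  }
})

test_that("fitPixel recovers noise-free parameters to 1e-6", {
  ctrl <- roflControl()
  check <- function(phi, alpha, d) {
    I <- intensityProfile(phi, alpha, d, acq)
    f <- fitPixel(measurementSeries(I, acq), ctrl)
    p <- fitParams(f)
    expect_lt(abs(wrapDirection(p[["phi"]] - (phi %% pi))) * cos(alpha), 1e-6)
    expect_lt(abs(p[["alpha"]] - alpha), 1e-6)
    expect_lt(abs(p[["d"]] - d), 1e-6)
    expect_lt(p[["chi2"]], 1e-8)
    expect_true(f@converged)
  }
  check(degToRad(45), degToRad(30), 0.5)
  check(degToRad(170), 0, 0.8)               # in-plane fiber
  check(degToRad(10), degToRad(-70), 0.95)   # steep negative inclination
  check(degToRad(90), degToRad(5), 0.05)     # weak signal
  set.seed(56)
  tr <- randomTruth(30, dMin = 0.05, dMax = 1, alphaMaxDeg = 85)
  for (k in seq_len(30)) check(tr$phi[k], tr$alpha[k], tr$d[k])
})

test_that("fit result never has higher chi2 than its initialization", {
  set.seed(57)
  ctrl <- roflControl()
  for (k in 1:30) {
    tr <- randomTruth(1, dMin = 0.1)
    s <- simulateSeries(tr$phi, tr$alpha, tr$d, acq)[[1]]
    ini <- gridInit(s, ctrl)
    f <- fitPixel(s, ctrl)
    expect_lte(f@chi2, ini$chi2 + 1e-9)
    # and the reported chi2 is reproducible from the reported parameters
    expect_equal(f@chi2, chiSquared(f@phi, f@alpha, f@d, s), tolerance = 1e-7)
  }
})

test_that("fit attains the dense brute-force chi2 minimum on noisy pixels", {
  # oracle: exhaustive scan over 91 x 46 x 90 parameter combinations
  set.seed(58)
  ctrl <- roflControl()
  for (k in 1:20) {
    tr <- randomTruth(1, dMin = 0.1, dMax = 0.95, alphaMaxDeg = 80)
    s <- simulateSeries(tr$phi, tr$alpha, tr$d, acq)[[1]]
    f <- fitPixel(s, ctrl)
    expect_lte(f@chi2, bruteForceChi2Min(s) + 1e-6)
  }
})

test_that("noisy single-pixel fit at standard signal level has R^2 above 0.9", {
  set.seed(59)
  s <- simulateSeries(degToRad(101), degToRad(-60), 0.5, acq, n = 20)
  rsqs <- vapply(s, function(x) fitParams(fitPixel(x))[["rsq"]], numeric(1))
  expect_true(all(rsqs > 0.9))
})

test_that("fitted parameters always lie in the standard parameter space", {
  set.seed(60)
  for (k in 1:20) {
    tr <- randomTruth(1, dMin = 0.05)
    f <- fitPixel(simulateSeries(tr$phi, tr$alpha, tr$d, acq)[[1]])
    expect_true(f@phi >= 0 && f@phi < pi)
    expect_true(abs(f@alpha) <= pi / 2)
    expect_gte(f@d, 0)
    expect_gte(f@chi2, 0)
  }
})

test_that("dust corruption shows up as a chi2 outlier without derailing the fit", {
  set.seed(61)
  clean <- simulateSeries(degToRad(45), degToRad(20), 0.7, acq, n = 50)
  chiClean <- vapply(clean, function(x) fitPixel(x)@chi2, numeric(1))
  s <- clean[[1]]
  I <- intensities(s)
  I[1, 7] <- I[1, 7] * 4      # a dust grain crossing one polarizer frame
  fDirty <- fitPixel(measurementSeries(I, acq))
  expect_gt(fDirty@chi2, 5 * median(chiClean))
  # the weighted fit still lands near the truth
  err <- evaluateFit(list(phi = degToRad(45), alpha = degToRad(20), d = 0.7), fDirty)
  expect_lt(err[["gamma_deg"]], 10)
  expect_lt(err[["sigma_d"]], 0.3)
})

test_that("fitImage reproduces per-pixel fits, masks background, parallelizes", {
  set.seed(62)
  ph <- generatePhantom(
    list(list(rows = 1:3, cols = 1:6, phi = degToRad(30), alpha = degToRad(10), d = 0.8),
         list(rows = 4:6, cols = 1:6, phi = degToRad(120), alpha = degToRad(65), d = 0.6)),
    height = 8, width = 6, acq = acq, seed = 63)
  maps <- fitImage(ph$stack, acq, workers = 1L)
  # rows 7:8 are background (40% transmittance < 10% threshold is FALSE here,
  # so instead verify the mask explicitly with a stronger threshold)
  expect_true(all(maps$mask[1:6, ]))
  # per-pixel agreement with fitPixel
  f11 <- fitPixel(measurementSeries(matrix(ph$stack[, , 1, 1], 5, 18), acq))
  expect_equal(maps$direction[1, 1], f11@phi)
  expect_equal(maps$inclination[1, 1], f11@alpha)
  expect_equal(maps$thickness[1, 1], f11@d)
  # identical results with 4 workers
  maps4 <- fitImage(ph$stack, acq, workers = 4L)
  expect_identical(maps$direction, maps4$direction)
  expect_identical(maps$inclination, maps4$inclination)
  expect_identical(maps$thickness, maps4$thickness)
  # strong masking removes the dim background
  mapsM <- fitImage(ph$stack, acq, maskFraction = 0.6)
  expect_true(all(!mapsM$mask[7:8, ]))
  expect_true(all(is.na(mapsM$direction[7:8, ])))
  expect_true(all(mapsM$mask[1:6, ]))
  # dimension mismatch errors
  expect_error(fitImage(ph$stack[, 1:10, , ], acq), "do not match")
})
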
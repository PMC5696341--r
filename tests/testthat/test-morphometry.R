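rectLabels <- function(nr, nc, r0, r1, c0, c1) {
  m <- matrix(0L, nr, nc)
  m[r0:r1, c0:c1] <- 1L
  new("CellLabelMap", labels = m, pixelSize = NA_real_)
}

test_that("axis-aligned rectangles give exact elongation and orientation", {
  lm <- rectLabels(20, 50, 6, 15, 6, 45)      # 10 px tall, 40 px wide
  sh <- cellShapeMetrics(lm, flowAxis = c(1, 0))
  expect_equal(sh$length_along_flow, 40)
  expect_equal(sh$width, 10)
  expect_equal(sh$elongation_factor, 4)
  expect_equal(sh$orientation_deg, 0, tolerance = 1e-9)
  # flow along +y: the same cell is now perpendicular
  shY <- cellShapeMetrics(lm, flowAxis = c(0, 1))
  expect_equal(shY$elongation_factor, 0.25)
  expect_equal(shY$orientation_deg, 90, tolerance = 1e-9)
})

test_that("border-touching cells are excluded with a message", {
  m <- matrix(0L, 12, 12)
  m[1:4, 3:6] <- 1L          # touches the top border
  m[7:10, 3:8] <- 2L
  lm <- new("CellLabelMap", labels = m, pixelSize = NA_real_)
  expect_message(sh <- cellShapeMetrics(lm), "1 border-touching")
  expect_identical(nrow(sh), 1L)
  expect_identical(sh$cell_id, 2L)
})

test_that("rendered ellipses recover orientation within 2 deg and elongation within 5%", {
  ml <- synthMonolayer(9, elongationMean = 4, elongationSd = 0,
                       orientationMean = 30, orientationSd = 0,
                       cellArea = 900, seed = 6)
  sh <- cellShapeMetrics(ml$labels)
  sh <- merge(sh, ml$shapes, by = "cell_id")
  expect_true(all(abs(sh$orientation_deg.x - 30) <= 2))
  expect_true(all(abs(sh$elongation_factor / sh$elongation_extent - 1) <= 0.05))
})

test_that("elongation is equivariant under a 90-degree rotation of cell and axis", {
  ml <- synthMonolayer(4, elongationMean = 3, orientationMean = 20,
                       cellArea = 700, seed = 9)
  sh <- cellShapeMetrics(ml$labels, flowAxis = c(1, 0))
  lab90 <- new("CellLabelMap", labels = t(labelMatrix(ml$labels)),
               pixelSize = NA_real_)   # transpose swaps x and y
  sh90 <- cellShapeMetrics(lab90, flowAxis = c(0, 1))
  expect_equal(sh90$elongation_factor, sh$elongation_factor, tolerance = 1e-9)
})

test_that("junction coverage tracks the rendered gap fraction and sums to 100", {
  ml0 <- synthMonolayer(6, gapFraction = 0, cellArea = 500, seed = 3)
  cov0 <- junctionCoverage(ml0$junction, ml0$borderMask)
  expect_lt(cov0$pctUncovered, 2)
  ml1 <- synthMonolayer(6, gapFraction = 0.1, cellArea = 500, seed = 3)
  cov1 <- junctionCoverage(ml1$junction, ml1$borderMask)
  expect_lt(abs(cov1$pctUncovered - 10), 2)
  expect_identical(cov1$pctCovered + cov1$pctUncovered, 100)
  expect_error(junctionCoverage(matrix(5, 8, 8), matrix(TRUE, 8, 8)),
               "degenerate histogram")
})

mkProfile <- function(position, intensity, cellId = 1L) {
  new("PolarizationProfile", cellId = cellId, position = position,
      intensity = intensity, timeMin = NA_real_)
}

test_that("polarization index: uniform 0.5, one-sided 1.0, known ratio 0.75", {
  p <- seq(-1, 1, by = 0.05)
  expect_equal(polarizationIndex(mkProfile(p, rep(3, length(p)))), 0.5)
  oneSided <- ifelse(p > 0, 2, 0)
  oneSided[p == 0] <- 0
  expect_equal(polarizationIndex(mkProfile(p, oneSided)), 1.0)
  # downstream area 3x the upstream area
  y <- ifelse(p >= 0, 3, 1)
  y[p == 0] <- 3
  idx <- polarizationIndex(mkProfile(p, y))
  expect_equal(idx, 0.75, tolerance = 0.02)
  expect_error(polarizationIndex(mkProfile(p, rep(0, length(p)))),
               "all-zero")
})

test_that("mirroring a profile complements its polarization index", {
  set.seed(12)
  p <- seq(-1, 1, by = 0.04)
  y <- runif(length(p), 0, 5)
  prof <- mkProfile(p, y)
  mirrored <- mkProfile(rev(-p), rev(y))
  expect_equal(polarizationIndex(mirrored), 1 - polarizationIndex(prof),
               tolerance = 1e-12)
})

test_that("intensity profiles integrate the image along the perpendicular axis", {
  # symmetric (elliptical) cell, uniform intensity -> symmetric profile
  mask <- matrix(FALSE, 21, 41)
  for (cc in 2:40) {
    half <- floor(9 * sqrt(pmax(1 - ((cc - 21) / 20)^2, 0)))
    if (half >= 1) mask[(11 - half):(11 + half), cc] <- TRUE
  }
  mask[, c(1, 41)] <- FALSE
  img <- matrix(0, 21, 41)
  img[mask] <- 2
  prof <- intensityProfile(mask, img, nucleusCentroid = c(21, 11))
  expect_equal(polarizationIndex(prof), 0.5, tolerance = 0.05)
  expect_equal(range(prof@position), c(-1, 1))
  # rectangular cell: column sums are proportional to the painted profile
  maskR <- matrix(FALSE, 21, 41)
  maskR[6:16, 6:36] <- TRUE
  # all signal strictly downstream of the nucleus
  imgD <- matrix(0, 21, 41)
  imgD[6:16, 26:36] <- 5
  profD <- intensityProfile(maskR, imgD, nucleusCentroid = c(21, 11))
  expect_gt(polarizationIndex(profD), 0.95)
  # painted two-sided linear gradient reproduces after normalization
  imgG <- matrix(0, 21, 41)
  for (cc in 6:36) imgG[6:16, cc] <- abs(cc - 21)
  profG <- intensityProfile(maskR, imgG, nucleusCentroid = c(21, 11))
  keep <- abs(profG@position) > 0.1
  expect_gt(cor(profG@intensity[keep], abs(profG@position[keep])), 0.98)
  # border-clipped cells are rejected
  maskB <- matrix(FALSE, 21, 41)
  maskB[1:16, 6:36] <- TRUE
  expect_error(intensityProfile(maskB, img, c(21, 8)), "border")
})

test_that("repolarization fits recover the characteristic time", {
  tp <- c(0, 5, 10, 20, 30, 45, 60, 90, 120)
  d <- 0.75 - (0.75 - 0.25) * exp(-tp / 30)
  fit <- fitRepolarization(tp, d)
  expect_equal(fit$tau, 30, tolerance = 1e-6)
  expect_equal(fit$d0, 0.25, tolerance = 1e-6)
  expect_equal(fit$dInf, 0.75, tolerance = 1e-6)
  expect_error(fitRepolarization(tp, rep(0.5, length(tp))), "no relaxation")
  # 5% noise, 10 timepoints, 100 seeded repeats: tau within 10% of truth
  set.seed(17)
  taus <- replicate(100, {
    s <- synthPolarSeries(tauMin = 30, nCells = 120, noiseSd = 0.05,
                          seed = sample.int(1e6, 1))
    fitRepolarization(s$meanSeries$time_min,
                      s$meanSeries$downstream_fraction)$tau
  })
  expect_true(all(abs(taus / 30 - 1) < 0.1))
})

test_that("polarization series generator honours its own kinetics", {
  s0 <- synthPolarSeries(tauMin = 30, noiseSd = 0, nCells = 5, seed = 1)
  m <- s0$meanSeries
  expect_equal(m$downstream_fraction[m$time_min == 0], 0.25)
  expect_equal(m$downstream_fraction[m$time_min == 120],
               0.75 - 0.5 * exp(-4), tolerance = 1e-9)
  fit <- fitRepolarization(m$time_min, m$downstream_fraction)
  expect_equal(fit$tau, 30, tolerance = 1e-6)
})

test_that("organelle polarity classification respects the deadband", {
  expect_identical(classifyGolgiPolarity(c(0, 0), c(5, 0)), "downstream")
  expect_identical(classifyGolgiPolarity(c(0, 0), c(-5, 0)), "upstream")
  expect_identical(classifyGolgiPolarity(c(0, 0), c(0, 0)), "unpolarized")
  # exactly at the deadband: closed interval, unpolarized
  expect_identical(classifyGolgiPolarity(c(0, 0), c(1, 0), deadband = 1),
                   "unpolarized")
  # perpendicular displacement never polarizes
  expect_identical(classifyGolgiPolarity(c(0, 0), c(0, 30)), "unpolarized")
})

test_that("nuclear-positive percentages count strict exceedances", {
  expect_equal(nuclearPositiveFraction(c(10, 20, 30), 15), 200 / 3)
  expect_equal(nuclearPositiveFraction(c(1, 2, 3), 10), 0)
  set.seed(4)
  v <- runif(200, 0, 100)
  expect_equal(nuclearPositiveFraction(v, 40), 100 * sum(v > 40) / 200)
  expect_error(nuclearPositiveFraction(numeric(0), 1), "no cells")
})

test_that("shear-response fit recovers an exact logarithmic law", {
  tau <- c(2, 4, 8, 12, 16, 20, 26, 30, 34)
  pct <- 20 * log(tau) + 5
  fit <- shearResponseCurve(tau, pct)
  expect_equal(fit$slope, 20, tolerance = 1e-9)
  expect_equal(fit$intercept, 5, tolerance = 1e-9)
  expect_equal(fit$r2, 1)
  # flat response: slope ~ 0, plateau reported
  flat <- shearResponseCurve(tau, rep(50, 9))
  expect_equal(flat$slope, 0, tolerance = 1e-9)
  expect_equal(flat$plateauLevel, 50)
  expect_error(shearResponseCurve(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_error(shearResponseCurve(c(-1, 2, 3), c(1, 2, 3)), "positive")
})
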
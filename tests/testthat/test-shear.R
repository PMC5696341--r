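randField <- function(nr = 6, nc = 5, seed = 1, units = "m/s") {
  set.seed(seed)
  velocityField(matrix(rnorm(nr * nc), nr), matrix(rnorm(nr * nc), nr),
                matrix(rnorm(nr * nc), nr), b = 0.05, h = 0.04, units = units)
}

test_that("baseline subtraction removes static offsets componentwise", {
  f <- randField(seed = 2)
  zero <- subtractBaseline(f, f)
  expect_equal(zero@vx, matrix(0, 6, 5))
  expect_equal(zero@vy, matrix(0, 6, 5))
  off <- velocityField(f@vx * 0 + 0.3, f@vx * 0 - 0.1, f@vx * 0 + 0.05,
                       b = f@b, h = f@h)
  g <- randField(seed = 3)
  gOff <- velocityField(g@vx + 0.3, g@vy - 0.1, g@vz + 0.05, b = g@b, h = g@h)
  corr <- subtractBaseline(gOff, off)
  expect_equal(corr@vx, g@vx)
  expect_equal(corr@vy, g@vy)
  expect_equal(corr@vz, g@vz)
  bad <- randField(nr = 4)
  expect_error(subtractBaseline(f, bad), "shapes")
})

rotatedCopy <- function(f) {
  flip <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  velocityField(flip(f@vx), -flip(f@vy), -flip(f@vz), b = f@b, h = f@h,
                units = f@units)
}

test_that("rotation averaging is consistent and cancels antisymmetric bias", {
  f <- randField(seed = 4)
  # a perfectly consistent rotated acquisition reproduces the original
  avg <- averageRotations(f, rotatedCopy(f))
  expect_equal(avg@vx, f@vx)
  expect_equal(avg@vy, f@vy)
  expect_equal(avg@vz, f@vz)
  # instrument bias +b0 in vy enters both acquisitions identically and
  # cancels exactly after re-registration
  b0 <- 0.2
  acq0 <- velocityField(f@vx, f@vy + b0, f@vz, b = f@b, h = f@h)
  r <- rotatedCopy(f)
  acq180 <- velocityField(r@vx, r@vy + b0, r@vz, b = f@b, h = f@h)
  avg2 <- averageRotations(acq0, acq180)
  expect_equal(avg2@vy, f@vy)
  expect_equal(avg2@vx, f@vx)
  # transform-then-mean oracle on a random pair
  g <- randField(seed = 5)
  got <- averageRotations(f, g)
  flip <- function(m) m[rev(seq_len(nrow(m))), ]
  expect_equal(got@vx, (f@vx + flip(g@vx)) / 2)
  expect_equal(got@vy, (f@vy - flip(g@vy)) / 2)
})

test_that("speed map is the per-voxel Euclidean norm with unit conversion", {
  vx <- matrix(3, 2, 2); vy <- matrix(4, 2, 2)
  f <- velocityField(vx, vy, b = 0.05, h = 0.04, units = "cm/s")
  expect_equal(speedMap(f), matrix(5, 2, 2))
  fm <- velocityField(vx, vy, b = 0.05, h = 0.04, units = "m/s")
  expect_equal(speedMap(fm), matrix(500, 2, 2))
  z <- velocityField(matrix(0, 3, 3), matrix(0, 3, 3), b = 1, h = 1)
  expect_equal(speedMap(z), matrix(0, 3, 3))
  r <- randField(seed = 6)
  expect_equal(speedMap(r), sqrt(r@vx^2 + r@vy^2 + r@vz^2) * 100)
})

test_that("wall shear follows the parallel-plate formula", {
  # unit inputs: mu = 1, Q = 1 through a 1 x 1 voxel -> tau = 6
  sm <- shearFromSpeed(matrix(1, 1, 1), mu = 1, b = 1, h = 1)
  expect_equal(shearValues(sm), matrix(6, 1, 1))
  # worked numbers: mu 0.0078, mean speed 17.1 cm/s, h 0.04 cm -> 20.0
  sm2 <- shearFromSpeed(matrix(17.1, 1, 1), mu = 0.0078, b = 0.05, h = 0.04)
  expect_equal(shearValues(sm2)[1, 1], 20.0, tolerance = 1e-3)
  # linearity in mu and speed; halving h doubles tau
  s <- matrix(2.5, 2, 2)
  t1 <- shearValues(shearFromSpeed(s, mu = 0.0078, b = 0.05, h = 0.04))
  expect_equal(shearValues(shearFromSpeed(s, mu = 0.0156, b = 0.05, h = 0.04)),
               2 * t1)
  expect_equal(shearValues(shearFromSpeed(2 * s, mu = 0.0078, b = 0.05,
                                          h = 0.04)), 2 * t1)
  expect_equal(shearValues(shearFromSpeed(s, mu = 0.0078, b = 0.05, h = 0.02)),
               2 * t1)
  # parabolic-profile option: measured speed read as the mid-plane peak
  tp <- shearValues(shearFromSpeed(s, mu = 0.0078, b = 0.05, h = 0.04,
                                   profile = "parabolic"))
  expect_equal(tp, t1 / 1.5)
  expect_error(shearFromSpeed(s, mu = 0, b = 1, h = 1), "> 0")
})

test_that("synthetic parallel-plate fields match their analytic shear exactly", {
  sv <- synthVelocityField(Q = 0.15, b = 0.5, h = 0.04, grid = c(16, 12))
  expect_equal(sv$tauTruth, 8.775)
  sm <- shearMap(sv$field, mu = 0.0078)
  inner <- sv$field@mask
  expect_identical(shearValues(sm)[inner], sv$analyticShear@tau[inner])
  expect_equal(max(abs(shearValues(sm)[inner] - sv$tauTruth)), 0, tolerance = 1e-12)
  # doubling the viscosity doubles the analytic truth
  sv2 <- synthVelocityField(Q = 0.15, b = 0.5, h = 0.04, mu = 0.0156)
  expect_equal(sv2$tauTruth, 2 * 8.775)
  expect_error(synthVelocityField(Q = 1, b = -1, h = 1), "> 0")
})

test_that("processing order commutes for the linear corrections", {
  f <- randField(seed = 7)
  base <- randField(seed = 8)
  r <- randField(seed = 9)
  a1 <- averageRotations(subtractBaseline(f, base), rotatedCopy(subtractBaseline(r, base)))
  # subtracting the baseline after rotation-averaging, with the baseline
  # averaged the same way, gives the same result
  avgBase <- base
  a2raw <- averageRotations(f, rotatedCopy(r))
  a2 <- subtractBaseline(a2raw, avgBase)
  expect_equal(a1@vx, a2@vx)
  expect_equal(a1@vy, a2@vy)
})

test_that("ROI means average valid voxels only", {
  tau <- matrix(26, 4, 4)
  sm <- new("ShearMap", tau = tau, mu = 0.0078, mask = matrix(TRUE, 4, 4))
  expect_equal(roiMeanShear(sm, matrix(TRUE, 4, 4)), 26)
  tau2 <- tau; tau2[1:2, ] <- 10
  sm2 <- new("ShearMap", tau = tau2, mu = 0.0078, mask = matrix(TRUE, 4, 4))
  expect_equal(roiMeanShear(sm2, matrix(TRUE, 4, 4)), 18)
  set.seed(11)
  tau3 <- matrix(runif(16, 5, 30), 4)
  roi <- matrix(runif(16) < 0.5, 4)
  sm3 <- new("ShearMap", tau = tau3, mu = 0.0078, mask = matrix(TRUE, 4, 4))
  expect_equal(roiMeanShear(sm3, roi), mean(tau3[roi]))
  expect_error(roiMeanShear(sm3, matrix(FALSE, 4, 4)), "empty ROI")
  expect_error(roiMeanShear(sm3, matrix(TRUE, 2, 2)), "mismatch")
})

test_that("velocity grids round-trip through CSV with sidecar", {
  f <- randField(seed = 10)
  pref <- file.path(tempdir(), "vel")
  writeVelocityGrid(f, pref)
  g <- readVelocityGrid(pref)
  expect_equal(g@vx, f@vx)
  expect_equal(g@vy, f@vy)
  expect_equal(g@vz, f@vz)
  expect_identical(g@units, f@units)
  expect_equal(g@b, f@b)
})
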
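trendOf <- function(co, t) {
  co[["c0"]] + co[["c1"]] * t + co[["c2"]] * t^2 +
    co[["amp"]] * exp(t / co[["tau"]])
}

test_that("asymmetric loss matches its closed form and asymmetry ratio", {
  expect_identical(asymmetricLoss(0, 0.8), 0)
  expect_equal(asymmetricLoss(1, 0.8), 1.8^4)      # 10.4976
  expect_equal(asymmetricLoss(-1, 0.8), 0.2^4)     # 0.0016
  expect_error(asymmetricLoss(1, 0), "alpha")
  # L(+r)/L(-r) = ((1+a)/(1-a))^4 for all r != 0, 0 < a < 1
  for (a in c(0.2, 0.5, 0.8)) for (r in c(0.1, 1, 13)) {
    expect_equal(asymmetricLoss(r, a) / asymmetricLoss(-r, a),
                 ((1 + a) / (1 - a))^4)
  }
})

test_that("noiseless polynomial+exponential trends are recovered to <1% RMSE", {
  t <- 0:599
  cos <- list(
    c(c0 = 120, c1 = -0.01, c2 = -2e-6, amp = 15, tau = -150),
    c(c0 = 80, c1 = -0.002, c2 = 1e-6, amp = 5, tau = -400),
    c(c0 = 200, c1 = 0, c2 = 0, amp = 30, tau = -100))
  for (co in cos) {
    f <- trendOf(co, t)
    tr <- cellTrace(1, t, f, "flow")
    m <- fitBleachModel(tr)
    rmse <- sqrt(mean((predictTrend(m, t) - f)^2))
    expect_lt(rmse, 0.01 * diff(range(f)))
    expect_true(m@converged)
    expect_lte(m@c1, 0)
    expect_lt(m@tau, 0)
  }
})

test_that("a constant trace yields an essentially constant trend", {
  tr <- cellTrace(1, 0:199, rep(100, 200), "flow")
  m <- fitBleachModel(tr)
  trend <- predictTrend(m, 0:199)
  expect_lt(diff(range(trend)), 1e-4)
  expect_lt(abs(m@c1), 1e-6)
  expect_lt(abs(m@c2), 1e-6)
})

test_that("the asymmetric fit rides below upward spikes, a symmetric fit does not", {
  set.seed(21)
  t <- 0:599
  base <- 120 - 0.01 * t
  f <- base + rnorm(600, 0, 0.3)
  spikeIdx <- unlist(lapply(c(60, 170, 300, 430), function(o) o:(o + 39)))
  f[spikeIdx] <- f[spikeIdx] + 8
  tr <- cellTrace(1, t, f, "flow")
  mAsym <- fitBleachModel(tr, alpha = 0.8)
  # symmetric surrogate: same driver, residuals unweighted
  sym <- minpack.lm::nls.lm(
    par = c(c0 = median(f), c1 = -1e-9, c2 = 0, amp = 0, tau = -200),
    lower = c(-Inf, -Inf, -Inf, -Inf, -Inf), upper = c(Inf, 0, Inf, Inf, -1e-6),
    fn = function(p, t, f)
      p[["c0"]] + p[["c1"]] * t + p[["c2"]] * t^2 +
      p[["amp"]] * exp(t / p[["tau"]]) - f,
    t = t, f = f)
  symTrend <- trendOf(as.list(sym$par) |> unlist(), t)
  asymTrend <- predictTrend(mAsym, t)
  # spike samples lie above the asymmetric trend (measured - trend > 0)
  expect_gt(mean(f[spikeIdx] - asymTrend[spikeIdx]), 0)
  # baseline bias: asymmetric trend tracks the true baseline better
  baseIdx <- setdiff(seq_along(t), spikeIdx)
  expect_lt(abs(mean(asymTrend[baseIdx] - base[baseIdx])),
            abs(mean(symTrend[baseIdx] - base[baseIdx])))
})

test_that("fit is equivariant under additive offsets", {
  set.seed(4)
  t <- 0:299
  f <- 100 - 0.02 * t + 10 * exp(-t / 120) + rnorm(300, 0, 0.5)
  m0 <- fitBleachModel(cellTrace(1, t, f, "flow"))
  m1 <- fitBleachModel(cellTrace(1, t, f + 50, "flow"))
  expect_equal(predictTrend(m1, t), predictTrend(m0, t) + 50,
               tolerance = 1e-6)
})

test_that("increasing alpha (within (0,1]) pushes the trend toward a lower envelope", {
  # the over/under penalty ratio ((1+a)/(1-a))^4 grows without bound as a -> 1,
  # so on spiked data the mean signed residual (measured - trend) must grow
  # with alpha over (0, 1); beyond 1 the ratio declines again
  set.seed(33)
  t <- 0:399
  f <- 110 - 0.005 * t + rnorm(400, 0, 0.4)
  f[100:180] <- f[100:180] + 6
  tr <- cellTrace(1, t, f, "flow")
  msr <- vapply(c(0.2, 0.5, 0.8, 0.95), function(a) {
    m <- suppressWarnings(fitBleachModel(tr, alpha = a))
    mean(f - predictTrend(m, t))   # mean signed residual, measured - trend
  }, numeric(1))
  expect_true(all(diff(msr) > 0))
})

test_that("alpha selection honours ties and improves baseline fidelity", {
  tr <- cellTrace(1, 0:199, 100 - 0.01 * (0:199), "flow")
  expect_equal(selectAlpha(tr, alphaGrid = c(0.8)), 0.8)
  # spike-free trace: criterion is flat; tie rule returns 0.8
  expect_equal(selectAlpha(tr), 0.8)
  # heavily spiked trace: the selected alpha beats the smallest grid value
  set.seed(5)
  t <- 0:599
  f <- 120 - 0.008 * t + rnorm(600, 0, 0.3)
  for (o in c(50, 150, 260, 380, 480)) f[o:(o + 49)] <- f[o:(o + 49)] + 7
  trs <- cellTrace(1, t, f, "flow")
  aSel <- selectAlpha(trs)
  crit <- function(a) {
    m <- fitBleachModel(trs, alpha = a)
    sub <- f <= median(f)
    abs(median((f - predictTrend(m, t))[sub]))
  }
  expect_lte(crit(aSel), crit(0.2) + 1e-9)
})

test_that("detrending subtracts the trend and re-anchors at the last flow value", {
  # pure-trend trace: correction flattens it at trend(t_last)
  t <- 0:299
  f <- 150 - 0.05 * t + 20 * exp(-t / 80)
  tr <- cellTrace(1, t, f, "flow")
  m <- fitBleachModel(tr)
  corr <- detrendTrace(tr, m)
  expect_equal(traceValues(corr), rep(traceValues(corr)[300], 300),
               tolerance = 1e-3)
  expect_equal(traceValues(corr)[300], f[300], tolerance = 0.2)
  # constant trend: output equals input
  tr2 <- cellTrace(1, t, rep(100, 300), "flow")
  m2 <- fitBleachModel(tr2)
  expect_equal(traceValues(detrendTrace(tr2, m2)), rep(100, 300),
               tolerance = 1e-4)
})

test_that("additive-bleach spiked traces detrend to a flat baseline with preserved amplitudes", {
  truth <- traceGroundTruth(baselineCa = 125,
                            spikeOnsets = c(100, 300, 450),
                            spikeDurations = c(10, 8, 12),
                            spikeAmplitudes = c(8, 6, 10),
                            noiseSd = 0, seed = 1)
  tr <- synthTrace(truth, bleachMode = "additive")
  m <- fitBleachModel(tr)
  corr <- detrendTrace(tr, m)
  ca <- calibrateTrace(corr, calibrationConstants(50, 250, 170))
  caV <- traceValues(ca)
  truthCa <- truthCalcium(truth)
  spikeIdx <- which(truthCa > 125)
  baseIdx <- setdiff(seq_along(truthCa), spikeIdx)
  # flat baseline at the true level
  expect_lt(max(abs(caV[baseIdx] - 125)), 0.75)
  # spike amplitudes preserved within 2%
  for (k in 1:3) {
    w <- which(truthCa > 125 + truth@spikeAmplitudes[k] * 0.75)
    w <- w[w >= truth@spikeOnsets[k] &
           w <= truth@spikeOnsets[k] + truth@spikeDurations[k] + 1]
    got <- max(caV[w]) - median(caV[baseIdx])
    expect_equal(got, truth@spikeAmplitudes[k], tolerance = 0.02)
  }
})
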
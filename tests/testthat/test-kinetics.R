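test_that("one-point normalization pins the aglycemia tail to exactly 1", {
  p <- tinyProtocol(); cfg <- tinyConfig()
  times <- seq(0, protocolDuration(p), by = 1 / 30)
  raw <- makeTrace(times, 1.3 + 0.4 * exp(-times) + 0.001 * sin(times))
  norm <- normalizeToMin(raw, p, cfg)
  ag <- findEpoch(p, "aglycemia")
  sel <- times >= ag$tEnd - cfg@minWindow & times <= ag$tEnd
  expect_equal(mean(norm@ratio[sel]), 1, tolerance = 1e-12)
  expect_true(norm@normalized)
  # a trace constant at its minimum normalizes to exactly 1 everywhere
  flat <- makeTrace(times, rep(1.07, length(times)))
  expect_equal(normalizeToMin(flat, p, cfg)@ratio,
               rep(1, length(times)))
})

test_that("normalization is a plain division and is idempotent", {
  p <- tinyProtocol(); cfg <- tinyConfig()
  times <- seq(0, protocolDuration(p), by = 1 / 30)
  ag <- findEpoch(p, "aglycemia")
  vals <- ifelse(times < ag$tStart, 1.30, 1.00)
  norm <- normalizeToMin(makeTrace(times, vals), p, cfg)
  expect_equal(norm@ratio[1], 1.30)
  again <- normalizeToMin(norm, p, cfg)
  expect_equal(again@ratio, norm@ratio, tolerance = 1e-12)
  expect_equal(again@normFactor, norm@normFactor)
})

test_that("normalization requires a usable aglycemia epoch", {
  noAg <- buildProtocol(data.frame(name = "a", tStart = 0, tEnd = 5,
                                   glcOut = 5))
  tr <- makeTrace(seq(0, 5, 0.1), rep(1.2, 51))
  expect_error(normalizeToMin(tr, noAg), "aglycemia")
})

test_that("rise rate is exact on a linear ramp between plateaus", {
  p <- tinyProtocol(); cfg <- tinyConfig()
  st <- findEpoch(p, "step")
  times <- seq(0, protocolDuration(p), by = 1 / 30)
  k <- 0.9  # normalized units per minute
  rampEnd <- st$tStart + 1
  vals <- ifelse(times < st$tStart, 1.2,
                 ifelse(times < rampEnd, 1.2 + k * (times - st$tStart),
                        1.2 + k * 1))
  est <- estimateRiseRate(makeTrace(times, vals), p, cfg)
  expect_equal(est$rate, k, tolerance = 1e-6)
  expect_equal(est$flag, "ok")
})

test_that("a flat trace is flagged not-estimable rather than zero", {
  p <- tinyProtocol(); cfg <- tinyConfig()
  times <- seq(0, protocolDuration(p), by = 1 / 30)
  est <- estimateRiseRate(makeTrace(times, rep(1.2, length(times))), p, cfg)
  expect_equal(est$flag, "not_estimable")
  expect_true(is.na(est$rate))
})

test_that("the glucose increase is plateau minus baseline", {
  p <- tinyProtocol(); cfg <- tinyConfig()
  st <- findEpoch(p, "step")
  times <- seq(0, protocolDuration(p), by = 1 / 30)
  # strictly inside the step epoch so the boundary sample stays baseline
  vals <- ifelse(times > st$tStart & times <= st$tEnd, 1.5, 1.2)
  expect_equal(estimateDelta(makeTrace(times, vals), p, cfg), 0.3,
               tolerance = 1e-9)
  expect_equal(estimateDelta(makeTrace(times, rep(1.4, length(times))),
                             p, cfg), 0)
})

test_that("higher transport capacity yields a larger glucose increase", {
  p <- tinyProtocol(); cfg <- tinyConfig()
  base <- cellPhysiology(VmaxT = 0.35, Vhk = 0.12, glc0 = 1.2)
  hi <- cellPhysiology(VmaxT = 0.9, Vhk = 0.12, glc0 = 1.2)
  s <- sensorParams()
  deltas <- vapply(list(base, hi), function(ph) {
    traj <- simulateCellGlucose(ph, p, dt = 0.02)
    tr <- traceFromTrajectory(traj, s)
    estimateDelta(normalizeToMin(tr, p, cfg), p, cfg)
  }, numeric(1))
  expect_gt(deltas[2], deltas[1])
})

test_that("consumption slope is exact on a line and ~0 on a flat trace", {
  p <- tinyProtocol(); cfg <- tinyConfig()
  ce <- findEpoch(p, "cytoB")
  times <- seq(0, protocolDuration(p), by = 1 / 30)
  vals <- 2 - 0.05 * times
  est <- estimateConsumptionRate(makeTrace(times, vals), p, cfg)
  expect_equal(est$rate, -0.05, tolerance = 1e-9)
  flat <- estimateConsumptionRate(makeTrace(times, rep(1.5, length(times))),
                                  p, cfg)
  expect_lt(abs(flat$rate), 1e-9)
})

test_that("consumption fits are flagged when data are scarce or rising", {
  p <- tinyProtocol(); cfg <- tinyConfig()
  ce <- findEpoch(p, "cytoB")
  sparse <- makeTrace(seq(0, protocolDuration(p), by = 1),
                      seq(2, 1, length.out = 11))
  expect_equal(estimateConsumptionRate(sparse, p, cfg)$flag, "few_points")
  times <- seq(0, protocolDuration(p), by = 1 / 30)
  rising <- makeTrace(times, 1 + 0.05 * times)
  expect_equal(estimateConsumptionRate(rising, p, cfg)$flag,
               "anomalous_positive")
  shortP <- buildProtocol(data.frame(name = c("b", "c", "a"),
                                     tStart = c(0, 2, 3),
                                     tEnd = c(2, 3, 5),
                                     glcOut = c(5, 5, 0),
                                     cytoB = c(FALSE, TRUE, FALSE)))
  expect_error(estimateConsumptionRate(makeTrace(times, rep(1, length(times))),
                                       shortP, cfg),
               "shorter")
})

test_that("the Theil-Sen option resists a single outlier where OLS does not", {
  p <- tinyProtocol(); cfg <- tinyConfig()
  times <- seq(0, protocolDuration(p), by = 1 / 30)
  vals <- 2 - 0.05 * times
  i <- which(times >= 6 & times <= 6.05)[1]
  vals[i] <- 5  # gross outlier inside the fit window
  ols <- estimateConsumptionRate(makeTrace(times, vals), p, cfg)
  ts <- estimateConsumptionRate(makeTrace(times, vals), p, cfg,
                                robust = TRUE)
  expect_gt(abs(ols$rate + 0.05), 0.005)
  expect_lt(abs(ts$rate + 0.05), 0.002)
})

test_that("estimators are invariant to a common time offset", {
  p <- tinyProtocol(); cfg <- tinyConfig()
  times <- seq(0, protocolDuration(p), by = 1 / 30)
  set.seed(3)
  vals <- 2 - 0.04 * times + rnorm(length(times), 0, 0.005)
  est0 <- estimateConsumptionRate(makeTrace(times, vals), p, cfg)
  off <- 17.3
  e <- epochs(p); e$tStart <- e$tStart + off; e$tEnd <- e$tEnd + off
  pOff <- buildProtocol(e)
  estOff <- estimateConsumptionRate(makeTrace(times + off, vals), pOff, cfg)
  expect_equal(est0$rate, estOff$rate, tolerance = 1e-9)
})

test_that("the noiseless pipeline recovers the preset consumption targets", {
  p <- standardProtocol()
  s <- sensorParams()
  for (g in c("ctrl", "cko")) {
    phys <- physiologyPreset(g)
    traj <- simulateCellGlucose(phys, p, dt = 0.02)
    tr <- noiselessPipelineTrace(traj, s,
                                 times = seq(0, protocolDuration(p), 2 / 60))
    est <- estimateConsumptionRate(normalizeToMin(tr, p), p)
    expect_equal(-est$rate, attr(phys, "targetRate"), tolerance = 0.02)
  }
})

test_that("normalized basal level matches the truth for a simulated cell", {
  fld <- tinyField(nCells = 1, background = 0)
  tr <- extractRatio(fld$stack, fld$rois, smoothWindow = 1)[[1]]
  kin <- cellKinetics(tr, fld$protocol, tinyConfig())
  s <- fld$sensor
  cfg <- tinyConfig()
  bl <- findEpoch(fld$protocol, "baseline")
  traj <- fld$trajectories[[1]]
  gB <- mean(traj@glc[traj@times >= bl$tEnd - cfg@baselineWindow &
                        traj@times <= bl$tEnd])
  # the one-point divisor is the mean ratio over the aglycemia tail window
  agEnd <- max(traj@times)
  selMin <- traj@times >= agEnd - cfg@minWindow
  truthMin <- mean(sensorResponse(traj@glc[selMin], s))
  truthNorm <- sensorResponse(gB, s) / truthMin
  expect_equal(kin$normBasal, truthNorm, tolerance = 0.02)
})
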
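test_that("a cell at transport equilibrium with no consumption stays constant", {
  phys <- cellPhysiology(VmaxT = 0.5, Vhk = 0, gNet = 0, glc0 = 5)
  p <- buildProtocol(data.frame(name = "hold", tStart = 0, tEnd = 10,
                                glcOut = 5))
  tr <- simulateCellGlucose(phys, p, dt = 0.05)
  expect_lt(max(abs(tr@glc - 5)), 1e-7)
})

test_that("transport-stop decline is zero-order at saturating glucose", {
  # with Km_hk -> 0 and transport blocked, d[Glc]/dt = -Vhk exactly
  phys <- cellPhysiology(VmaxT = 0, Vhk = 0.2, KmHk = 1e-6, gNet = 0,
                         glc0 = 4)
  p <- buildProtocol(data.frame(name = "stop", tStart = 0, tEnd = 10,
                                glcOut = 5, cytoB = TRUE))
  tr <- simulateCellGlucose(phys, p, dt = 0.05)
  sel <- tr@times <= 5  # still far from depletion
  fit <- stats::lm(tr@glc[sel] ~ tr@times[sel])
  expect_equal(unname(coef(fit)[2]), -0.2, tolerance = 1e-6)
})

test_that("post-step plateau matches an independent bisection root of the flux balance", {
  phys <- cellPhysiology(VmaxT = 0.4, KmT = 2, Vhk = 0.12, KmHk = 0.05,
                         gNet = 0, glc0 = 1.2)
  # long hold: the relaxation time near the 25 mM plateau is ~30 min
  p <- buildProtocol(data.frame(name = "step", tStart = 0, tEnd = 700,
                                glcOut = 25))
  tr <- simulateCellGlucose(phys, p, dt = 0.05)
  # independent oracle: hand-rolled bisection on T(g) = C(g)
  flux <- function(g) {
    0.4 * (25 / (2 + 25) - g / (2 + g)) - 0.12 * g / (0.05 + g)
  }
  lo <- 0; hi <- 25
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (flux(mid) > 0) lo <- mid else hi <- mid
  }
  root <- (lo + hi) / 2
  expect_lt(abs(tr@glc[length(tr@glc)] - root), 1e-6)
  expect_lt(abs(steadyStateGlucose(phys, 25) - root), 1e-6)
})

test_that("raising extracellular glucose never lowers the steady state", {
  phys <- cellPhysiology(VmaxT = 0.4, Vhk = 0.12)
  ss <- vapply(c(0, 1, 2, 5, 10, 25), steadyStateGlucose, numeric(1),
               phys = phys)
  expect_true(all(diff(ss) >= -1e-12))
})

test_that("aglycemia drives cytosolic glucose and the sensor ratio to their floor", {
  phys <- cellPhysiology(VmaxT = 0.4, Vhk = 0.12, gNet = 0, glc0 = 1.2)
  p <- buildProtocol(data.frame(name = "agly", tStart = 0, tEnd = 60,
                                glcOut = 0))
  tr <- simulateCellGlucose(phys, p, dt = 0.05)
  expect_lt(tr@glc[length(tr@glc)], 1e-4)
  s <- sensorParams()
  expect_lt(sensorResponse(tr@glc[length(tr@glc)], s) - s@Rmin, 1e-3)
})

test_that("the network-exchange term pulls an uncoupled cell toward the network level", {
  # with transport and consumption off, [Glc]i relaxes to glcNet...
  phys <- cellPhysiology(VmaxT = 0, Vhk = 0, gNet = 0.5, glc0 = 0.2)
  p <- buildProtocol(data.frame(name = "x", tStart = 0, tEnd = 40,
                                glcOut = 5))
  tr <- simulateCellGlucose(phys, p, dt = 0.05, glcNet = 1.2)
  expect_equal(tr@glc[length(tr@glc)], 1.2, tolerance = 1e-6)
  # ...and carbenoxolone removes that flux entirely
  pCbx <- buildProtocol(data.frame(name = "x", tStart = 0, tEnd = 40,
                                   glcOut = 5, cbx = TRUE))
  trCbx <- simulateCellGlucose(phys, pCbx, dt = 0.05, glcNet = 1.2)
  expect_equal(trCbx@glc, rep(0.2, length(trCbx@glc)), tolerance = 1e-9)
})

test_that("too-coarse time steps are rejected", {
  p <- buildProtocol(data.frame(name = "a", tStart = 0, tEnd = 1, glcOut = 5))
  expect_error(simulateCellGlucose(cellPhysiology(), p, dt = 0.2),
               "dt too large")
  expect_error(simulateCellGlucose(cellPhysiology(), p, dt = 0),
               "dt")
})

test_that("physiology parameter validity is enforced", {
  expect_error(cellPhysiology(VmaxT = -1), "0")
  expect_error(cellPhysiology(KmT = 0), "KmT")
  expect_error(cellPhysiology(KmHk = 0), "KmHk")
})
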
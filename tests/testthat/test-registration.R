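test_that("a static stack registers to all-zero shifts", {
  fld <- tinyField(nCells = 3, shotNoise = TRUE, readNoiseSd = 2, seed = 8)
  sh <- shiftTable(estimateShifts(fld$stack, reference = 1:5,
                                  subpixelFactor = 10))
  expect_true(all(abs(sh$dx) <= 0.1))
  expect_true(all(abs(sh$dy) <= 0.1))
})

test_that("an injected constant integer shift is recovered exactly", {
  fld <- tinyField(nCells = 3, frameShape = c(64, 64))
  scene <- fld$scene
  scene@motionPath[, 1] <- 3; scene@motionPath[, 2] <- -2
  scene@motionPath[1, ] <- 0
  r <- renderStack(scene, fld$trajectories, fld$sensor)
  sh <- shiftTable(estimateShifts(r$stack, reference = 1, subpixelFactor = 1))
  expect_identical(sh$dx[-1], rep(3, nrow(sh) - 1))
  expect_identical(sh$dy[-1], rep(-2, nrow(sh) - 1))
})

test_that("a 0.4 px shift is recovered within 0.1 px at subpixel factor 10", {
  fld <- tinyField(nCells = 3, frameShape = c(64, 64))
  scene <- fld$scene
  scene@motionPath[, ] <- 0
  scene@motionPath[2, ] <- c(0.4, -0.4)
  r <- renderStack(scene, fld$trajectories, fld$sensor)
  sh <- shiftTable(estimateShifts(r$stack, reference = 1,
                                  subpixelFactor = 10))
  expect_lt(abs(sh$dx[2] - 0.4), 0.1)
  expect_lt(abs(sh$dy[2] + 0.4), 0.1)
})

test_that("zero shifts leave the stack bit-identical", {
  fld <- tinyField(nCells = 2, shotNoise = TRUE, seed = 5)
  nf <- nFrames(fld$stack)
  zero <- new("ShiftSeries",
              shifts = data.frame(frame = seq_len(nf), dx = 0, dy = 0,
                                  peak = 1, lowConf = FALSE),
              reference = 1L, maxShift = 20)
  out <- applyShifts(fld$stack, zero)
  expect_identical(out@yellow, fld$stack@yellow)
  expect_identical(out@blue, fld$stack@blue)
  expect_identical(out@times, fld$stack@times)
})

test_that("integer shift then unshift restores the original where valid", {
  img <- matrix(stats::runif(64 * 64), 64, 64)
  fwd <- translateImage(img, 4, -3, fill = 0)
  back <- translateImage(fwd$img, -4, 3, fill = 0)
  ok <- back$valid & translateImage(fwd$valid * 1, -4, 3, fill = 0)$img > 0.5
  expect_equal(back$img[ok], img[ok], tolerance = 1e-12)
})

test_that("both channels always receive the identical transform", {
  # yellow == blue in, so they must remain equal out for any shift series
  fld <- tinyField(nCells = 2, frameShape = c(48, 48))
  st <- fld$stack
  st@blue <- st@yellow
  nf <- nFrames(st)
  sh <- new("ShiftSeries",
            shifts = data.frame(frame = seq_len(nf),
                                dx = sin(seq_len(nf) / 5) * 2,
                                dy = cos(seq_len(nf) / 7) * 2,
                                peak = 1, lowConf = FALSE),
            reference = 1L, maxShift = 20)
  out <- applyShifts(st, sh)
  expect_identical(out@yellow, out@blue)
  expect_equal(nFrames(out), nf)
})

test_that("registered drifting stacks track the motion-free render within noise", {
  prot <- tinyProtocol()
  base <- tinyField(nCells = 3, protocol = prot, frameShape = c(64, 64),
                    shotNoise = TRUE, readNoiseSd = 2, seed = 77)
  moving <- base$scene
  set.seed(123)
  steps <- matrix(rnorm(2 * nrow(moving@motionPath), 0, 0.15), ncol = 2)
  steps[1, ] <- 0
  moving@motionPath <- pmin(pmax(apply(steps, 2, cumsum), -6), 6)
  r <- renderStack(moving, base$trajectories, base$sensor)
  reg <- registerStack(r$stack, reference = 1:10, subpixelFactor = 10)
  trMoving <- extractRatio(reg$stack, r$rois, smoothWindow = 1)
  trStill <- extractRatio(base$stack, base$rois, smoothWindow = 1)
  # noise floor: RMS deviation of the noise-matched motionless render from
  # the exact noiseless pipeline trace of the same cell
  pipe <- noiselessPipelineTrace(base$trajectories[[1]], base$sensor,
                                 times = frameTimes(base$stack),
                                 background = 20,
                                 brightness = base$scene@cells$brightness[1],
                                 smoothWindow = 1)
  noiseRms <- sqrt(mean((trStill[[1]]@ratio - pipe@ratio)^2, na.rm = TRUE))
  dev <- trMoving[[1]]@ratio - trStill[[1]]@ratio
  expect_lt(sqrt(mean(dev^2, na.rm = TRUE)), 3 * noiseRms)
})

test_that("shift recovery over random drift paths is accurate to < 0.15 px", {
  # property suite at reduced size; the acceptance suite runs 100 paths
  fld <- tinyField(nCells = 3, frameShape = c(64, 64),
                   protocol = buildProtocol(data.frame(
                     name = "short", tStart = 0, tEnd = 1, glcOut = 5)))
  errs <- c()
  for (rep in 1:10) {
    scene <- fld$scene
    set.seed(1000 + rep)
    nf <- nrow(scene@motionPath)
    steps <- matrix(rnorm(2 * nf, 0, 0.3), ncol = 2)
    steps[1, ] <- 0
    scene@motionPath <- pmin(pmax(apply(steps, 2, cumsum), -6), 6)
    scene@shotNoise <- TRUE; scene@readNoiseSd <- 2
    r <- renderStack(scene, fld$trajectories, fld$sensor)
    sh <- shiftTable(estimateShifts(r$stack, reference = 1,
                                    subpixelFactor = 10))
    errs <- c(errs, abs(sh$dx - scene@motionPath[, 1]),
              abs(sh$dy - scene@motionPath[, 2]))
  }
  expect_lt(mean(errs), 0.15)
})
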
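test_that("boxcar smoothing has unit DC gain and the exact kernel", {
  expect_equal(boxcarSmooth(rep(3.5, 40), 11), rep(3.5, 40))
  imp <- c(rep(0, 20), 1, rep(0, 20))
  sm <- boxcarSmooth(imp, 11)
  expect_equal(sm[16:26], rep(1 / 11, 11))
  expect_equal(sum(sm), 1)  # mass conserved
  x <- stats::rnorm(30)
  expect_identical(boxcarSmooth(x, 1), x)
  expect_error(boxcarSmooth(x, 10), "odd")
})

test_that("boxcar boundaries shrink symmetrically without invented padding", {
  x <- c(4, 8, 6, 2, 10, 12)
  sm <- boxcarSmooth(x, 5)
  expect_equal(sm[1], 4)                    # window of 1
  expect_equal(sm[2], mean(x[1:3]))         # window of 3
  expect_equal(sm[3], mean(x[1:5]))         # full window
  expect_equal(sm[6], 12)
})

test_that("boxcar treats missing samples as absent, not zero", {
  x <- c(1, NA, 3)
  expect_equal(boxcarSmooth(x, 3)[2], 2)
  expect_true(is.na(boxcarSmooth(c(NA, NA, NA), 3)[2]))
})

test_that("mean-then-divide differs from mean-of-ratios and returns the quotient of means", {
  # 2-pixel ROI: (yellow, blue) = (10, 5) and (2, 2)
  yellow <- array(0, c(1, 2, 1)); yellow[1, , 1] <- c(10, 2)
  blue <- array(0, c(1, 2, 1)); blue[1, , 1] <- c(5, 2)
  st <- new("TwoChannelStack", yellow = yellow, blue = blue, times = 0,
            validMask = array(TRUE, c(0, 0, 0)), pixelSize = 1,
            provenance = list())
  rois <- new("ROISet", labels = matrix(1L, 1, 2),
              meta = data.frame(cell = 1L), minPixels = 1)
  tr <- extractRatio(st, rois, smoothWindow = 1)[[1]]
  expect_equal(tr@ratio, 12 / 7)
  expect_false(isTRUE(all.equal(tr@ratio, mean(c(10 / 5, 2 / 2)))))
})

test_that("ratios are invariant to common channel scaling", {
  fld <- tinyField(nCells = 2, shotNoise = FALSE)
  st <- fld$stack
  tr1 <- extractRatio(st, fld$rois, smoothWindow = 11)
  st@yellow <- st@yellow * 37.5
  st@blue <- st@blue * 37.5
  tr2 <- extractRatio(st, fld$rois, smoothWindow = 11)
  for (i in seq_along(tr1))
    expect_equal(tr1[[i]]@ratio, tr2[[i]]@ratio, tolerance = 1e-12)
})

test_that("extraction equals a brute-force quotient-of-means oracle", {
  set.seed(21)
  nr <- 20; nc <- 20; nf <- 7
  yellow <- array(stats::runif(nr * nc * nf, 50, 400), c(nr, nc, nf))
  blue <- array(stats::runif(nr * nc * nf, 50, 400), c(nr, nc, nf))
  labels <- matrix(0L, nr, nc)
  labels[sample(nr * nc, 60)] <- rep(1:3, each = 20)  # random scattered ROIs
  st <- new("TwoChannelStack", yellow = yellow, blue = blue,
            times = seq_len(nf), validMask = array(TRUE, c(0, 0, 0)),
            pixelSize = 1, provenance = list())
  rois <- new("ROISet", labels = labels, meta = data.frame(cell = 1:3),
              minPixels = 1)
  got <- extractRatio(st, rois, smoothWindow = 1)
  for (k in 1:3) {
    idx <- which(labels == k)
    for (f in seq_len(nf)) {
      oracle <- mean(yellow[, , f][idx]) / mean(blue[, , f][idx])
      expect_equal(got[[k]]@ratio[f], oracle, tolerance = 1e-12)
    }
  }
})

test_that("image-level and trace-level smoothing agree on fully valid ROIs", {
  fld <- tinyField(nCells = 2, shotNoise = TRUE, readNoiseSd = 2, seed = 14)
  a <- extractRatio(fld$stack, fld$rois, smoothWindow = 11,
                    smoothImages = TRUE)
  b <- extractRatio(fld$stack, fld$rois, smoothWindow = 11,
                    smoothImages = FALSE)
  # per-channel smoothing then division vs division then smoothing:
  # close but not identical for a fluctuating denominator
  for (i in 1:2)
    expect_equal(a[[i]]@ratio, b[[i]]@ratio, tolerance = 5e-3)
})

test_that("smoothing a stack never changes frame count or timestamps", {
  fld <- tinyField(nCells = 1)
  sm <- smoothStack(fld$stack, 11)
  expect_identical(dim(sm@yellow), dim(fld$stack@yellow))
  expect_identical(sm@times, fld$stack@times)
})

test_that("segmentation finds disjoint bright disks and filters small ones", {
  img <- matrix(0, 64, 64)
  mkDisk <- function(cx, cy, r) {
    for (x in (cx - r):(cx + r)) for (y in (cy - r):(cy + r))
      if ((x - cx)^2 + (y - cy)^2 <= r^2) img[y, x] <<- 100
  }
  mkDisk(16, 16, 5)
  mkDisk(46, 40, 6)
  mkDisk(56, 8, 2)   # 13 px, below the minimum
  rois <- segmentRois(img, thresholdQuantile = 0.9, minPixels = 20)
  expect_equal(nrow(roiMeta(rois)), 2L)
  sizes <- sort(roiMeta(rois)$nPixels)
  countPix <- function(r) sum(outer(-r:r, -r:r,
                                    function(a, b) a^2 + b^2 <= r^2))
  expect_equal(sizes, sort(c(countPix(5), countPix(6))))
  # deterministic labeling by centroid (row, col)
  expect_equal(roiMeta(rois)$cell, 1:2)
  expect_warning(segmentRois(matrix(0, 16, 16)), "empty")
})

test_that("background-offset subtraction restores the sensor-ideal ratio", {
  fld <- tinyField(nCells = 1, background = 20)
  tr <- extractRatio(fld$stack, fld$rois, smoothWindow = 1,
                     backgroundOffset = 20)[[1]]
  truth <- traceFromTrajectory(fld$trajectories[[1]], fld$sensor,
                               times = frameTimes(fld$stack))
  expect_lt(max(abs(tr@ratio - truth@ratio)), 1e-10)
})

test_that("noiseless simulator traces reproduce the sensor response of the truth", {
  fld <- tinyField(nCells = 1, background = 0)
  tr <- extractRatio(fld$stack, fld$rois, smoothWindow = 1)[[1]]
  truth <- traceFromTrajectory(fld$trajectories[[1]], fld$sensor,
                               times = frameTimes(fld$stack))
  expect_lt(max(abs(tr@ratio / truth@ratio - 1)), 1e-6)
})
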
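test_that("star masks yield exactly k intersections at radii crossing the arms", {
  for (k in c(3, 5, 8)) {
    mask <- starMask(k)
    center <- c(41, 41)  # pixelSize 1, center at image middle
    prof <- shollProfile(mask, center, r0 = 4, dr = 2, rMax = 36,
                         pixelSize = 1)
    # radii where arms are well separated (arc spacing >> arm width)
    clear <- prof$radius >= ceiling(k * 5 / (2 * pi)) + 4 & prof$radius <= 34
    expect_true(all(prof$crossings[clear] == k),
                label = sprintf("%d-armed star", k))
    oracle <- shollOracle(mask, center, prof$radius)
    expect_equal(prof$crossings, oracle)
  }
})

test_that("empty masks and filled disks give the degenerate profiles", {
  empty <- matrix(FALSE, 41, 41)
  prof <- shollProfile(empty, c(21, 21), r0 = 4, dr = 2, rMax = 16)
  expect_true(all(prof$crossings == 0))
  disk <- matrix(FALSE, 61, 61)
  for (x in 1:61) for (y in 1:61)
    if ((x - 31)^2 + (y - 31)^2 <= 12^2) disk[y, x] <- TRUE
  p2 <- shollProfile(disk, c(31, 31), r0 = 4, dr = 2, rMax = 24)
  expect_true(all(p2$crossings[p2$radius < 12] == 1))
  expect_true(all(p2$crossings[p2$radius > 13] == 0))
})

test_that("profiles are invariant to padding and joint translation", {
  mask <- starMask(5)
  prof <- shollProfile(mask, c(41, 41), r0 = 4, dr = 2, rMax = 30)
  pad <- matrix(FALSE, 121, 121)
  pad[31:111, 26:106] <- mask  # translate by (+25, +30) in (x, y)
  prof2 <- shollProfile(pad, c(41 + 25, 41 + 30), r0 = 4, dr = 2, rMax = 30)
  expect_equal(prof$crossings, prof2$crossings)
})

test_that("circles fully outside the image warn and count zero", {
  mask <- matrix(TRUE, 21, 21)
  expect_warning(p <- shollProfile(mask, c(11, 11), r0 = 4, dr = 40,
                                   rMax = 60),
                 "outside")
  expect_equal(p$crossings[p$radius > 30], 0L)
  expect_error(shollProfile(mask, c(100, 100)), "center")
})

test_that("the trapezoid hand example integrates to 4.5 mm^3", {
  s <- data.frame(position = seq(0, 2.5, 0.5),
                  infarct = c(1, 2, 2, 2, 2, 1), ipsi = 1, contra = 1)
  expect_equal(infarctVolume(s, correction = "none")$volume, 4.5)
  # with ipsi == contra everywhere, all modes coincide
  expect_equal(infarctVolume(s, correction = "standard")$volume, 4.5)
  expect_equal(infarctVolume(s, correction = "inverse")$volume, 4.5)
  # uniform spacing: the sum x spacing mode agrees on interior-heavy data
  expect_equal(infarctVolume(s, integration = "sum")$volume,
               sum(c(1, 2, 2, 2, 2, 1)) * 0.5)
})

test_that("edema correction scales single sections as hand-computed", {
  s <- data.frame(position = c(0, 1, 2), infarct = c(1, 2, 1),
                  ipsi = c(1, 1.2, 1), contra = 1)
  v <- infarctVolume(s, correction = "standard")
  # brute-force piecewise trapezoid with the middle area scaled by 1/1.2
  a <- c(1, 2 / 1.2, 1)
  expect_equal(v$volume, sum(diff(s$position) * (a[-1] + a[-length(a)]) / 2))
  expect_equal(v$sections$correctedArea, a)
  vInv <- infarctVolume(s, correction = "inverse")
  expect_equal(vInv$sections$correctedArea, c(1, 2 * 1.2, 1))
  expect_false(isTRUE(all.equal(v$volume, vInv$volume)))
})

test_that("volume is linear in the section areas", {
  set.seed(6)
  s <- data.frame(position = 0:5, infarct = runif(6, 0.5, 3),
                  ipsi = runif(6, 0.9, 1.3), contra = runif(6, 0.9, 1.3))
  v1 <- infarctVolume(s)$volume
  s2 <- s; s2$infarct <- 2 * s2$infarct
  expect_equal(infarctVolume(s2)$volume, 2 * v1, tolerance = 1e-12)
})

test_that("invalid section tables are rejected", {
  s <- data.frame(position = c(0, 1, 1), infarct = 1, ipsi = 1, contra = 1)
  expect_error(infarctVolume(s), "monotonic")
  s2 <- data.frame(position = 0:1, infarct = 1, ipsi = c(1, 0), contra = 1)
  expect_error(infarctVolume(s2), "ipsilateral")
  expect_error(infarctVolume(data.frame(position = 0, infarct = 1,
                                        ipsi = 1, contra = 1)),
               "2 sections")
})
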
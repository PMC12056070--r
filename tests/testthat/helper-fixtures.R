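# Shared fixtures: everything is generated in code at test time.

# Compact protocol covering all epoch roles; pair with tinyConfig().
tinyProtocol <- function() {
  standardProtocol(durations = c(baseline = 2, step = 2, washout = 1,
                                 cytoB = 3, aglycemia = 2),
                   glcOut = c(5, 25, 5, 5, 0))
}

tinyConfig <- function() {
  kineticsConfig(minWindow = 1, washinDelay = 0.5, consumptionFitSpan = 2,
                 plateauWindow = 1, baselineWindow = 1)
}

# Build a RatioTrace directly from numbers.
makeTrace <- function(times, ratio, meta = list(cell = 1L)) {
  new("RatioTrace", times = times, ratio = ratio, nValid = integer(0),
      meta = meta, window = 1, normalized = FALSE, normFactor = NA_real_)
}

# Render a small field; defaults are noise-free and motion-free so tests
# opt in to the artifacts they probe.
tinyField <- function(nCells = 2, protocol = tinyProtocol(),
                      phys = cellPhysiology(), sensor = sensorParams(),
                      frameShape = c(48, 48), motionSd = 0,
                      shotNoise = FALSE, readNoiseSd = 0, seed = 42, ...) {
  scene <- buildScene(nCells = nCells, protocol = protocol,
                      frameShape = frameShape, motionSd = motionSd,
                      shotNoise = shotNoise, readNoiseSd = readNoiseSd,
                      seed = seed, ...)
  trajs <- lapply(seq_len(nCells), function(i)
    simulateCellGlucose(phys, protocol, dt = 0.02))
  out <- renderStack(scene, trajs, sensor)
  out$scene <- scene
  out$trajectories <- trajs
  out$protocol <- protocol
  out$sensor <- sensor
  out
}

# Draw a k-armed star of given arm half-width (px) into a logical mask.
starMask <- function(k, size = 81, armHalfWidth = 1.5,
                     rInner = 2, rOuter = 38) {
  cx <- (size + 1) / 2; cy <- cx
  mask <- matrix(FALSE, size, size)
  angles <- (seq_len(k) - 1) * 2 * pi / k + 0.12  # avoid axis alignment
  for (a in angles) {
    ux <- cos(a); uy <- sin(a)
    for (t in seq(rInner, rOuter, by = 0.25)) {
      x <- cx + t * ux; y <- cy + t * uy
      rows <- max(1, floor(y - armHalfWidth)):min(size, ceiling(y + armHalfWidth))
      cols <- max(1, floor(x - armHalfWidth)):min(size, ceiling(x + armHalfWidth))
      for (r in rows) for (cc in cols) {
        if ((r - y)^2 + (cc - x)^2 <= armHalfWidth^2) mask[r, cc] <- TRUE
      }
    }
  }
  mask
}

# Dense-sampling Sholl oracle: label contiguous foreground arcs on a
# finely sampled circle (arc step 0.1 px), independent of the
# implementation's arc step and run counting.
shollOracle <- function(mask, center, radii, pixelSize = 1) {
  nr <- nrow(mask); nc <- ncol(mask)
  cx <- center[1] / pixelSize; cy <- center[2] / pixelSize
  vapply(radii, function(r) {
    rpx <- r / pixelSize
    n <- max(16L, ceiling(2 * pi * rpx / 0.1))
    th <- (seq_len(n) - 1) * 2 * pi / n
    xs <- round(cx + rpx * cos(th)); ys <- round(cy + rpx * sin(th))
    v <- logical(n)
    ok <- xs >= 1 & xs <= nc & ys >= 1 & ys <= nr
    v[ok] <- mask[cbind(ys[ok], xs[ok])]
    if (!any(v)) return(0L)
    if (all(v)) return(1L)
    sum(v & !c(v[n], v[-n]))
  }, integer(1))
}

# Hierarchical null data: animal-level variance dominating, no group effect.
nullNestedData <- function(seed, nAnimalsPerGroup = 4, nSlices = 2,
                           nCells = 4, sdAnimal = 1, sdSlice = 0.3,
                           sdCell = 0.5, effect = 0) {
  set.seed(seed)
  nA <- 2 * nAnimalsPerGroup
  d <- expand.grid(cell = seq_len(nCells), slice = seq_len(nSlices),
                   animal = seq_len(nA))
  d$genotype <- ifelse(d$animal <= nAnimalsPerGroup, "ctrl", "cko")
  aEff <- rnorm(nA, 0, sdAnimal)
  sliceId <- (d$animal - 1) * nSlices + d$slice
  sEff <- rnorm(nA * nSlices, 0, sdSlice)
  d$value <- aEff[d$animal] + sEff[sliceId] + rnorm(nrow(d), 0, sdCell) +
    ifelse(d$genotype == "cko", effect, 0)
  d$slice <- sliceId
  d
}
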
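#' @include AllClasses.R registration.R
NULL

## Evaluate `code` under a temporary RNG state seeded with `seed`;
## the caller's RNG stream is restored afterwards.
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Build an imaging scene
#'
#' Places non-overlapping disk-shaped cells in the field of view, draws a
#' per-cell brightness, and generates a rigid lateral drift path (Gaussian
#' random walk, clipped). Cells are kept away from the frame edge by
#' `radius + motionMax + 2` pixels so drift never clips them.
#'
#' @param nCells number of cells (fields typically hold 5-8).
#' @param nFrames number of frames; alternatively give `protocol`.
#' @param protocol optional [FretProtocol-class] from which `nFrames` is
#'   derived using `framePeriod`.
#' @param frameShape frame size in pixels (rows, cols).
#' @param pixelSize micrometres per pixel.
#' @param cellRadius disk radius in pixels.
#' @param brightness median pre-noise cell brightness (summed over both
#'   channels, counts); per-cell values are log-normal around this.
#' @param brightnessCv log-scale standard deviation of cell brightness.
#' @param background counts added to both channels everywhere.
#' @param framePeriod seconds between frames.
#' @param motionSd per-frame random-walk step standard deviation (px).
#' @param motionMax drift clip (px).
#' @param shotNoise enable Poisson shot noise.
#' @param readNoiseSd Gaussian read-noise standard deviation (counts).
#' @param seed optional integer; when given, scene construction (and only
#'   it) is seeded and the caller's RNG stream is untouched.
#' @return a [FretScene-class].
#' @export
buildScene <- function(nCells = 6, nFrames = NULL, protocol = NULL,
                       frameShape = c(256L, 256L), pixelSize = 0.5,
                       cellRadius = 6, brightness = 300, brightnessCv = 0.2,
                       background = 20, framePeriod = 2,
                       motionSd = 0.15, motionMax = 6,
                       shotNoise = TRUE, readNoiseSd = 2, seed = NULL) {
  if (is.null(nFrames)) {
    if (is.null(protocol)) stop("give either nFrames or a protocol")
    nFrames <- floor(protocolDuration(protocol) * 60 / framePeriod) + 1L
  }
  frameShape <- as.integer(frameShape)
  .withSeed(seed, {
    margin <- cellRadius + motionMax + 2
    lo <- margin + 1
    hiR <- frameShape[1L] - margin
    hiC <- frameShape[2L] - margin
    if (hiR <= lo || hiC <= lo)
      stop("frame too small for the requested cell radius and drift bound")
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    while (length(xs) < nCells) {
      x <- stats::runif(1, lo, hiC); y <- stats::runif(1, lo, hiR)
      if (!length(xs) ||
          all((xs - x)^2 + (ys - y)^2 > (2 * cellRadius + 2)^2)) {
        xs <- c(xs, x); ys <- c(ys, y)
      }
      tries <- tries + 1L
      if (tries > 5000L) stop("could not place ", nCells,
                              " non-overlapping cells in the field")
    }
    b <- brightness * exp(stats::rnorm(nCells, 0, brightnessCv))
    path <- if (motionSd > 0) {
      steps <- matrix(stats::rnorm(2L * nFrames, 0, motionSd), ncol = 2L)
      steps[1L, ] <- 0
      p <- apply(steps, 2L, cumsum)
      pmin(pmax(p, -motionMax), motionMax)
    } else matrix(0, nFrames, 2L)
    colnames(path) <- c("dx", "dy")
    new("FretScene", frameShape = frameShape, pixelSize = pixelSize,
        cells = data.frame(x = xs, y = ys, radius = cellRadius,
                           brightness = b),
        background = background, framePeriod = framePeriod,
        motionPath = path, shotNoise = shotNoise,
        readNoiseSd = readNoiseSd,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}

## Linear indices of the disk footprint of cell j (unshifted coordinates).
.diskIndices <- function(scene, j) {
  nr <- scene@frameShape[1L]; nc <- scene@frameShape[2L]
  cx <- scene@cells$x[j]; cy <- scene@cells$y[j]; r <- scene@cells$radius[j]
  rows <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
  grid <- expand.grid(row = rows, col = cols)
  keep <- (grid$row - cy)^2 + (grid$col - cx)^2 <= r^2
  list(idx = grid$row[keep] + (grid$col[keep] - 1L) * nr,
       clipped = any(cy - r < 1 | cy + r > nr | cx - r < 1 | cx + r > nc))
}

#' Render a two-channel image stack from ground-truth trajectories
#'
#' Each cell's glucose trajectory is mapped through the sensor to a ratio
#' \eqn{R(t)}; the pre-noise cell signal is split as donor (blue)
#' \eqn{B/(1+R)} and acceptor (yellow) \eqn{B R/(1+R)}, so blue + yellow
#' equals the cell brightness \eqn{B} exactly (brightness conservation).
#' Background counts are added to both channels, the whole frame is
#' translated along the scene's motion path (regions entering from outside
#' the field carry background), and Poisson shot noise followed by
#' Gaussian read noise is applied when enabled. Ground-truth ROI labels are
#' returned in unshifted coordinates.
#'
#' @param scene a [FretScene-class]; its motion path length must equal the
#'   rendered frame count.
#' @param trajectories list of [GlucoseTrajectory-class], one per cell.
#' @param sensor a [SensorParams-class].
#' @param cellMeta optional data.frame (one row per cell) merged into the
#'   ROI metadata (e.g. cell/slice/animal/genotype and truth parameters).
#' @return list with `stack` (a [TwoChannelStack-class]), `rois`
#'   (a [ROISet-class] with ground-truth labels) and `meta`
#'   (the per-cell metadata table, including a `clipped` flag).
#' @export
renderStack <- function(scene, trajectories, sensor = sensorParams(),
                        cellMeta = NULL) {
  nCells <- nrow(scene@cells)
  if (length(trajectories) != nCells)
    stop("need exactly one trajectory per cell")
  nr <- scene@frameShape[1L]; nc <- scene@frameShape[2L]
  tAll <- trajectories[[1L]]@times
  t0 <- min(tAll)
  nf <- floor((max(tAll) - t0) * 60 / scene@framePeriod) + 1L
  times <- t0 + (seq_len(nf) - 1L) * scene@framePeriod / 60
  if (nrow(scene@motionPath) != nf)
    stop("motion path length (", nrow(scene@motionPath),
         ") does not match the stack (", nf, " frames)")

  Rmat <- t(vapply(trajectories, function(tr) {
    g <- stats::approx(tr@times, tr@glc, xout = times, rule = 2)$y
    sensorResponse(g, sensor)
  }, numeric(nf)))

  disks <- lapply(seq_len(nCells), .diskIndices, scene = scene)
  clipped <- vapply(disks, `[[`, logical(1L), "clipped")
  if (any(clipped))
    warning(sum(clipped), " cell(s) extend outside the frame; clipped")

  bg <- scene@background
  B <- scene@cells$brightness
  yellow <- array(0, c(nr, nc, nf))
  blue <- array(0, c(nr, nc, nf))
  baseY <- matrix(bg, nr, nc)
  anyMotion <- any(scene@motionPath != 0)
  for (f in seq_len(nf)) {
    yf <- baseY; bf <- baseY
    for (j in seq_len(nCells)) {
      R <- Rmat[j, f]
      yf[disks[[j]]$idx] <- bg + B[j] * R / (1 + R)
      bf[disks[[j]]$idx] <- bg + B[j] / (1 + R)
    }
    if (anyMotion && any(scene@motionPath[f, ] != 0)) {
      yf <- translateImage(yf, scene@motionPath[f, 1L],
                           scene@motionPath[f, 2L], fill = bg)$img
      bf <- translateImage(bf, scene@motionPath[f, 1L],
                           scene@motionPath[f, 2L], fill = bg)$img
    }
    ## pre-noise intensities are non-negative by construction
    if (scene@shotNoise) {
      yf <- stats::rpois(nr * nc, yf)
      bf <- stats::rpois(nr * nc, bf)
    }
    if (scene@readNoiseSd > 0) {
      yf <- pmax(yf + stats::rnorm(nr * nc, 0, scene@readNoiseSd), 0)
      bf <- pmax(bf + stats::rnorm(nr * nc, 0, scene@readNoiseSd), 0)
    }
    yellow[, , f] <- yf
    blue[, , f] <- bf
  }

  labels <- matrix(0L, nr, nc)
  for (j in seq_len(nCells)) labels[disks[[j]]$idx] <- j
  meta <- data.frame(cell = seq_len(nCells),
                     x = scene@cells$x, y = scene@cells$y,
                     radius = scene@cells$radius,
                     brightness = B, clipped = clipped)
  if (!is.null(cellMeta)) {
    stopifnot(nrow(cellMeta) == nCells)
    keep <- setdiff(names(cellMeta), names(meta))
    meta <- cbind(meta, cellMeta[, keep, drop = FALSE])
    if ("cell" %in% names(cellMeta)) meta$cell <- cellMeta$cell
  }
  if (!identical(meta$cell, seq_len(nCells))) {
    relab <- labels
    for (j in seq_len(nCells)) relab[labels == j] <- meta$cell[j]
    labels <- relab
  }
  stack <- new("TwoChannelStack", yellow = yellow, blue = blue,
               times = times, validMask = array(TRUE, c(0L, 0L, 0L)),
               pixelSize = scene@pixelSize,
               provenance = list(seed = scene@seed, registered = FALSE))
  rois <- new("ROISet", labels = labels, meta = meta,
              minPixels = min(lengths(lapply(disks, `[[`, "idx"))))
  list(stack = stack, rois = rois, meta = meta)
}
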
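#' @include AllClasses.R
NULL

## Symmetric half-width per position for a centered window that shrinks
## at the boundaries (no invented padding values).
.shrinkHalfwidth <- function(n, window) {
  if (window %% 2 == 0) stop("boxcar window must be odd (centering undefined)")
  if (window < 1) stop("boxcar window must be >= 1")
  h <- (window - 1) / 2
  pmin(h, seq_len(n) - 1L, n - seq_len(n))
}

#' Centered boxcar (moving-average) smoothing
#'
#' Centered moving average with an odd window. Near the boundaries the
#' window shrinks symmetrically, so the filter has unit DC gain everywhere
#' and never invents padding values. `NA` samples are treated as missing:
#' they are excluded from the local average and stay `NA` only if every
#' sample in the window is missing.
#'
#' @param x numeric vector.
#' @param window odd integer window length in samples (default 11 frames).
#' @return smoothed vector of the same length.
#' @examples
#' boxcarSmooth(rep(2, 20), 11)            # constant in, constant out
#' boxcarSmooth(c(rep(0, 10), 1, rep(0, 10)), 11)[6:16]  # 11 x 1/11
#' @export
boxcarSmooth <- function(x, window = 11) {
  n <- length(x)
  hi <- .shrinkHalfwidth(n, window)
  if (window == 1 || n == 0L) return(x)
  v <- as.numeric(!is.na(x))
  xs <- ifelse(is.na(x), 0, x)
  csx <- c(0, cumsum(xs))
  csv <- c(0, cumsum(v))
  i <- seq_len(n)
  num <- csx[i + hi + 1L] - csx[i - hi]
  den <- csv[i + hi + 1L] - csv[i - hi]
  out <- ifelse(den > 0, num / den, NA_real_)
  out
}

## Boxcar along the frame axis of a pixels x frames matrix with per-frame
## shrinking half-widths; returns windowed sums (not means).
.boxcarFrameSums <- function(M, hi) {
  npix <- nrow(M); nf <- ncol(M)
  CS <- matrix(0, npix, nf + 1L)
  for (j in seq_len(nf)) CS[, j + 1L] <- CS[, j] + M[, j]
  out <- matrix(0, npix, nf)
  for (i in seq_len(nf)) out[, i] <- CS[, i + hi[i] + 1L] - CS[, i - hi[i]]
  out
}

#' Temporal boxcar smoothing of an image stack
#'
#' Applies [boxcarSmooth()] per pixel along the frame axis, honoring the
#' validity mask: invalid pixels are excluded from the local average and a
#' smoothed pixel is invalid only when no valid sample falls in its
#' window. The smoothing order mirrors the analysis convention: motion
#' correction first, then temporal smoothing, then ratio extraction.
#'
#' @param stack a [TwoChannelStack-class].
#' @param window odd boxcar length in frames (default 11).
#' @return a smoothed [TwoChannelStack-class].
#' @export
smoothStack <- function(stack, window = 11) {
  nf <- nFrames(stack)
  hi <- .shrinkHalfwidth(nf, window)
  if (window == 1L) return(stack)
  d <- dim(stack@yellow)
  npix <- d[1L] * d[2L]
  mask <- validMask(stack)
  V <- if (is.null(mask)) NULL else matrix(as.numeric(mask), npix, nf)
  smoothOne <- function(A) {
    M <- matrix(A, npix, nf)
    if (is.null(V)) {
      S <- .boxcarFrameSums(M, hi)
      sweep(S, 2L, 2 * hi + 1, "/")
    } else {
      S <- .boxcarFrameSums(M * V, hi)
      SV <- .boxcarFrameSums(V, hi)
      out <- S / SV
      out[SV == 0] <- 0
      out
    }
  }
  yellow <- array(smoothOne(stack@yellow), d)
  blue <- array(smoothOne(stack@blue), d)
  newMask <- if (is.null(V)) stack@validMask else {
    SV <- .boxcarFrameSums(V, hi)
    array(SV > 0, d)
  }
  prov <- stack@provenance
  prov$smoothWindow <- window
  new("TwoChannelStack", yellow = yellow, blue = blue, times = stack@times,
      validMask = newMask, pixelSize = stack@pixelSize, provenance = prov)
}

#' Segment bright ROIs from a mean image
#'
#' Thresholds the image at an intensity quantile, labels connected
#' components, discards components smaller than `minPixels`, and relabels
#' the survivors deterministically by their centroid position (row, then
#' column).
#'
#' @param meanImage numeric matrix (e.g. the time-mean of a channel).
#' @param thresholdQuantile intensity quantile used as threshold.
#' @param minPixels minimum accepted component size.
#' @return a [ROISet-class]; empty (with a warning) if nothing survives.
#' @export
segmentRois <- function(meanImage, thresholdQuantile = 0.95, minPixels = 20) {
  if (any(!is.finite(meanImage))) stop("mean image must be finite")
  th <- stats::quantile(meanImage, thresholdQuantile, names = FALSE)
  bw <- meanImage > th
  lab <- EBImage::bwlabel(bw)
  lab <- matrix(as.integer(round(lab)), nrow(bw), ncol(bw))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minPixels)
  if (!length(keep)) {
    warning("no components survive the size filter; empty ROI set")
    return(new("ROISet", labels = matrix(0L, nrow(bw), ncol(bw)),
               meta = data.frame(cell = integer(0)), minPixels = minPixels))
  }
  cent <- t(vapply(keep, function(k) {
    idx <- which(lab == k)
    r <- (idx - 1L) %% nrow(lab) + 1L
    c <- (idx - 1L) %/% nrow(lab) + 1L
    c(mean(r), mean(c))
  }, numeric(2L)))
  ord <- keep[order(cent[, 1L], cent[, 2L])]
  out <- matrix(0L, nrow(bw), ncol(bw))
  for (i in seq_along(ord)) out[lab == ord[i]] <- i
  new("ROISet", labels = out,
      meta = data.frame(cell = seq_along(ord),
                        nPixels = sizes[ord]),
      minPixels = minPixels)
}

#' Mean-then-divide ROI ratio extraction
#'
#' For every ROI and frame the ratio is the mean of the valid yellow
#' (acceptor) pixels divided by the mean of the valid blue (donor) pixels
#' — channel means first, division second, never a mean of per-pixel
#' ratios. By default the image stack is boxcar-smoothed before extraction
#' (the pipeline order is: motion correction, temporal smoothing, then
#' ratiometry); `smoothImages = FALSE` instead smooths the extracted
#' trace, which is equivalent for fully valid ROIs since both operations
#' are linear per channel only when validity does not vary — the image
#' path is the reference behaviour.
#'
#' Frames in which fewer than `minValidFrac` of the ROI pixels are valid
#' are marked missing (`NA`) and excluded from all downstream fits; they
#' are never interpolated.
#'
#' @param stack a (typically registered) [TwoChannelStack-class].
#' @param rois a [ROISet-class]; labels must match the frame size.
#' @param smoothWindow odd boxcar window in frames (default 11).
#' @param smoothImages smooth the images (default) or the extracted trace.
#' @param minValidFrac minimum valid-pixel fraction per frame.
#' @param backgroundOffset counts subtracted from each channel mean before
#'   division (e.g. a background-ROI estimate); 0 by default — no
#'   background subtraction is applied unless requested.
#' @return list of raw [RatioTrace-class], one per ROI.
#' @export
extractRatio <- function(stack, rois, smoothWindow = 11,
                         smoothImages = TRUE, minValidFrac = 0.5,
                         backgroundOffset = 0) {
  labels <- roiLabels(rois)
  d <- dim(stack@yellow)
  if (!identical(dim(labels), d[1:2]))
    stop("ROI label image does not match the frame size")
  ids <- roiMeta(rois)$cell
  present <- unique(as.integer(labels[labels > 0L]))
  if (!all(ids %in% present)) stop("unknown ROI label in metadata")

  rawMask <- validMask(stack)
  nf <- d[3L]; npix <- d[1L] * d[2L]

  ## work only on the union of ROI pixels: temporal smoothing is a
  ## per-pixel operation, so restricting it to these rows is identical to
  ## smoothing the full stack and then extracting
  idxList <- lapply(ids, function(id) which(labels == id))
  allIdx <- sort(unique(unlist(idxList)))
  sub <- function(A) {
    dim(A) <- c(npix, nf)
    A[allIdx, , drop = FALSE]
  }
  Y <- sub(stack@yellow)
  B <- sub(stack@blue)
  RawV <- if (is.null(rawMask)) NULL else sub(rawMask * 1)
  if (smoothWindow > 1 && smoothImages) {
    hi <- .shrinkHalfwidth(nf, smoothWindow)
    if (is.null(RawV)) {
      Y <- sweep(.boxcarFrameSums(Y, hi), 2L, 2 * hi + 1, "/")
      B <- sweep(.boxcarFrameSums(B, hi), 2L, 2 * hi + 1, "/")
      Vm <- NULL
    } else {
      SV <- .boxcarFrameSums(RawV, hi)
      Y <- .boxcarFrameSums(Y * RawV, hi) / SV
      B <- .boxcarFrameSums(B * RawV, hi) / SV
      Y[SV == 0] <- 0; B[SV == 0] <- 0
      Vm <- (SV > 0) * 1
    }
  } else {
    Vm <- RawV
  }

  lapply(seq_along(ids), function(i) {
    idx <- idxList[[i]]
    id <- ids[i]
    rows <- match(idx, allIdx)
    if (is.null(Vm)) {
      sy <- colSums(Y[rows, , drop = FALSE])
      sb <- colSums(B[rows, , drop = FALSE])
      nv <- rep(length(idx), nf)
    } else {
      W <- Vm[rows, , drop = FALSE]
      sy <- colSums(Y[rows, , drop = FALSE] * W)
      sb <- colSums(B[rows, , drop = FALSE] * W)
      nv <- colSums(W)
    }
    nRaw <- if (is.null(RawV)) rep(length(idx), nf)
            else colSums(RawV[rows, , drop = FALSE])
    ratio <- (sy / nv - backgroundOffset) / (sb / nv - backgroundOffset)
    bad <- nv < 1 | nRaw < minValidFrac * length(idx)
    nonpos <- !bad & (sb / nv - backgroundOffset) <= 0
    if (any(nonpos)) {
      warning("non-positive donor mean in ", sum(nonpos),
              " frame(s) of ROI ", id, "; marked missing")
      bad <- bad | nonpos
    }
    ratio[bad] <- NA_real_
    if (smoothWindow > 1 && !smoothImages)
      ratio <- boxcarSmooth(ratio, smoothWindow)
    m <- roiMeta(rois)[i, , drop = FALSE]
    new("RatioTrace", times = stack@times, ratio = ratio,
        nValid = as.integer(round(nRaw)), meta = as.list(m),
        window = smoothWindow, normalized = FALSE, normFactor = NA_real_)
  })
}
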
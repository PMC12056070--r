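#' @include AllClasses.R
NULL

#' Translate an image by a (possibly fractional) rigid shift
#'
#' Moves image content by `+dx` columns and `+dy` rows using bilinear
#' interpolation. Output pixels whose source lies outside the input frame
#' are set to `fill` and reported invalid.
#'
#' @param img numeric matrix.
#' @param dx,dy shift in pixels (columns, rows).
#' @param fill value for pixels sourced from outside the frame.
#' @return list with `img` (shifted matrix) and `valid` (logical matrix).
#' @export
translateImage <- function(img, dx, dy, fill = NA_real_) {
  nr <- nrow(img); nc <- ncol(img)
  sr <- seq_len(nr) - dy
  sc <- seq_len(nc) - dx
  r0 <- floor(sr); wr <- sr - r0
  c0 <- floor(sc); wc <- sc - c0
  r0c <- pmin(pmax(r0, 1L), nr); r1c <- pmin(pmax(r0 + 1L, 1L), nr)
  c0c <- pmin(pmax(c0, 1L), nc); c1c <- pmin(pmax(c0 + 1L, 1L), nc)
  out <- img[r0c, c0c, drop = FALSE] * ((1 - wr) %o% (1 - wc)) +
    img[r1c, c0c, drop = FALSE] * (wr %o% (1 - wc)) +
    img[r0c, c1c, drop = FALSE] * ((1 - wr) %o% wc) +
    img[r1c, c1c, drop = FALSE] * (wr %o% wc)
  valid <- outer(sr >= 1 - 1e-9 & sr <= nr + 1e-9,
                 sc >= 1 - 1e-9 & sc <= nc + 1e-9, "&")
  out[!valid] <- fill
  list(img = out, valid = valid)
}

## Signed FFT frequency indices for length n.
.fftFreqIdx <- function(n) {
  u <- 0:(n - 1)
  u[u > n / 2] <- u[u > n / 2] - n
  u
}

## Evaluate the cross-correlation surface of the spectral product P at
## fractional lags (rs, cs) via a matrix-multiply inverse DFT.
.upsampledCorr <- function(P, rs, cs) {
  nr <- nrow(P); nc <- ncol(P)
  fu <- .fftFreqIdx(nr); fv <- .fftFreqIdx(nc)
  kr <- exp(2i * pi * outer(rs, fu) / nr)
  kc <- exp(2i * pi * outer(fv, cs) / nc)
  Re(kr %*% P %*% kc) / (nr * nc)
}

#' Estimate per-frame rigid shifts by cross-correlation
#'
#' Correlation-based motion estimation: each frame's summed-channel image
#' (yellow + blue, higher SNR than either channel and shared motion) is
#' cross-correlated against a template built as the mean of the reference
#' frames. Both are mean-subtracted so the broad background does not
#' dominate the correlation. The integer peak (searched within
#' `maxShift`) is refined to `1/subpixelFactor` pixel by sampling the
#' correlation surface on an upsampled grid around the peak via a
#' matrix-multiply DFT. Ties are broken toward the smaller absolute shift.
#'
#' @param stack a [TwoChannelStack-class].
#' @param reference integer indices of frames averaged into the template.
#' @param subpixelFactor integer >= 1; 1 gives integer-pixel shifts.
#' @param maxShift search bound in pixels.
#' @param lowConfThreshold normalized-correlation value below which a frame
#'   is flagged low-confidence.
#' @return a [ShiftSeries-class]; `dx`, `dy` are the estimated motion of
#'   each frame relative to the template (content displacement).
#' @export
estimateShifts <- function(stack, reference = 1:10, subpixelFactor = 1,
                           maxShift = 20, lowConfThreshold = 0.3) {
  nf <- nFrames(stack)
  reference <- reference[reference >= 1 & reference <= nf]
  if (!length(reference)) stop("reference frames do not exist in the stack")
  if (subpixelFactor < 1 || subpixelFactor != round(subpixelFactor))
    stop("subpixelFactor must be a positive integer")
  nr <- dim(stack@yellow)[1L]; nc <- dim(stack@yellow)[2L]
  maxShift <- min(maxShift, floor(nr / 2) - 1, floor(nc / 2) - 1)

  summed <- stack@yellow + stack@blue
  template <- apply(summed[, , reference, drop = FALSE], c(1, 2), mean)
  template <- template - mean(template)
  tNorm <- sqrt(sum(template^2))
  FT <- Conj(stats::fft(template))

  u <- .fftFreqIdx(nr); v <- .fftFreqIdx(nc)
  rowsOk <- which(abs(u) <= maxShift)
  colsOk <- which(abs(v) <= maxShift)

  dx <- numeric(nf); dy <- numeric(nf); peak <- numeric(nf)
  low <- logical(nf)
  prev <- c(0, 0)
  for (f in seq_len(nf)) {
    frame <- summed[, , f]
    if (stats::sd(frame) == 0) {
      warning("frame ", f, " has no structure; carrying previous shift")
      dx[f] <- prev[1L]; dy[f] <- prev[2L]
      peak[f] <- 0; low[f] <- TRUE
      next
    }
    frame <- frame - mean(frame)
    P <- stats::fft(frame) * FT
    cc <- Re(stats::fft(P, inverse = TRUE)) / (nr * nc)
    sub <- cc[rowsOk, colsOk, drop = FALSE]
    m <- max(sub)
    cand <- which(sub >= m - 1e-9 * abs(m), arr.ind = TRUE)
    d2 <- u[rowsOk[cand[, 1L]]]^2 + v[colsOk[cand[, 2L]]]^2
    best <- cand[which.min(d2), , drop = FALSE]
    dyF <- u[rowsOk[best[1L, 1L]]]
    dxF <- v[colsOk[best[1L, 2L]]]
    pk <- m
    if (subpixelFactor > 1) {
      k <- ceiling(0.75 * subpixelFactor)
      offs <- (-k:k) / subpixelFactor
      ccUp <- .upsampledCorr(P, dyF + offs, dxF + offs)
      mu <- max(ccUp)
      candU <- which(ccUp >= mu - 1e-12 * abs(mu), arr.ind = TRUE)
      d2u <- (dyF + offs[candU[, 1L]])^2 + (dxF + offs[candU[, 2L]])^2
      bu <- candU[which.min(d2u), , drop = FALSE]
      dyF <- dyF + offs[bu[1L, 1L]]
      dxF <- dxF + offs[bu[1L, 2L]]
      pk <- mu
    }
    dxF <- max(min(dxF, maxShift), -maxShift)
    dyF <- max(min(dyF, maxShift), -maxShift)
    fNorm <- sqrt(sum(frame^2))
    peak[f] <- pk / (tNorm * fNorm)
    low[f] <- peak[f] < lowConfThreshold
    dx[f] <- dxF; dy[f] <- dyF
    prev <- c(dxF, dyF)
  }
  new("ShiftSeries",
      shifts = data.frame(frame = seq_len(nf), dx = dx, dy = dy,
                          peak = peak, lowConf = low),
      reference = as.integer(reference), maxShift = maxShift)
}

#' Undo estimated motion on both channels
#'
#' Applies the negated shifts to the yellow and blue channels with the
#' identical transform (ratio integrity), using bilinear interpolation for
#' fractional shifts. Pixels sourced from outside the frame are marked
#' invalid in the validity mask and excluded from downstream ROI means;
#' they are never zero-filled into statistics. Frame count and timestamps
#' are unchanged.
#'
#' @param stack a [TwoChannelStack-class].
#' @param shifts a [ShiftSeries-class] from [estimateShifts()].
#' @return a registered [TwoChannelStack-class].
#' @export
applyShifts <- function(stack, shifts) {
  s <- shiftTable(shifts)
  nf <- nFrames(stack)
  if (nrow(s) != nf) stop("shift series length does not match the stack")
  nr <- dim(stack@yellow)[1L]; nc <- dim(stack@yellow)[2L]
  yellow <- stack@yellow; blue <- stack@blue
  oldMask <- validMask(stack)
  mask <- array(TRUE, dim = dim(yellow))
  for (f in seq_len(nf)) {
    if (s$dx[f] == 0 && s$dy[f] == 0) {
      if (!is.null(oldMask)) mask[, , f] <- oldMask[, , f]
      next
    }
    ty <- translateImage(yellow[, , f], -s$dx[f], -s$dy[f], fill = 0)
    tb <- translateImage(blue[, , f], -s$dx[f], -s$dy[f], fill = 0)
    yellow[, , f] <- ty$img
    blue[, , f] <- tb$img
    v <- ty$valid
    if (!is.null(oldMask)) {
      tm <- translateImage(oldMask[, , f] * 1, -s$dx[f], -s$dy[f], fill = 0)
      v <- v & tm$img > 0.999
    }
    mask[, , f] <- v
  }
  prov <- stack@provenance
  prov$registered <- TRUE
  new("TwoChannelStack", yellow = yellow, blue = blue, times = stack@times,
      validMask = mask, pixelSize = stack@pixelSize, provenance = prov)
}

#' Estimate and apply motion correction in one call
#'
#' @inheritParams estimateShifts
#' @return list with `stack` (registered [TwoChannelStack-class]) and
#'   `shifts` (the [ShiftSeries-class]).
#' @export
registerStack <- function(stack, reference = 1:10, subpixelFactor = 10,
                          maxShift = 20, lowConfThreshold = 0.3) {
  sh <- estimateShifts(stack, reference = reference,
                       subpixelFactor = subpixelFactor, maxShift = maxShift,
                       lowConfThreshold = lowConfThreshold)
  list(stack = applyShifts(stack, sh), shifts = sh)
}
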
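#' @include AllClasses.R
NULL

#' Accessors for glucoFRET objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a glucoFRET S4 object.
#' @return `epochs()` a data.frame of protocol epochs; `nFrames()` an
#'   integer; `frameTimes()` numeric minutes; `validMask()` a logical array
#'   or `NULL`; `shiftTable()` a data.frame of per-frame shifts;
#'   `roiLabels()` an integer label matrix; `roiMeta()` a data.frame;
#'   `traceMeta()` a list.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("epochs", function(object) standardGeneric("epochs"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("shiftTable", function(object) standardGeneric("shiftTable"))

#' @rdname accessors
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))

#' @rdname accessors
#' @export
setGeneric("roiMeta", function(object) standardGeneric("roiMeta"))

#' @rdname accessors
#' @export
setGeneric("traceMeta", function(object) standardGeneric("traceMeta"))

#' @rdname accessors
#' @export
setMethod("epochs", "FretProtocol", function(object) object@epochs)

#' @rdname accessors
#' @export
setMethod("nFrames", "TwoChannelStack", function(object) dim(object@yellow)[3L])

#' @rdname accessors
#' @export
setMethod("frameTimes", "TwoChannelStack", function(object) object@times)

#' @rdname accessors
#' @export
setMethod("validMask", "TwoChannelStack", function(object) {
  if (length(object@validMask)) object@validMask else NULL
})

#' @rdname accessors
#' @export
setMethod("shiftTable", "ShiftSeries", function(object) object@shifts)

#' @rdname accessors
#' @export
setMethod("roiLabels", "ROISet", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("roiMeta", "ROISet", function(object) object@meta)

#' @rdname accessors
#' @export
setMethod("traceMeta", "RatioTrace", function(object) object@meta)

#' Extract a channel from a two-channel stack
#'
#' @param object a [TwoChannelStack-class].
#' @param which `"yellow"` (acceptor) or `"blue"` (donor).
#' @return numeric array (rows, cols, frames).
#' @export
setGeneric("channelFrames",
           function(object, which = c("yellow", "blue"))
             standardGeneric("channelFrames"))

#' @rdname channelFrames
#' @export
setMethod("channelFrames", "TwoChannelStack", function(object, which) {
  which <- match.arg(which, c("yellow", "blue"))
  slot(object, which)
})

setMethod("show", "FretProtocol", function(object) {
  e <- object@epochs
  cat(sprintf("FretProtocol with %d epoch(s), %.1f-%.1f min\n",
              nrow(e), min(e$tStart), max(e$tEnd)))
  print(e, row.names = FALSE)
})

setMethod("show", "SensorParams", function(object) {
  cat(sprintf("SensorParams: Kd = %.3g mM, Rmin = %.3g, Rmax = %.3g\n",
              object@Kd, object@Rmin, object@Rmax))
})

setMethod("show", "CellPhysiology", function(object) {
  cat(sprintf(paste0("CellPhysiology: VmaxT = %.4g, KmT = %.3g, ",
                     "Vhk = %.4g, KmHk = %.3g mM; gNet = %.3g /min; ",
                     "glc0 = %.3g mM\n"),
              object@VmaxT, object@KmT, object@Vhk, object@KmHk,
              object@gNet, object@glc0))
})

setMethod("show", "GlucoseTrajectory", function(object) {
  cat(sprintf("GlucoseTrajectory: %d points, %.1f-%.1f min, [Glc]i %.3g-%.3g mM\n",
              length(object@times), min(object@times), max(object@times),
              min(object@glc), max(object@glc)))
})

setMethod("show", "FretScene", function(object) {
  cat(sprintf(paste0("FretScene: %dx%d px (%.2f um/px), %d cell(s), ",
                     "frame period %.2g s, %d frame(s)\n"),
              object@frameShape[1L], object@frameShape[2L], object@pixelSize,
              nrow(object@cells), object@framePeriod, nrow(object@motionPath)))
})

setMethod("show", "TwoChannelStack", function(object) {
  d <- dim(object@yellow)
  cat(sprintf("TwoChannelStack: %dx%d px, %d frames, %.1f-%.1f min\n",
              d[1L], d[2L], d[3L], min(object@times), max(object@times)))
  if (length(object@validMask))
    cat(sprintf("  valid pixels: %.1f%%\n", 100 * mean(object@validMask)))
})

setMethod("show", "ShiftSeries", function(object) {
  s <- object@shifts
  cat(sprintf("ShiftSeries: %d frames, |shift| max %.2f px, %d low-confidence\n",
              nrow(s), max(abs(c(s$dx, s$dy))), sum(s$lowConf)))
})

setMethod("show", "ROISet", function(object) {
  cat(sprintf("ROISet: %d ROI(s) on a %dx%d label image\n",
              nrow(object@meta), nrow(object@labels), ncol(object@labels)))
})

setMethod("show", "RatioTrace", function(object) {
  cat(sprintf("RatioTrace (%s): %d frames, %d missing%s\n",
              if (object@normalized) "normalized" else "raw",
              length(object@ratio), sum(is.na(object@ratio)),
              if (length(object@meta$cell))
                sprintf(", cell %s", object@meta$cell) else ""))
})

setMethod("show", "KineticsConfig", function(object) {
  cat(sprintf(paste0("KineticsConfig: minWindow %.3g, washinDelay %.3g, ",
                     "consumptionFitSpan %.3g, plateauWindow %.3g, ",
                     "baselineWindow %.3g min; rise bounds %.0f-%.0f%%\n"),
              object@minWindow, object@washinDelay, object@consumptionFitSpan,
              object@plateauWindow, object@baselineWindow,
              100 * object@riseFitBounds[1L], 100 * object@riseFitBounds[2L]))
})
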
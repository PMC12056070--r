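#' @import methods
NULL

## Central S4 containers for the simulation + analysis pipeline.
## Conventions used throughout the package:
##   - images are numeric matrices indexed [row, col] = [y, x], 1-based,
##     with pixel centers at integer coordinates;
##   - a shift (dx, dy) moves image content by +dx columns and +dy rows;
##   - time is in minutes, frame period in seconds, glucose in mM.

#' Experimental protocol of perfusion epochs
#'
#' Ordered, non-overlapping epochs, each with a name, start/end time
#' (minutes), extracellular glucose concentration (mM) and drug flags:
#' `cytoB` (glucose transport blocked by cytochalasin B) and `cbx`
#' (gap-junction/hemichannel coupling blocked by carbenoxolone).
#'
#' @slot epochs data.frame with columns `name`, `tStart`, `tEnd`,
#'   `glcOut`, `cytoB`, `cbx`.
#' @seealso [buildProtocol()], [standardProtocol()]
#' @exportClass FretProtocol
setClass("FretProtocol", slots = c(epochs = "data.frame"))

setValidity("FretProtocol", function(object) {
  e <- object@epochs
  need <- c("name", "tStart", "tEnd", "glcOut", "cytoB", "cbx")
  if (!all(need %in% names(e)))
    return(paste("epochs must have columns:", paste(need, collapse = ", ")))
  if (nrow(e) < 1L) return("protocol needs at least one epoch")
  if (any(e$tEnd <= e$tStart)) return("each epoch must satisfy tEnd > tStart")
  if (any(e$glcOut < 0)) return("extracellular glucose must be >= 0")
  if (is.unsorted(e$tStart, strictly = TRUE))
    return("epochs must be strictly ordered by tStart")
  if (nrow(e) > 1L && any(e$tStart[-1L] < e$tEnd[-nrow(e)] - 1e-9))
    return("epochs must not overlap")
  TRUE
})

#' Single-site FRET sensor parameters
#'
#' One-site binding model for a ratiometric glucose sensor:
#' \eqn{R(g) = R_{min} + (R_{max}-R_{min})\, g/(K_d+g)}.
#'
#' @slot Kd half-saturation glucose concentration (mM).
#' @slot Rmin ratio at zero glucose.
#' @slot Rmax ratio at saturation.
#' @exportClass SensorParams
setClass("SensorParams",
         slots = c(Kd = "numeric", Rmin = "numeric", Rmax = "numeric"))

setValidity("SensorParams", function(object) {
  if (length(object@Kd) != 1L || object@Kd <= 0) return("Kd must be a single value > 0")
  if (object@Rmin <= 0) return("Rmin must be > 0")
  if (object@Rmax <= object@Rmin) return("Rmax must exceed Rmin")
  TRUE
})

#' Single-cell glucose handling parameters
#'
#' Parameters of the cytosolic glucose balance
#' \eqn{d[Glc]_i/dt = T + X - C} with facilitated transport
#' \eqn{T = V_{max,T}(S(g_o) - S(g_i))}, \eqn{S(g)=g/(K_{m,T}+g)},
#' network exchange \eqn{X = g_{net}([Glc]_{net} - g_i)} and
#' Michaelis-Menten consumption \eqn{C = V_{hk}\, g_i/(K_{m,hk}+g_i)}.
#'
#' @slot VmaxT maximal transport rate (mM/min).
#' @slot KmT transporter half-saturation, same on both membrane faces (mM).
#' @slot Vhk maximal consumption (hexokinase) rate (mM/min).
#' @slot KmHk consumption half-saturation (mM).
#' @slot gNet lumped network-exchange conductance (1/min); zeroed under CBX.
#' @slot glc0 initial cytosolic glucose (mM).
#' @exportClass CellPhysiology
setClass("CellPhysiology",
         slots = c(VmaxT = "numeric", KmT = "numeric", Vhk = "numeric",
                   KmHk = "numeric", gNet = "numeric", glc0 = "numeric"))

setValidity("CellPhysiology", function(object) {
  v <- c(object@VmaxT, object@KmT, object@Vhk, object@KmHk,
         object@gNet, object@glc0)
  if (length(v) != 6L || any(!is.finite(v))) return("all parameters must be finite scalars")
  if (any(v < 0)) return("all parameters must be >= 0")
  if (object@KmT <= 0) return("KmT must be > 0")
  if (object@KmHk <= 0) return("KmHk must be > 0")
  TRUE
})

#' Ground-truth cytosolic glucose trajectory
#'
#' @slot times minutes.
#' @slot glc cytosolic glucose (mM) at each time point.
#' @slot phys generating [CellPhysiology-class] parameters.
#' @slot protocol generating [FretProtocol-class].
#' @exportClass GlucoseTrajectory
setClass("GlucoseTrajectory",
         slots = c(times = "numeric", glc = "numeric",
                   phys = "CellPhysiology", protocol = "FretProtocol"))

setValidity("GlucoseTrajectory", function(object) {
  if (length(object@times) != length(object@glc))
    return("times and glc must have the same length")
  if (any(object@glc < 0)) return("glc must be >= 0 everywhere")
  if (is.unsorted(object@times)) return("times must be non-decreasing")
  TRUE
})

#' Imaging scene description for the renderer
#'
#' @slot frameShape integer (rows, cols) of each frame.
#' @slot pixelSize micrometres per pixel.
#' @slot cells data.frame with per-cell `x`, `y` (px, centre), `radius` (px)
#'   and `brightness` (pre-noise counts summed over both channels).
#' @slot background counts added to both channels.
#' @slot framePeriod seconds between frames.
#' @slot motionPath nFrames x 2 matrix of (dx, dy) pixel offsets applied to
#'   every frame (rigid lateral drift).
#' @slot shotNoise logical; Poisson shot noise on.
#' @slot readNoiseSd Gaussian read-noise standard deviation (counts).
#' @slot seed integer seed recorded for provenance.
#' @exportClass FretScene
setClass("FretScene",
         slots = c(frameShape = "integer", pixelSize = "numeric",
                   cells = "data.frame", background = "numeric",
                   framePeriod = "numeric", motionPath = "matrix",
                   shotNoise = "logical", readNoiseSd = "numeric",
                   seed = "integer"))

setValidity("FretScene", function(object) {
  if (length(object@frameShape) != 2L || any(object@frameShape < 8L))
    return("frameShape must be two integers >= 8")
  if (object@framePeriod <= 0) return("framePeriod must be > 0")
  need <- c("x", "y", "radius", "brightness")
  if (!all(need %in% names(object@cells)))
    return(paste("cells must have columns:", paste(need, collapse = ", ")))
  if (ncol(object@motionPath) != 2L) return("motionPath must have 2 columns")
  TRUE
})

#' Two-channel (acceptor/donor) image time series
#'
#' Acceptor ("yellow", 545/55 nm band) and donor ("blue", 475/50 nm band)
#' frames with timestamps and a per-pixel validity mask. An empty
#' `validMask` (length 0) means all pixels are valid.
#'
#' @slot yellow numeric array (rows, cols, frames), acceptor channel.
#' @slot blue numeric array of identical shape, donor channel.
#' @slot times frame timestamps in minutes.
#' @slot validMask logical array of identical shape, or `logical(0)`.
#' @slot pixelSize micrometres per pixel.
#' @slot provenance list (seed, scene digest, processing steps).
#' @exportClass TwoChannelStack
setClass("TwoChannelStack",
         slots = c(yellow = "array", blue = "array", times = "numeric",
                   validMask = "array", pixelSize = "numeric",
                   provenance = "list"))

setValidity("TwoChannelStack", function(object) {
  dy <- dim(object@yellow); db <- dim(object@blue)
  if (length(dy) != 3L) return("yellow must be a 3-d array (rows, cols, frames)")
  if (!identical(dy, db)) return("yellow and blue must have identical shape")
  if (length(object@times) != dy[3L])
    return("times length must equal the number of frames")
  if (length(object@validMask) &&
      !identical(dim(object@validMask), dy))
    return("validMask must match channel shape (or be empty)")
  TRUE
})

#' Per-frame rigid shifts estimated by registration
#'
#' @slot shifts data.frame with columns `frame`, `dx`, `dy`, `peak`
#'   (normalized correlation at the optimum) and `lowConf`.
#' @slot reference integer indices of the template frames.
#' @slot maxShift search bound (px).
#' @exportClass ShiftSeries
setClass("ShiftSeries",
         slots = c(shifts = "data.frame", reference = "integer",
                   maxShift = "numeric"))

setValidity("ShiftSeries", function(object) {
  s <- object@shifts
  need <- c("frame", "dx", "dy", "peak", "lowConf")
  if (!all(need %in% names(s)))
    return(paste("shifts must have columns:", paste(need, collapse = ", ")))
  if (any(!is.finite(s$dx)) || any(!is.finite(s$dy)))
    return("shifts must be finite")
  if (any(abs(c(s$dx, s$dy)) > object@maxShift + 1e-9))
    return("shifts exceed maxShift")
  TRUE
})

#' ROI label image with per-cell nesting metadata
#'
#' @slot labels integer matrix; 0 = background, k = cell k.
#' @slot meta data.frame with one row per cell (`cell`, and where known
#'   `slice`, `animal`, `genotype`, plus any ground-truth columns).
#' @slot minPixels minimum accepted ROI size used when building the set.
#' @exportClass ROISet
setClass("ROISet",
         slots = c(labels = "matrix", meta = "data.frame",
                   minPixels = "numeric"))

setValidity("ROISet", function(object) {
  lab <- object@labels
  if (any(lab < 0) || any(lab != round(lab)))
    return("labels must be non-negative integers")
  ids <- sort(unique(as.integer(lab[lab > 0])))
  if (!("cell" %in% names(object@meta))) return("meta must have a 'cell' column")
  if (!all(object@meta$cell %in% ids))
    return("every cell id in meta must appear in the label image")
  TRUE
})

#' Per-cell ratio time series
#'
#' Acceptor/donor ratio per frame for one ROI, raw or minimum-normalized.
#' Missing frames (too few valid pixels, or non-positive donor signal)
#' are `NA` and are excluded from all downstream fits.
#'
#' @slot times minutes.
#' @slot ratio per-frame mean(yellow)/mean(blue); NA where missing.
#' @slot nValid number of valid ROI pixels per frame.
#' @slot meta list of nesting metadata (cell, slice, animal, genotype, ...).
#' @slot window boxcar smoothing window (frames) applied upstream.
#' @slot normalized logical; TRUE once normalized to the aglycemia minimum.
#' @slot normFactor the raw-ratio minimum used for normalization (NA if raw).
#' @exportClass RatioTrace
setClass("RatioTrace",
         slots = c(times = "numeric", ratio = "numeric", nValid = "integer",
                   meta = "list", window = "numeric", normalized = "logical",
                   normFactor = "numeric"))

setValidity("RatioTrace", function(object) {
  if (length(object@times) != length(object@ratio))
    return("times and ratio must have the same length")
  if (length(object@nValid) && length(object@nValid) != length(object@ratio))
    return("nValid must match ratio length")
  ok <- object@ratio[!is.na(object@ratio)]
  if (any(ok <= 0)) return("defined ratios must be > 0")
  TRUE
})

#' Configuration of the kinetic estimators
#'
#' All windows in minutes. Defaults follow the package's declared
#' conventions: see the methods vignette for rationale.
#'
#' @slot minWindow length of the aglycemia tail averaged for the one-point
#'   minimum (default 2).
#' @slot washinDelay time skipped after a drug epoch starts (default 1).
#' @slot consumptionFitSpan length of the transport-stop fit window
#'   (default 5).
#' @slot riseFitBounds fraction-of-plateau pair for the rise fit
#'   (default c(0.2, 0.8)).
#' @slot plateauWindow tail of the step epoch averaged as plateau (default 2).
#' @slot baselineWindow tail of the baseline epoch averaged as baseline
#'   (default 2).
#' @exportClass KineticsConfig
setClass("KineticsConfig",
         slots = c(minWindow = "numeric", washinDelay = "numeric",
                   consumptionFitSpan = "numeric", riseFitBounds = "numeric",
                   plateauWindow = "numeric", baselineWindow = "numeric"))

setValidity("KineticsConfig", function(object) {
  w <- c(object@minWindow, object@washinDelay, object@consumptionFitSpan,
         object@plateauWindow, object@baselineWindow)
  if (any(!is.finite(w)) || any(w[-2L] <= 0) || object@washinDelay < 0)
    return("windows must be positive (washinDelay may be 0)")
  b <- object@riseFitBounds
  if (length(b) != 2L || b[1L] <= 0 || b[2L] >= 1 || b[1L] >= b[2L])
    return("riseFitBounds must satisfy 0 < lower < upper < 1")
  TRUE
})
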
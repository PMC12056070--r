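#' @include AllClasses.R simulate.R kinetics.R
NULL

## Transport Vmax that puts the resting cytosolic glucose at baselineGlc
## for a given consumption capacity (uncoupled cell, gNet = 0).
.transportVmaxFor <- function(Vhk, KmHk, baselineGlc, glcOut, KmT) {
  dS <- glcOut / (KmT + glcOut) - baselineGlc / (KmT + baselineGlc)
  if (dS <= 0) stop("baseline glucose must be below the transport equilibrium")
  (Vhk * baselineGlc / (KmHk + baselineGlc)) / dS
}

## OLS slope of the minimum-normalized noiseless trace over the
## transport-stop fit window, for a candidate Vhk (positive = decline).
## The trace is taken through the same measurement model the imaging
## pipeline applies to a rendered cell: per-channel intensities including
## the (unsubtracted) background, channel-wise boxcar smoothing, then the
## quotient of channel means. For background = 0 and window = 1 this
## reduces to sensorResponse() of the trajectory.
.noiselessConsumptionSlope <- function(Vhk, baselineGlc, sensor, protocol,
                                       cfg, KmT, KmHk, framePeriod, dt,
                                       background = 20, brightness = 300,
                                       smoothWindow = 11) {
  e <- epochs(protocol)
  glcOut0 <- e$glcOut[1L]
  VmaxT <- .transportVmaxFor(Vhk, KmHk, baselineGlc, glcOut0, KmT)
  phys <- cellPhysiology(VmaxT = VmaxT, KmT = KmT, Vhk = Vhk, KmHk = KmHk,
                         gNet = 0, glc0 = baselineGlc)
  traj <- simulateCellGlucose(phys, protocol, dt = dt)
  times <- seq(min(traj@times), max(traj@times), by = framePeriod / 60)
  trace <- noiselessPipelineTrace(traj, sensor, times = times,
                                  background = background,
                                  brightness = brightness,
                                  smoothWindow = smoothWindow)
  norm <- normalizeToMin(trace, protocol, cfg)
  est <- estimateConsumptionRate(norm, protocol, cfg)
  -est$rate
}

#' Noiseless pipeline read-out of a ground-truth trajectory
#'
#' The exact ratio trace the imaging pipeline recovers from a uniform,
#' motion-free, noise-free rendered cell: donor and acceptor channel
#' intensities are formed with the (unsubtracted) background offset,
#' boxcar-smoothed per channel, and divided (mean-then-divide). This is
#' the measurement-model reference used by
#' [calibrateConsumptionPreset()]; with `background = 0` and
#' `smoothWindow = 1` it equals [traceFromTrajectory()].
#'
#' @param traj a [GlucoseTrajectory-class].
#' @param sensor a [SensorParams-class].
#' @param times output frame times (minutes).
#' @param background background counts per channel.
#' @param brightness cell brightness (summed-channel counts).
#' @param smoothWindow boxcar window in frames.
#' @param meta metadata list for the trace.
#' @return a raw [RatioTrace-class].
#' @export
noiselessPipelineTrace <- function(traj, sensor = sensorParams(),
                                   times = NULL, background = 20,
                                   brightness = 300, smoothWindow = 11,
                                   meta = list()) {
  if (is.null(times)) times <- traj@times
  g <- stats::approx(traj@times, traj@glc, xout = times, rule = 2)$y
  R <- sensorResponse(g, sensor)
  y <- background + brightness * R / (1 + R)
  b <- background + brightness / (1 + R)
  if (smoothWindow > 1) {
    y <- boxcarSmooth(y, smoothWindow)
    b <- boxcarSmooth(b, smoothWindow)
  }
  new("RatioTrace", times = times, ratio = y / b, nValid = integer(0),
      meta = meta, window = smoothWindow, normalized = FALSE,
      normFactor = NA_real_)
}

#' Calibrate the consumption capacity to a target measured decline rate
#'
#' Finds the maximal consumption rate `Vhk` (mM/min) such that the
#' transport-stop read-out of the analysis pipeline — the OLS slope of the
#' minimum-normalized ratio over the cytochalasin-B fit window — equals
#' `targetRate` on a noiseless simulation. A chain-rule tangent estimate,
#' \deqn{slope \approx \frac{dR/dg\,(g_b)\; V_{hk}\, g_b/(K_{m,hk}+g_b)}{R_{min}},}
#' seeds a bracketing root search on the actual noiseless pipeline
#' read-out, so the returned value reproduces the target by construction
#' rather than only to tangent-approximation accuracy. The transport
#' capacity is co-adjusted so the resting cytosolic glucose stays at
#' `baselineGlc` (attribute `VmaxT`).
#'
#' @param targetRate desired decline magnitude, minimum-normalized ratio
#'   units per minute; must be > 0.
#' @param baselineGlc resting cytosolic glucose (mM).
#' @param sensor a [SensorParams-class].
#' @param protocol a [FretProtocol-class] containing a cytochalasin-B and a
#'   terminal aglycemia epoch.
#' @param cfg a [KineticsConfig-class] defining the fit window.
#' @param KmT,KmHk transporter / consumption half-saturations (mM).
#' @param framePeriod imaging frame period (s) used for the noiseless
#'   check trace.
#' @param dt integration step (minutes).
#' @param background,brightness,smoothWindow measurement-model constants of
#'   the noiseless reference trace (see [noiselessPipelineTrace()]); they
#'   default to the scene and smoothing defaults of the pipeline.
#' @return `Vhk` (mM/min) with attributes `VmaxT` (mM/min) and
#'   `achievedRate` (the noiseless pipeline read-out at the returned value).
#' @export
calibrateConsumptionPreset <- function(targetRate, baselineGlc = 1.2,
                                       sensor = sensorParams(),
                                       protocol = standardProtocol(),
                                       cfg = kineticsConfig(),
                                       KmT = 2, KmHk = 0.05,
                                       framePeriod = 2, dt = 0.02,
                                       background = 20, brightness = 300,
                                       smoothWindow = 11) {
  if (!is.finite(targetRate) || targetRate <= 0)
    stop("targetRate must be > 0")
  slope0 <- sensorSlope(baselineGlc, sensor)
  if (slope0 < 1e-8)
    stop("unreachable target: sensor slope is ~0 at the baseline glucose")
  shk <- baselineGlc / (KmHk + baselineGlc)
  vhk0 <- targetRate * sensor@Rmin / (slope0 * shk)
  g <- function(v) .noiselessConsumptionSlope(v, baselineGlc, sensor,
                                              protocol, cfg, KmT, KmHk,
                                              framePeriod, dt,
                                              background, brightness,
                                              smoothWindow)
  ## The pipeline read-out is non-monotone in Vhk (at very high consumption
  ## the glucose pool empties inside the fit window and the fitted slope
  ## collapses), so bracket the target on the rising branch only.
  v <- vhk0 / 16
  prev <- g(v)
  if (prev >= targetRate) v <- v / 16
  repeat {
    v2 <- v * 1.4
    cur <- g(v2)
    if (cur >= targetRate) break
    if (cur < prev)
      stop("unreachable target: the pipeline read-out peaks at ",
           signif(prev, 3), " per minute before reaching the target")
    v <- v2; prev <- cur
  }
  vhk <- stats::uniroot(function(x) g(x) - targetRate, c(v, v2),
                        tol = vhk0 * 1e-6)$root
  achieved <- g(vhk)
  e <- epochs(protocol)
  attr(vhk, "VmaxT") <- .transportVmaxFor(vhk, KmHk, baselineGlc,
                                          e$glcOut[1L], KmT)
  attr(vhk, "achievedRate") <- achieved
  vhk
}

.presetCache <- new.env(parent = emptyenv())

## Calibration curve: monotone log-log interpolation of target rate ->
## Vhk over a span of x/÷ exp(span) around the centre target, so per-cell
## calibration costs an interpolation instead of a root search. Rates
## outside the tabulated span are clamped (≈ ±6 sd of the default
## variability). Cached per centre target.
.rateCalibrationCurve <- function(targetRate, baselineGlc = 1.2,
                                  sensor = sensorParams(),
                                  protocol = standardProtocol(),
                                  cfg = kineticsConfig(),
                                  span = 0.6, n = 9L) {
  key <- paste0("curve_", format(targetRate, digits = 12), "_",
                format(baselineGlc, digits = 12))
  if (!is.null(.presetCache[[key]])) return(.presetCache[[key]])
  rates <- targetRate * exp(seq(-span, span, length.out = n))
  vhks <- vapply(rates, function(tr) as.numeric(
    calibrateConsumptionPreset(tr, baselineGlc = baselineGlc,
                               sensor = sensor, protocol = protocol,
                               cfg = cfg)), numeric(1L))
  lr <- log(rates); lv <- log(vhks)
  sf <- stats::splinefun(lr, lv, method = "monoH.FC")
  out <- function(rate) {
    x <- pmin(pmax(log(rate), lr[1L]), lr[n])
    vhk <- exp(sf(x))
    vmax <- vapply(vhk, .transportVmaxFor, numeric(1L), KmHk = 0.05,
                   baselineGlc = baselineGlc,
                   glcOut = epochs(protocol)$glcOut[1L], KmT = 2)
    list(Vhk = vhk, VmaxT = vmax)
  }
  .presetCache[[key]] <- out
  out
}

#' Genotype physiology presets
#'
#' Cell-physiology parameter sets calibrated so the noiseless pipeline
#' read-out of the transport-stop decline equals the published group-mean
#' consumption rates: 0.030 min^-1 for control astrocytes (`"ctrl"`) and
#' 0.079 min^-1 for the GLUT1-deleted genotype (`"cko"`), in
#' minimum-normalized ratio units. Both presets rest at the same baseline
#' cytosolic glucose; the cKO preset carries proportionally higher
#' transport capacity, reflecting the higher membrane glucose permeability
#' that accompanies its higher glycolytic rate.
#'
#' @param genotype `"ctrl"` or `"cko"`.
#' @param targetRate override the calibration target (normalized units per
#'   minute).
#' @param baselineGlc resting cytosolic glucose (mM).
#' @param sensor,protocol,cfg calibration context; see
#'   [calibrateConsumptionPreset()].
#' @return a [CellPhysiology-class] with attribute `targetRate`.
#' @export
physiologyPreset <- function(genotype = c("ctrl", "cko"), targetRate = NULL,
                             baselineGlc = 1.2, sensor = sensorParams(),
                             protocol = standardProtocol(),
                             cfg = kineticsConfig()) {
  genotype <- match.arg(genotype)
  if (is.null(targetRate))
    targetRate <- switch(genotype, ctrl = 0.030, cko = 0.079)
  key <- paste0(genotype, "_", format(targetRate, digits = 12), "_",
                format(baselineGlc, digits = 12), "_",
                format(sensor@Kd, digits = 12))
  cacheable <- missing(protocol) && missing(cfg) && missing(sensor)
  if (cacheable && !is.null(.presetCache[[key]]))
    return(.presetCache[[key]])
  vhk <- calibrateConsumptionPreset(targetRate, baselineGlc = baselineGlc,
                                    sensor = sensor, protocol = protocol,
                                    cfg = cfg)
  phys <- cellPhysiology(VmaxT = attr(vhk, "VmaxT"), KmT = 2,
                         Vhk = as.numeric(vhk), KmHk = 0.05, gNet = 0,
                         glc0 = baselineGlc)
  attr(phys, "targetRate") <- targetRate
  if (cacheable) .presetCache[[key]] <- phys
  phys
}
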
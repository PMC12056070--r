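#' @include AllClasses.R protocol.R
NULL

#' Configuration for the kinetic estimators
#'
#' @param minWindow minutes of the aglycemia tail averaged as the one-point
#'   minimum.
#' @param washinDelay minutes skipped after a drug epoch starts (bath
#'   exchange).
#' @param consumptionFitSpan minutes of the transport-stop fit window.
#' @param riseFitBounds fraction-of-plateau pair delimiting the rise fit.
#' @param plateauWindow minutes at the end of the step epoch averaged as
#'   the plateau.
#' @param baselineWindow minutes at the end of the baseline epoch averaged
#'   as the baseline.
#' @return a [KineticsConfig-class].
#' @export
kineticsConfig <- function(minWindow = 2, washinDelay = 1,
                           consumptionFitSpan = 5,
                           riseFitBounds = c(0.2, 0.8),
                           plateauWindow = 2, baselineWindow = 2) {
  new("KineticsConfig", minWindow = minWindow, washinDelay = washinDelay,
      consumptionFitSpan = consumptionFitSpan, riseFitBounds = riseFitBounds,
      plateauWindow = plateauWindow, baselineWindow = baselineWindow)
}

## Ordinary least-squares slope with diagnostics; NAs dropped.
.olsSlope <- function(t, y) {
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  n <- length(t)
  if (n < 2L)
    return(list(slope = NA_real_, intercept = NA_real_, se = NA_real_,
                r2 = NA_real_, n = n))
  tm <- t - mean(t); ym <- y - mean(y)
  sxx <- sum(tm^2)
  slope <- sum(tm * ym) / sxx
  res <- ym - slope * tm
  rss <- sum(res^2)
  tss <- sum(ym^2)
  se <- if (n > 2L) sqrt(rss / (n - 2L) / sxx) else NA_real_
  list(slope = slope, intercept = mean(y) - slope * mean(t), se = se,
       r2 = if (tss > 0) 1 - rss / tss else NA_real_, n = n)
}

## Mean of trace samples with t in [t1, t2]; NA-aware.
.windowMean <- function(trace, t1, t2) {
  sel <- trace@times >= t1 - 1e-9 & trace@times <= t2 + 1e-9
  vals <- trace@ratio[sel]
  if (!length(vals) || all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' One-point aglycemia normalization of a ratio trace
#'
#' Divides the raw ratio by its mean over the tail of the terminal
#' aglycemia (0 mM glucose) epoch, so the normalized trace averages exactly
#' 1 over that window. This is the one-point sensor calibration: all
#' downstream levels and rates are expressed in minimum-normalized ratio
#' units.
#'
#' @param trace a raw [RatioTrace-class].
#' @param protocol the [FretProtocol-class] the trace was acquired under.
#' @param cfg a [KineticsConfig-class]; `minWindow` sets the tail length.
#' @return a normalized [RatioTrace-class] (`normFactor` holds the divisor).
#' @export
normalizeToMin <- function(trace, protocol, cfg = kineticsConfig()) {
  ag <- findEpoch(protocol, "aglycemia")
  if (ag$tEnd - ag$tStart < cfg@minWindow - 1e-9)
    stop("aglycemia epoch shorter than the minimum-averaging window")
  m <- .windowMean(trace, ag$tEnd - cfg@minWindow, ag$tEnd)
  if (!is.finite(m)) stop("no data in the aglycemia minimum window")
  if (m <= 0) stop("aglycemia minimum is not positive")
  out <- trace
  out@ratio <- trace@ratio / m
  out@normalized <- TRUE
  out@normFactor <- if (trace@normalized) trace@normFactor else m
  out
}

#' Glucose rise rate after a step in extracellular glucose
#'
#' Fits a straight line to the normalized trace between the first crossings
#' of the lower and upper fractions (default 20% and 80%) of the
#' baseline-to-plateau excursion after the step-epoch start. A rise is
#' declared detectable only when the excursion exceeds 3x the residual
#' standard deviation of the baseline window.
#'
#' @param trace a normalized [RatioTrace-class].
#' @param protocol a [FretProtocol-class].
#' @param cfg a [KineticsConfig-class].
#' @param stepName,baselineName optional explicit epoch names.
#' @return list with `rate` (normalized units per minute; `NA` when not
#'   estimable), `se`, `r2`, `n`, and `flag` (`"ok"` or
#'   `"not_estimable"`).
#' @export
estimateRiseRate <- function(trace, protocol, cfg = kineticsConfig(),
                             stepName = NULL, baselineName = NULL) {
  st <- findEpoch(protocol, "step", name = stepName)
  bl <- if (is.null(baselineName)) findEpoch(protocol, "baseline")
        else findEpoch(protocol, name = baselineName)
  b <- .windowMean(trace, bl$tEnd - cfg@baselineWindow, bl$tEnd)
  p <- .windowMean(trace, st$tEnd - cfg@plateauWindow, st$tEnd)
  if (!is.finite(b) || !is.finite(p)) stop("empty baseline or plateau window")
  selB <- trace@times >= bl$tEnd - cfg@baselineWindow - 1e-9 &
    trace@times <= bl$tEnd + 1e-9
  resSd <- stats::sd(trace@ratio[selB], na.rm = TRUE)
  if (!is.finite(resSd)) resSd <- 0
  if ((p - b) <= 3 * resSd)
    return(list(rate = NA_real_, se = NA_real_, r2 = NA_real_, n = 0L,
                flag = "not_estimable"))
  lo <- b + cfg@riseFitBounds[1L] * (p - b)
  hi <- b + cfg@riseFitBounds[2L] * (p - b)
  sel <- trace@times >= st$tStart - 1e-9 & !is.na(trace@ratio)
  tt <- trace@times[sel]; yy <- trace@ratio[sel]
  iLo <- which(yy >= lo)[1L]
  iHi <- which(yy >= hi)[1L]
  if (is.na(iLo) || is.na(iHi) || iHi <= iLo)
    return(list(rate = NA_real_, se = NA_real_, r2 = NA_real_, n = 0L,
                flag = "not_estimable"))
  win <- seq(iLo, iHi)
  fit <- .olsSlope(tt[win], yy[win])
  list(rate = fit$slope, se = fit$se, r2 = fit$r2, n = fit$n, flag = "ok")
}

#' Glucose increase upon a step in extracellular glucose
#'
#' Plateau minus baseline, both taken as window means of the normalized
#' trace (dimensionless, minimum-normalized ratio units).
#'
#' @inheritParams estimateRiseRate
#' @return numeric delta (normalized units).
#' @export
estimateDelta <- function(trace, protocol, cfg = kineticsConfig(),
                          stepName = NULL, baselineName = NULL) {
  st <- findEpoch(protocol, "step", name = stepName)
  bl <- if (is.null(baselineName)) findEpoch(protocol, "baseline")
        else findEpoch(protocol, name = baselineName)
  b <- .windowMean(trace, bl$tEnd - cfg@baselineWindow, bl$tEnd)
  p <- .windowMean(trace, st$tEnd - cfg@plateauWindow, st$tEnd)
  if (!is.finite(b) || !is.finite(p)) stop("empty baseline or plateau window")
  p - b
}

#' Transport-stop glucose consumption rate
#'
#' Ordinary least-squares slope of the normalized trace over the window
#' `[epoch start + washinDelay, + consumptionFitSpan]` of the
#' cytochalasin-B epoch. The slope is returned signed: negative values mean
#' consumption. A positive slope larger than twice its standard error is
#' flagged `"anomalous_positive"` but still returned; fits with fewer than
#' 10 points are flagged `"few_points"`.
#'
#' @param trace a normalized [RatioTrace-class].
#' @param protocol a [FretProtocol-class].
#' @param cfg a [KineticsConfig-class].
#' @param epochName optional explicit drug-epoch name.
#' @param robust use the Theil-Sen (median of pairwise slopes) estimator
#'   instead of OLS; `se` and `r2` are still reported from the OLS fit.
#' @return list with `rate` (1/min), `se`, `r2`, `n`, `flag`.
#' @export
estimateConsumptionRate <- function(trace, protocol, cfg = kineticsConfig(),
                                    epochName = NULL, robust = FALSE) {
  ce <- if (is.null(epochName)) findEpoch(protocol, "cytoB")
        else findEpoch(protocol, name = epochName)
  t0 <- ce$tStart + cfg@washinDelay
  t1 <- t0 + cfg@consumptionFitSpan
  if (t1 > ce$tEnd + 1e-9)
    stop("drug epoch shorter than washinDelay + consumptionFitSpan")
  sel <- trace@times >= t0 - 1e-9 & trace@times <= t1 + 1e-9
  fit <- .olsSlope(trace@times[sel], trace@ratio[sel])
  if (robust && fit$n >= 2L) {
    tt <- trace@times[sel]; yy <- trace@ratio[sel]
    ok <- is.finite(yy)
    tt <- tt[ok]; yy <- yy[ok]
    ij <- utils::combn(length(tt), 2L)
    fit$slope <- stats::median((yy[ij[2L, ]] - yy[ij[1L, ]]) /
                                 (tt[ij[2L, ]] - tt[ij[1L, ]]))
  }
  flag <- "ok"
  if (fit$n < 10L) flag <- "few_points"
  else if (is.finite(fit$se) && fit$slope > 2 * fit$se) flag <- "anomalous_positive"
  list(rate = fit$slope, se = fit$se, r2 = fit$r2, n = fit$n, flag = flag)
}

#' All kinetic read-outs for one cell
#'
#' Normalizes the raw trace to the aglycemia minimum and extracts the raw
#' basal ratio, normalized basal level, rise rate, glucose increase and
#' transport-stop consumption rate with their diagnostics.
#'
#' @param trace a raw [RatioTrace-class].
#' @param protocol a [FretProtocol-class].
#' @param cfg a [KineticsConfig-class].
#' @return one-row data.frame (metadata columns first).
#' @export
cellKinetics <- function(trace, protocol, cfg = kineticsConfig()) {
  norm <- normalizeToMin(trace, protocol, cfg)
  bl <- findEpoch(protocol, "baseline")
  rawBasal <- .windowMean(trace, bl$tEnd - cfg@baselineWindow, bl$tEnd)
  normBasal <- .windowMean(norm, bl$tEnd - cfg@baselineWindow, bl$tEnd)
  rise <- estimateRiseRate(norm, protocol, cfg)
  delta <- estimateDelta(norm, protocol, cfg)
  cons <- estimateConsumptionRate(norm, protocol, cfg)
  m <- traceMeta(trace)
  gv <- function(k) if (!is.null(m[[k]])) m[[k]] else NA
  data.frame(cell = gv("cell"), slice = gv("slice"), animal = gv("animal"),
             genotype = gv("genotype"),
             rawBasal = rawBasal, normBasal = normBasal,
             riseRate = rise$rate, riseR2 = rise$r2, riseN = rise$n,
             riseFlag = rise$flag,
             deltaGlc = delta,
             consumptionRate = cons$rate, consSe = cons$se, consR2 = cons$r2,
             consN = cons$n, consFlag = cons$flag,
             normFactor = norm@normFactor,
             stringsAsFactors = FALSE)
}

#' Kinetic read-outs for a list of traces
#'
#' @param traces list of raw [RatioTrace-class] objects.
#' @param protocol a [FretProtocol-class].
#' @param cfg a [KineticsConfig-class].
#' @return data.frame with one row per cell.
#' @export
kineticsTable <- function(traces, protocol, cfg = kineticsConfig()) {
  do.call(rbind, lapply(traces, cellKinetics, protocol = protocol, cfg = cfg))
}
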
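#' @include AllClasses.R
NULL

#' Construct sensor parameters
#'
#' Defaults describe a single-site glucose FRET sensor with half-saturation
#' near 0.7 mM operating between a zero-glucose ratio of 1.0 and a
#' saturated ratio of 2.2. These are conventions of the simulator, not
#' measured constants; override freely.
#'
#' @param Kd half-saturation (mM).
#' @param Rmin ratio at zero glucose.
#' @param Rmax ratio at saturation.
#' @return a [SensorParams-class].
#' @export
sensorParams <- function(Kd = 0.7, Rmin = 1.0, Rmax = 2.2) {
  new("SensorParams", Kd = Kd, Rmin = Rmin, Rmax = Rmax)
}

#' Sensor ratio as a function of glucose
#'
#' Single-site binding: \eqn{R(g) = R_{min} + (R_{max}-R_{min})\,g/(K_d+g)},
#' strictly increasing in g.
#'
#' @param glc glucose concentration(s), mM; must be >= 0.
#' @param sensor a [SensorParams-class].
#' @return ratio value(s).
#' @examples
#' s <- sensorParams()
#' sensorResponse(c(0, 0.7), s)  # Rmin and the mid-point
#' @export
sensorResponse <- function(glc, sensor = sensorParams()) {
  if (any(glc < 0)) stop("glucose must be >= 0")
  sensor@Rmin + (sensor@Rmax - sensor@Rmin) * glc / (sensor@Kd + glc)
}

#' Invert the sensor response
#'
#' Algebraic inverse of [sensorResponse()]; defined on the open interval
#' (Rmin, Rmax). The closed endpoints map to 0 and infinite glucose and are
#' rejected.
#'
#' @param R ratio value(s), strictly inside (Rmin, Rmax).
#' @param sensor a [SensorParams-class].
#' @return glucose in mM.
#' @export
invertSensor <- function(R, sensor = sensorParams()) {
  if (any(R <= sensor@Rmin) || any(R >= sensor@Rmax))
    stop("ratio must lie strictly inside (Rmin, Rmax)")
  f <- (R - sensor@Rmin) / (sensor@Rmax - sensor@Rmin)
  sensor@Kd * f / (1 - f)
}

## dR/dglc of the binding curve.
sensorSlope <- function(glc, sensor) {
  (sensor@Rmax - sensor@Rmin) * sensor@Kd / (sensor@Kd + glc)^2
}
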
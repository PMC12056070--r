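#' @include AllClasses.R protocol.R sensor.R
NULL

#' Construct single-cell glucose-handling parameters
#'
#' @param VmaxT maximal facilitated-transport rate (mM/min).
#' @param KmT transporter half-saturation (mM); the carrier is symmetric,
#'   the same Km applies at both membrane faces.
#' @param Vhk maximal consumption rate (mM/min).
#' @param KmHk consumption half-saturation (mM); the small default keeps the
#'   transport-stop decline quasi-linear (zero-order) over the fit window.
#' @param gNet network-exchange conductance (1/min) toward a fixed network
#'   glucose level; set to 0 to model an uncoupled cell and zeroed
#'   automatically during carbenoxolone epochs.
#' @param glc0 initial cytosolic glucose (mM).
#' @return a [CellPhysiology-class].
#' @export
cellPhysiology <- function(VmaxT = 0.35, KmT = 2, Vhk = 0.12,
                           KmHk = 0.05, gNet = 0, glc0 = 1.2) {
  new("CellPhysiology", VmaxT = VmaxT, KmT = KmT, Vhk = Vhk,
      KmHk = KmHk, gNet = gNet, glc0 = glc0)
}

## Flux terms of the cytosolic glucose balance. Exposed internally so the
## steady-state solver and the ODE right-hand side cannot drift apart.
.fluxTransport <- function(g, glcOut, phys) {
  phys@VmaxT * (glcOut / (phys@KmT + glcOut) - g / (phys@KmT + g))
}
.fluxConsumption <- function(g, phys) {
  phys@Vhk * g / (phys@KmHk + g)
}

#' Simulate the cytosolic glucose trajectory of one cell
#'
#' Integrates \eqn{d[Glc]_i/dt = T + X - C} across the protocol epochs:
#' facilitated transport \eqn{T} (zeroed while cytochalasin B is present),
#' network exchange \eqn{X = g_{net}([Glc]_{net} - [Glc]_i)} (zeroed while
#' carbenoxolone is present), and Michaelis-Menten consumption \eqn{C}.
#' Drug action is instantaneous at epoch boundaries in this ground truth;
#' bath-exchange delays are an analysis-side convention (see
#' [kineticsConfig()]).
#'
#' @param phys a [CellPhysiology-class].
#' @param protocol a [FretProtocol-class].
#' @param dt output time step in minutes; must not exceed one tenth of the
#'   shortest epoch.
#' @param glcNet fixed network glucose level (mM) seen through `gNet`.
#' @return a [GlucoseTrajectory-class].
#' @examples
#' tr <- simulateCellGlucose(cellPhysiology(), standardProtocol(), dt = 0.05)
#' range(tr@glc)
#' @export
simulateCellGlucose <- function(phys, protocol, dt = 0.02, glcNet = 1.2) {
  e <- epochs(protocol)
  shortest <- min(e$tEnd - e$tStart)
  if (dt <= 0) stop("dt must be > 0")
  if (dt > 0.1 * shortest + 1e-12)
    stop("dt too large: must be <= 0.1 x the shortest epoch (",
         signif(0.1 * shortest, 3), " min)")

  rhs <- function(t, y, p) {
    g <- max(y[1L], 0)
    Tt <- if (p$cytoB) 0 else .fluxTransport(g, p$glcOut, phys)
    Xt <- if (p$cbx) 0 else phys@gNet * (glcNet - g)
    Ct <- .fluxConsumption(g, phys)
    list(Tt + Xt - Ct)
  }

  times <- numeric(0)
  glc <- numeric(0)
  g0 <- phys@glc0
  for (i in seq_len(nrow(e))) {
    te <- seq(e$tStart[i], e$tEnd[i], by = dt)
    if (te[length(te)] < e$tEnd[i] - 1e-9) te <- c(te, e$tEnd[i])
    p <- list(glcOut = e$glcOut[i], cytoB = e$cytoB[i], cbx = e$cbx[i])
    sol <- deSolve::ode(y = c(g = g0), times = te, func = rhs, parms = p,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    gseg <- sol[, "g"]
    if (min(gseg) < -1e-6)
      stop("unstable integration step (negative overshoot); use a smaller dt")
    gseg <- pmax(gseg, 0)
    keep <- if (length(times)) -1L else seq_along(te)
    times <- c(times, te[keep])
    glc <- c(glc, gseg[keep])
    g0 <- gseg[length(gseg)]
  }
  new("GlucoseTrajectory", times = times, glc = glc,
      phys = phys, protocol = protocol)
}

#' Steady-state cytosolic glucose at a fixed extracellular level
#'
#' Solves the flux balance T + X = C for the resting cytosolic glucose by
#' root bracketing.
#'
#' @param phys a [CellPhysiology-class].
#' @param glcOut extracellular glucose (mM).
#' @param glcNet fixed network glucose (mM).
#' @param tol root tolerance (mM).
#' @return steady-state cytosolic glucose (mM).
#' @export
steadyStateGlucose <- function(phys, glcOut, glcNet = 1.2, tol = 1e-9) {
  f <- function(g) .fluxTransport(g, glcOut, phys) +
    phys@gNet * (glcNet - g) - .fluxConsumption(g, phys)
  upper <- max(glcOut, glcNet, phys@glc0, 1) * 2 + 1
  if (f(0) <= 0) return(0)
  stats::uniroot(f, c(0, upper), tol = tol)$root
}

#' Sample a ground-truth trajectory through the sensor
#'
#' Interpolates a [GlucoseTrajectory-class] onto the requested time points
#' and maps it through [sensorResponse()], giving the noiseless ratio trace
#' the imaging pipeline should recover.
#'
#' @param traj a [GlucoseTrajectory-class].
#' @param sensor a [SensorParams-class].
#' @param times output time points in minutes (default: trajectory times).
#' @param meta list of nesting metadata to attach.
#' @return a raw [RatioTrace-class].
#' @export
traceFromTrajectory <- function(traj, sensor = sensorParams(), times = NULL,
                                meta = list()) {
  if (is.null(times)) times <- traj@times
  g <- stats::approx(traj@times, traj@glc, xout = times, rule = 2)$y
  new("RatioTrace", times = times, ratio = sensorResponse(g, sensor),
      nValid = integer(0), meta = meta, window = 1, normalized = FALSE,
      normFactor = NA_real_)
}
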
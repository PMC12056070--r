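#' @include AllClasses.R
NULL

#' Build a perfusion protocol from epoch specifications
#'
#' @param epochSpecs a data.frame (or list of lists coercible to one) with
#'   columns `name`, `tStart`, `tEnd` (minutes), `glcOut` (mM) and optional
#'   logical `cytoB`, `cbx` (default `FALSE`).
#' @return a validated [FretProtocol-class] with epochs ordered by `tStart`.
#' @examples
#' buildProtocol(data.frame(name = "baseline", tStart = 0, tEnd = 10,
#'                          glcOut = 5))
#' @export
buildProtocol <- function(epochSpecs) {
  if (is.list(epochSpecs) && !is.data.frame(epochSpecs))
    epochSpecs <- do.call(rbind, lapply(epochSpecs, function(x)
      as.data.frame(x, stringsAsFactors = FALSE)))
  e <- as.data.frame(epochSpecs, stringsAsFactors = FALSE)
  if (nrow(e) < 1L) stop("at least one epoch is required")
  if (is.null(e$cytoB)) e$cytoB <- FALSE
  if (is.null(e$cbx)) e$cbx <- FALSE
  if (is.null(e$name)) e$name <- paste0("epoch", seq_len(nrow(e)))
  e <- e[order(e$tStart), c("name", "tStart", "tEnd", "glcOut", "cytoB", "cbx")]
  rownames(e) <- NULL
  e$cytoB <- as.logical(e$cytoB)
  e$cbx <- as.logical(e$cbx)
  new("FretProtocol", epochs = e)
}

#' The standard glucose-step / transport-stop protocol
#'
#' Baseline at 5 mM extracellular glucose, a step to 25 mM, washout back to
#' 5 mM, a cytochalasin-B transport-stop epoch at 5 mM, and terminal
#' aglycemia (0 mM) for the one-point sensor calibration.
#'
#' @param durations named numeric vector of epoch lengths in minutes.
#' @param glcOut extracellular glucose per epoch (mM).
#' @param cbx apply carbenoxolone throughout (blocks the network-exchange
#'   term of the simulator).
#' @return a [FretProtocol-class].
#' @examples
#' standardProtocol()
#' @export
standardProtocol <- function(durations = c(baseline = 6, step = 8,
                                           washout = 6, cytoB = 8,
                                           aglycemia = 8),
                             glcOut = c(5, 25, 5, 5, 0),
                             cbx = FALSE) {
  stopifnot(length(durations) == 5L, length(glcOut) == 5L)
  tEnd <- cumsum(unname(durations))
  tStart <- c(0, tEnd[-5L])
  buildProtocol(data.frame(
    name = names(durations),
    tStart = tStart, tEnd = tEnd, glcOut = glcOut,
    cytoB = c(FALSE, FALSE, FALSE, TRUE, FALSE),
    cbx = cbx, stringsAsFactors = FALSE))
}

#' Total duration of a protocol in minutes
#' @param protocol a [FretProtocol-class].
#' @return numeric minutes from the first epoch start to the last epoch end.
#' @export
protocolDuration <- function(protocol) {
  e <- epochs(protocol)
  max(e$tEnd) - min(e$tStart)
}

## Locate the epoch playing a given role. Explicit `name` wins; otherwise
## aglycemia = last zero-glucose epoch, cytoB = first flagged epoch,
## step = highest-glucose epoch, baseline = epoch preceding the step.
findEpoch <- function(protocol, role = c("aglycemia", "cytoB", "step",
                                         "baseline"),
                      name = NULL) {
  e <- epochs(protocol)
  if (!is.null(name)) {
    i <- match(name, e$name)
    if (is.na(i)) stop("no epoch named '", name, "'")
    return(e[i, , drop = FALSE])
  }
  role <- match.arg(role)
  i <- switch(role,
    aglycemia = { k <- which(e$glcOut == 0); if (length(k)) max(k) else NA_integer_ },
    cytoB = { k <- which(e$cytoB); if (length(k)) min(k) else NA_integer_ },
    step = which.max(e$glcOut),
    baseline = {
      s <- which.max(e$glcOut)
      if (s > 1L) s - 1L else NA_integer_
    })
  if (is.na(i)) stop("protocol has no '", role, "' epoch")
  e[i, , drop = FALSE]
}
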
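#' @include AllClasses.R scene.R calibration.R photometry.R kinetics.R
NULL

## Assign cells to slices, slices to animals, and split large slices into
## imaging fields of at most maxPerField cells.
.designTable <- function(nCells, nSlices, nAnimals, maxPerField = 8L) {
  if (nSlices < nAnimals) stop("need at least one slice per animal")
  animalOfSlice <- sort(rep_len(seq_len(nAnimals), nSlices))
  base <- nCells %/% nSlices
  cellsPerSlice <- rep(base, nSlices) +
    c(rep(1L, nCells %% nSlices), rep(0L, nSlices - nCells %% nSlices))
  rows <- list()
  cellId <- 0L
  fieldId <- 0L
  for (s in seq_len(nSlices)) {
    k <- cellsPerSlice[s]
    nFld <- ceiling(k / maxPerField)
    sizes <- rep(k %/% nFld, nFld) +
      c(rep(1L, k %% nFld), rep(0L, nFld - k %% nFld))
    for (f in seq_len(nFld)) {
      fieldId <- fieldId + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        cell = cellId + seq_len(sizes[f]),
        slice = s, animal = animalOfSlice[s], field = fieldId)
      cellId <- cellId + sizes[f]
    }
  }
  do.call(rbind, rows)
}

#' Simulate a full imaging experiment for one genotype
#'
#' Generates a nested design (cells within slices within animals, slices
#' imaged as fields of at most 8 cells), draws multiplicative biological
#' variability at the animal, slice and cell level (log-normal factors
#' with unit mean, applied jointly to transport and consumption capacity
#' so every cell rests at the same baseline glucose), simulates each
#' cell's glucose trajectory under the protocol, and renders one noisy,
#' drifting two-channel stack per field with ground-truth ROI labels.
#'
#' @param genotype `"ctrl"` or `"cko"` (selects the consumption preset).
#' @param nCells,nSlices,nAnimals design size.
#' @param seed integer seed; the whole experiment is reproducible from it.
#' @param frameShape frame size in pixels.
#' @param protocol a [FretProtocol-class].
#' @param sensor a [SensorParams-class].
#' @param phys optional [CellPhysiology-class] template overriding the
#'   genotype preset.
#' @param jitterSd named log-scale standard deviations of the biological
#'   variability factors (`animal`, `slice`, `cell`).
#' @param ... scene options forwarded to [buildScene()] (pixel size, cell
#'   radius, brightness, background, frame period, motion, noise).
#' @return list with `fields` (each: `stack`, `rois`, `meta`,
#'   `trajectories`), `design`, `protocol`, `sensor`, `genotype`, `seed`.
#' @export
simulateExperiment <- function(genotype = c("ctrl", "cko"), nCells = 63,
                               nSlices = 9, nAnimals = 5, seed = 1,
                               frameShape = c(256L, 256L),
                               protocol = standardProtocol(),
                               sensor = sensorParams(), phys = NULL,
                               jitterSd = c(animal = 0.04, slice = 0.04,
                                            cell = 0.10), ...) {
  genotype <- match.arg(genotype)
  if (is.null(phys)) phys <- physiologyPreset(genotype)
  design <- .jitteredDesign(nCells, nSlices, nAnimals, jitterSd, seed)
  .withSeed(seed + 1L, {
    fields <- lapply(split(design, design$field), function(dd)
      .simulateField(dd, protocol, sensor, phys, genotype, frameShape, ...))
    list(fields = fields, design = design, protocol = protocol,
         sensor = sensor, genotype = genotype, seed = seed)
  })
}

## Design table plus multiplicative log-normal jitter factors, drawn
## under `seed` so the truth layer is reproducible independently of the
## rendering stream.
.jitteredDesign <- function(nCells, nSlices, nAnimals, jitterSd, seed) {
  design <- .designTable(nCells, nSlices, nAnimals)
  totVar <- sum(jitterSd^2)
  .withSeed(seed, {
    fa <- stats::rnorm(nAnimals, 0, jitterSd[["animal"]])
    fs <- stats::rnorm(nSlices, 0, jitterSd[["slice"]])
    fc <- stats::rnorm(nCells, 0, jitterSd[["cell"]])
    design$factor <- exp(fa[design$animal] + fs[design$slice] +
                           fc[design$cell] - totVar / 2)
    design
  })
}

## Per-cell physiology under the biological variability model. When the
## template carries a calibrated target rate, variability is drawn on the
## measured-rate scale (each cell's consumption capacity is calibrated so
## its noiseless read-out is factor x target), matching how group
## dispersion is reported for this assay; otherwise capacities scale
## multiplicatively.
.cellPhysiologies <- function(dd, phys, protocol, sensor) {
  target <- attr(phys, "targetRate")
  if (!is.null(target)) {
    curve <- .rateCalibrationCurve(target, baselineGlc = phys@glc0,
                                   sensor = sensor, protocol = protocol)
    cal <- curve(target * dd$factor)
    list(phys = lapply(seq_len(nrow(dd)), function(j)
      cellPhysiology(VmaxT = cal$VmaxT[j], KmT = phys@KmT,
                     Vhk = cal$Vhk[j], KmHk = phys@KmHk,
                     gNet = phys@gNet, glc0 = phys@glc0)),
      truthVhk = cal$Vhk, truthRate = target * dd$factor)
  } else {
    list(phys = lapply(dd$factor, function(f)
      cellPhysiology(VmaxT = phys@VmaxT * f, KmT = phys@KmT,
                     Vhk = phys@Vhk * f, KmHk = phys@KmHk,
                     gNet = phys@gNet, glc0 = phys@glc0)),
      truthVhk = phys@Vhk * dd$factor, truthRate = rep(NA_real_, nrow(dd)))
  }
}

## Simulate and render one imaging field (consumes the current RNG stream).
.simulateField <- function(dd, protocol, sensor, phys, genotype,
                           frameShape, ...) {
  k <- nrow(dd)
  scene <- buildScene(nCells = k, protocol = protocol,
                      frameShape = frameShape, ...)
  pp <- .cellPhysiologies(dd, phys, protocol, sensor)
  trajs <- lapply(pp$phys, simulateCellGlucose, protocol = protocol)
  cellMeta <- data.frame(cell = dd$cell, slice = dd$slice,
                         animal = dd$animal, genotype = genotype,
                         truthFactor = dd$factor,
                         truthVhk = pp$truthVhk,
                         truthRate = pp$truthRate)
  r <- renderStack(scene, trajs, sensor, cellMeta = cellMeta)
  list(stack = r$stack, rois = r$rois, meta = r$meta, trajectories = trajs)
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' For every field: correlation-based motion correction (subpixel), boxcar
#' smoothing of the registered images, mean-then-divide ROI ratiometry
#' using the ground-truth labels, one-point aglycemia normalization and
#' kinetic estimation per cell.
#'
#' @param experiment result of [simulateExperiment()].
#' @param cfg a [KineticsConfig-class].
#' @param smoothWindow boxcar window in frames.
#' @param subpixelFactor registration upsampling factor.
#' @param reference template frame indices for registration.
#' @param maxShift registration search bound (px).
#' @return data.frame with one row per cell ([cellKinetics()] columns plus
#'   ground truth).
#' @export
analyzeExperiment <- function(experiment, cfg = kineticsConfig(),
                              smoothWindow = 11, subpixelFactor = 10,
                              reference = 1:10, maxShift = 20) {
  res <- lapply(experiment$fields, .analyzeField,
                protocol = experiment$protocol, cfg = cfg,
                smoothWindow = smoothWindow,
                subpixelFactor = subpixelFactor, reference = reference,
                maxShift = maxShift)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.analyzeField <- function(fld, protocol, cfg, smoothWindow = 11,
                          subpixelFactor = 10, reference = 1:10,
                          maxShift = 20) {
  reg <- registerStack(fld$stack, reference = reference,
                       subpixelFactor = subpixelFactor,
                       maxShift = maxShift)
  traces <- extractRatio(reg$stack, fld$rois, smoothWindow = smoothWindow)
  kin <- kineticsTable(traces, protocol, cfg)
  truth <- fld$meta[match(kin$cell, fld$meta$cell), , drop = FALSE]
  kin$truthVhk <- truth$truthVhk
  kin$truthFactor <- truth$truthFactor
  kin$truthRate <- truth$truthRate
  kin
}

#' Simulate and analyze one genotype group, returning the recovered rate
#'
#' Equivalent to [simulateExperiment()] followed by
#' [analyzeExperiment()] (identical random streams), but fused per field
#' so that at most one image stack is held in memory at a time — a full
#' group at the published design sizes is then analyzable within a few
#' gigabytes.
#'
#' @inheritParams simulateExperiment
#' @param frameShape frame size; the reduced default keeps a full group
#'   tractable on one CPU.
#' @param cfg a [KineticsConfig-class].
#' @param ... scene options forwarded to [buildScene()].
#' @return list with `cells` (per-cell results), `meanRate` (signed;
#'   negative = decline), `sem`, `n`.
#' @export
recoverGroupRate <- function(genotype = c("ctrl", "cko"), nCells = 63,
                             nSlices = 9, nAnimals = 5, seed = 1,
                             frameShape = c(128L, 128L),
                             protocol = standardProtocol(),
                             sensor = sensorParams(), phys = NULL,
                             jitterSd = c(animal = 0.04, slice = 0.04,
                                          cell = 0.10),
                             cfg = kineticsConfig(), ...) {
  genotype <- match.arg(genotype)
  if (is.null(phys)) phys <- physiologyPreset(genotype)
  design <- .jitteredDesign(nCells, nSlices, nAnimals, jitterSd, seed)
  cells <- .withSeed(seed + 1L, {
    res <- lapply(split(design, design$field), function(dd) {
      fld <- .simulateField(dd, protocol, sensor, phys, genotype,
                            frameShape, ...)
      kin <- .analyzeField(fld, protocol, cfg)
      rm(fld)
      gc(verbose = FALSE)
      kin
    })
    do.call(rbind, res)
  })
  rownames(cells) <- NULL
  r <- cells$consumptionRate[is.finite(cells$consumptionRate)]
  list(cells = cells, meanRate = mean(r),
       sem = stats::sd(r) / sqrt(length(r)), n = length(r))
}
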
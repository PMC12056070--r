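#' @include AllClasses.R protocol.R
NULL

## 16-bit TIFF helpers: tiff stores values scaled to [0, 1].
.tiff16Write <- function(frames, path) {
  pages <- lapply(frames, function(m) {
    m <- pmin(pmax(round(m), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
}

.tiff16Read <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(m) {
    storage.mode(m) <- "double"
    m
  })
}

#' Write a two-channel stack as a pair of multi-page 16-bit TIFFs
#'
#' Writes `<prefix>_yellow.tif`, `<prefix>_blue.tif` (counts rounded and
#' clipped to 16-bit range) and `<prefix>_frames.csv` (frame, time_min).
#'
#' @param stack a [TwoChannelStack-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
writeStack <- function(stack, dir, prefix = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- nFrames(stack)
  yf <- lapply(seq_len(nf), function(f) stack@yellow[, , f])
  bf <- lapply(seq_len(nf), function(f) stack@blue[, , f])
  py <- file.path(dir, paste0(prefix, "_yellow.tif"))
  pb <- file.path(dir, paste0(prefix, "_blue.tif"))
  pt <- file.path(dir, paste0(prefix, "_frames.csv"))
  .tiff16Write(yf, py)
  .tiff16Write(bf, pb)
  utils::write.csv(data.frame(frame = seq_len(nf), time_min = stack@times,
                              pixel_size_um = stack@pixelSize),
                   pt, row.names = FALSE)
  invisible(c(py, pb, pt))
}

#' Read a two-channel stack written by [writeStack()]
#'
#' @param dir directory containing the files.
#' @param prefix file-name prefix used when writing.
#' @return a [TwoChannelStack-class].
#' @export
readStack <- function(dir, prefix = "stack") {
  yf <- .tiff16Read(file.path(dir, paste0(prefix, "_yellow.tif")))
  bf <- .tiff16Read(file.path(dir, paste0(prefix, "_blue.tif")))
  tb <- utils::read.csv(file.path(dir, paste0(prefix, "_frames.csv")))
  d <- c(dim(yf[[1L]]), length(yf))
  new("TwoChannelStack",
      yellow = array(unlist(yf), d), blue = array(unlist(bf), d),
      times = tb$time_min, validMask = array(TRUE, c(0L, 0L, 0L)),
      pixelSize = tb$pixel_size_um[1L],
      provenance = list(source = dir))
}

#' Write / read ROI labels with metadata
#'
#' The label image is stored as a single-page 16-bit TIFF (0 = background,
#' k = cell k) next to a `<prefix>_cells.csv` metadata table.
#'
#' @param rois a [ROISet-class].
#' @param dir directory.
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
writeRoiLabels <- function(rois, dir, prefix = "rois") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pl <- file.path(dir, paste0(prefix, "_labels.tif"))
  pm <- file.path(dir, paste0(prefix, "_cells.csv"))
  .tiff16Write(list(roiLabels(rois)), pl)
  utils::write.csv(roiMeta(rois), pm, row.names = FALSE)
  invisible(c(pl, pm))
}

#' @rdname writeRoiLabels
#' @param minPixels minimum ROI size recorded on the restored object.
#' @export
readRoiLabels <- function(dir, prefix = "rois", minPixels = 20) {
  lab <- .tiff16Read(file.path(dir, paste0(prefix, "_labels.tif")))[[1L]]
  meta <- utils::read.csv(file.path(dir, paste0(prefix, "_cells.csv")))
  new("ROISet", labels = matrix(as.integer(lab), nrow(lab), ncol(lab)),
      meta = meta, minPixels = minPixels)
}

#' Write / read a protocol as YAML
#'
#' @param protocol a [FretProtocol-class].
#' @param path output `.yaml` path.
#' @return `writeProtocol()` returns the path invisibly; `readProtocol()`
#'   a [FretProtocol-class].
#' @export
writeProtocol <- function(protocol, path) {
  e <- epochs(protocol)
  yaml::write_yaml(list(epochs = lapply(seq_len(nrow(e)), function(i)
    as.list(e[i, ]))), path)
  invisible(path)
}

#' @rdname writeProtocol
#' @export
readProtocol <- function(path) {
  spec <- yaml::read_yaml(path)
  buildProtocol(do.call(rbind, lapply(spec$epochs, as.data.frame)))
}

#' Write extracted traces as a long-format CSV
#'
#' Columns: cell, slice, animal, genotype, time_min, raw_ratio, n_valid.
#'
#' @param traces list of [RatioTrace-class].
#' @param path output `.csv` path.
#' @return the path, invisibly.
#' @export
writeTraces <- function(traces, path) {
  long <- do.call(rbind, lapply(traces, function(tr) {
    m <- traceMeta(tr)
    gv <- function(k) if (!is.null(m[[k]])) m[[k]] else NA
    data.frame(cell = gv("cell"), slice = gv("slice"),
               animal = gv("animal"), genotype = gv("genotype"),
               time_min = tr@times, raw_ratio = tr@ratio,
               n_valid = if (length(tr@nValid)) tr@nValid else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraces
#' @export
readTraces <- function(path) {
  long <- utils::read.csv(path)
  lapply(split(long, long$cell), function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    new("RatioTrace", times = d$time_min, ratio = d$raw_ratio,
        nValid = as.integer(d$n_valid),
        meta = list(cell = d$cell[1L], slice = d$slice[1L],
                    animal = d$animal[1L], genotype = d$genotype[1L]),
        window = 1, normalized = FALSE, normFactor = NA_real_)
  })
}

#' Read lesion sections from CSV
#'
#' Expects columns `section`, `position_mm`, `infarct_mm2`, `ipsi_mm2`,
#' `contra_mm2` and returns the data.frame [infarctVolume()] consumes.
#'
#' @param path CSV path.
#' @return data.frame with columns `position`, `infarct`, `ipsi`, `contra`.
#' @export
readLesionSections <- function(path) {
  d <- utils::read.csv(path)
  need <- c("position_mm", "infarct_mm2", "ipsi_mm2", "contra_mm2")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  data.frame(position = d$position_mm, infarct = d$infarct_mm2,
             ipsi = d$ipsi_mm2, contra = d$contra_mm2)
}

#' Write / read an estimated shift series as CSV
#'
#' Columns: frame, dx, dy, peak, lowConf.
#'
#' @param shifts a [ShiftSeries-class].
#' @param path output `.csv` path.
#' @return the path, invisibly.
#' @export
writeShifts <- function(shifts, path) {
  utils::write.csv(shiftTable(shifts), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeShifts
#' @param maxShift search bound recorded on the restored object.
#' @export
readShifts <- function(path, maxShift = 20) {
  s <- utils::read.csv(path)
  new("ShiftSeries", shifts = s, reference = NA_integer_,
      maxShift = maxShift)
}

#' Write per-cell kinetics results as CSV
#'
#' One row per cell with the [cellKinetics()] columns.
#'
#' @param results data.frame from [kineticsTable()] or
#'   [analyzeExperiment()].
#' @param path output `.csv` path.
#' @return the path, invisibly.
#' @export
writeKineticsResults <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeKineticsResults
#' @export
readKineticsResults <- function(path) {
  utils::read.csv(path)
}

#' Read a binary mask image
#'
#' Accepts single-page TIFF (any bit depth) or PNG; any value above half
#' the image maximum counts as foreground.
#'
#' @param path image path (`.tif`/`.tiff`/`.png`).
#' @return logical matrix.
#' @export
readMask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    pg <- tiff::readTIFF(path, all = FALSE, as.is = TRUE)
    pg
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG masks requires the 'png' package")
    png::readPNG(path)
  } else stop("unsupported mask format: .", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  m <- max(img)
  if (m <= 0) matrix(FALSE, nrow(img), ncol(img)) else img > m / 2
}

#' Write a full simulated experiment to a run directory
#'
#' One directory with, per field, the two-channel TIFF pair and ROI
#' labels, plus the shared protocol YAML, a combined per-cell metadata /
#' ground-truth CSV and a JSON manifest (seed, package and R versions).
#'
#' @param experiment result of [simulateExperiment()].
#' @param dir run directory (created).
#' @return the manifest path, invisibly.
#' @export
writeSimulationRun <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(experiment$fields)) {
    fld <- experiment$fields[[i]]
    prefix <- sprintf("field%02d", i)
    writeStack(fld$stack, dir, prefix)
    writeRoiLabels(fld$rois, dir, prefix)
  }
  writeProtocol(experiment$protocol, file.path(dir, "protocol.yaml"))
  meta <- do.call(rbind, lapply(seq_along(experiment$fields), function(i)
    cbind(field = i, experiment$fields[[i]]$meta)))
  utils::write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  manifest <- list(seed = experiment$seed,
                   genotype = experiment$genotype,
                   nFields = length(experiment$fields),
                   package = as.character(utils::packageVersion("glucoFRET")),
                   rVersion = R.version.string)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(mp)
}
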
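#' @include AllClasses.R
NULL

## Tidy a kinetics-style data.frame into the columns the nested model needs.
.nestedData <- function(data, value, group, slice, animal) {
  need <- c(value, group, slice, animal)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data.frame(y = data[[value]],
                  g = factor(data[[group]]),
                  a = factor(paste0(data[[animal]])),
                  stringsAsFactors = FALSE)
  d$s <- factor(paste(data[[animal]], data[[slice]], sep = ":"))
  d <- d[is.finite(d$y), , drop = FALSE]
  if (nlevels(droplevels(d$g)) != 2L)
    stop("exactly two groups are required")
  d$g <- droplevels(d$g)
  perGroup <- tapply(d$a, d$g, function(x) length(unique(x)))
  if (any(perGroup < 2L))
    stop("each group needs >= 2 animals; the group effect is otherwise ",
         "confounded with animal")
  d
}

#' Two-group comparison honoring cells-within-slices-within-animals nesting
#'
#' Fits a linear mixed model with a fixed group effect and random
#' intercepts for animal and slice-within-animal, and reports the
#' two-sided test of the group effect (t statistic on the fixed effect
#' with Satterthwaite degrees of freedom). If a random-effect variance
#' collapses to zero, the model is refitted without that component and a
#' note is attached. If the model cannot be fitted at all, a seeded
#' hierarchical bootstrap (resampling animals, then slices, then cells) is
#' used instead and recorded in `method`.
#'
#' @param data data.frame of per-cell estimates with nesting labels.
#' @param value,group,slice,animal column names.
#' @param method `"auto"` (mixed model with bootstrap fallback), `"lmm"`,
#'   or `"bootstrap"`.
#' @param nBoot bootstrap draws (>= 2000 recommended).
#' @param seed seed for the bootstrap resampling.
#' @return an object of class `"nestedComparison"`: list with `effect`
#'   (second group minus first), `se`, `df`, `p`, `varcomp`, `groups`,
#'   `method`, `note`.
#' @export
fitNestedComparison <- function(data, value = "consumptionRate",
                                group = "genotype", slice = "slice",
                                animal = "animal",
                                method = c("auto", "lmm", "bootstrap"),
                                nBoot = 2000, seed = 1) {
  method <- match.arg(method)
  d <- .nestedData(data, value, group, slice, animal)

  if (method == "bootstrap") {
    res <- .bootWrap(d, nBoot, seed)
    res$groups <- levels(d$g)
    res$note <- character(0)
    res$varcomp <- c(a = NA_real_, s = NA_real_)
    class(res) <- "nestedComparison"
    return(res)
  }

  fitOne <- function(formula) {
    suppressMessages(suppressWarnings(
      lmerTest::lmer(formula, data = d, REML = TRUE,
                     control = lme4::lmerControl(
                       check.conv.singular = lme4::.makeCC(action = "ignore",
                                                           tol = 1e-4)))))
  }
  note <- character(0)
  res <- tryCatch({
    fit <- fitOne(y ~ g + (1 | a) + (1 | s))
    vc <- as.data.frame(lme4::VarCorr(fit))
    getVar <- function(which) {
      i <- match(which, vc$grp)
      if (is.na(i)) 0 else vc$vcov[i]
    }
    tot <- sum(vc$vcov)
    if (getVar("s") < 1e-10 * tot) {
      fit <- fitOne(y ~ g + (1 | a))
      note <- c(note, "slice variance collapsed; refitted without it")
    } else if (getVar("a") < 1e-10 * tot) {
      fit <- fitOne(y ~ g + (1 | s))
      note <- c(note, "animal variance collapsed; refitted without it")
    }
    co <- stats::coef(summary(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    if (nrow(co) < 2L || !is.finite(co[2L, "Pr(>|t|)"]))
      stop("degenerate fit")
    list(effect = unname(co[2L, "Estimate"]), se = unname(co[2L, "Std. Error"]),
         df = unname(co[2L, "df"]), p = unname(co[2L, "Pr(>|t|)"]),
         varcomp = stats::setNames(vc$vcov, vc$grp), method = "lmm")
  }, error = function(e) {
    if (method == "lmm") stop("mixed model failed: ", conditionMessage(e))
    NULL
  })
  if (is.null(res)) {
    res <- .bootWrap(d, nBoot, seed)
    note <- c(note, "mixed model failed to converge; hierarchical bootstrap used")
  }
  res$groups <- levels(d$g)
  res$note <- note
  if (is.null(res$varcomp)) res$varcomp <- c(a = NA_real_, s = NA_real_)
  class(res) <- "nestedComparison"
  res
}

## simple row-index hierarchical bootstrap (animals -> slices -> cells)
.bootWrap <- function(d, nBoot, seed) {
  lv <- levels(d$g)
  obs <- unname(tapply(d$y, d$g, mean)[lv[2L]] -
                  tapply(d$y, d$g, mean)[lv[1L]])
  aOf <- as.character(d$a); sOf <- as.character(d$s); gOf <- as.character(d$g)
  animals <- split(seq_len(nrow(d)), aOf)
  animalGroup <- vapply(animals, function(i) gOf[i[1L]], character(1L))
  slicesOf <- lapply(animals, function(i) split(i, sOf[i]))
  draws <- .withSeed(seed, vapply(seq_len(nBoot), function(b) {
    rows <- unlist(lapply(lv, function(gl) {
      an <- names(animals)[animalGroup == gl]
      picked <- sample(an, length(an), replace = TRUE)
      unlist(lapply(picked, function(x) {
        sl <- slicesOf[[x]]
        psl <- sample(names(sl), length(sl), replace = TRUE)
        unlist(lapply(psl, function(nm) {
          i <- sl[[nm]]
          sample(i, length(i), replace = TRUE)
        }))
      }))
    }), use.names = FALSE)
    m <- tapply(d$y[rows], factor(gOf[rows], levels = lv), mean)
    unname(m[2L] - m[1L])
  }, numeric(1L)))
  p <- 2 * min(mean(draws <= 0), mean(draws >= 0))
  list(effect = obs, se = stats::sd(draws), df = NA_real_,
       p = min(max(p, 1 / nBoot), 1), method = "bootstrap")
}

#' @export
print.nestedComparison <- function(x, ...) {
  cat(sprintf("Nested two-group comparison (%s)\n", x$method))
  cat(sprintf("  effect (%s - %s): %.5g  SE %.3g  df %.3g  p = %.4g\n",
              x$groups[2L], x$groups[1L], x$effect, x$se, x$df, x$p))
  if (!all(is.na(x$varcomp)))
    cat("  variance components:",
        paste(sprintf("%s = %.3g", names(x$varcomp), x$varcomp),
              collapse = ", "), "\n")
  if (length(x$note)) cat("  note:", paste(x$note, collapse = "; "), "\n")
  invisible(x)
}

#' Write a group-comparison report as JSON plus readable text
#'
#' @param fit a `"nestedComparison"` from [fitNestedComparison()].
#' @param summary result of [summarizeGroups()] on the same data.
#' @param path output path without extension; `<path>.json` and
#'   `<path>.txt` are written.
#' @return invisibly, the two paths.
#' @export
writeStatsReport <- function(fit, summary, path) {
  jsonPath <- paste0(path, ".json")
  txtPath <- paste0(path, ".txt")
  jsonlite::write_json(list(
    effect = fit$effect, se = fit$se, df = fit$df, p = fit$p,
    method = fit$method, groups = fit$groups,
    varianceComponents = as.list(fit$varcomp),
    note = fit$note,
    summary = summary$groups, foldChange = summary$foldChange,
    flags = summary$flags), jsonPath, auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  txt <- c(utils::capture.output(print(fit)),
           utils::capture.output(print(summary$groups)),
           sprintf("fold change: %s", format(summary$foldChange)))
  writeLines(txt, txtPath)
  invisible(c(jsonPath, txtPath))
}

#' Per-group summaries and fold change
#'
#' Cell-level mean and SEM per group, sample sizes at all three nesting
#' levels, and the fold change of absolute group means (second group over
#' first). The SEM is computed at the cell level, matching the common
#' reporting convention; single-cell groups have undefined SEM and are
#' flagged.
#'
#' @inheritParams fitNestedComparison
#' @return list with `groups` (data.frame: group, mean, sem, nCells,
#'   nSlices, nAnimals), `foldChange`, and `flags` (character).
#' @export
summarizeGroups <- function(data, value = "consumptionRate",
                            group = "genotype", slice = "slice",
                            animal = "animal") {
  need <- c(value, group, slice, animal)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  g <- factor(data[[group]])
  if (!nlevels(g)) stop("no groups present")
  y <- data[[value]]
  flags <- character(0)
  rows <- lapply(levels(g), function(lv) {
    sel <- g == lv & is.finite(y)
    n <- sum(sel)
    if (n == 0L) stop("group '", lv, "' is empty")
    sem <- if (n >= 2L) stats::sd(y[sel]) / sqrt(n) else NA_real_
    data.frame(group = lv, mean = mean(y[sel]), sem = sem, nCells = n,
               nSlices = length(unique(paste(data[[animal]][sel],
                                             data[[slice]][sel]))),
               nAnimals = length(unique(data[[animal]][sel])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(!is.finite(out$sem)))
    flags <- c(flags, "SEM undefined for single-cell group(s)")
  fold <- NA_real_
  if (nrow(out) == 2L) {
    if (abs(out$mean[1L]) < .Machine$double.eps * 100) {
      flags <- c(flags, "fold change undefined (zero reference mean)")
    } else fold <- abs(out$mean[2L]) / abs(out$mean[1L])
  }
  list(groups = out, foldChange = fold, flags = flags)
}
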
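setMethod("show", "ComponentReport", function(object) {
  cat(sprintf("ComponentReport '%s': %d frames, c = %.3g mg/ml\n",
    object@id, length(object@frames), object@meanConc))
  cat(sprintf("  MW_RALS = %.1f +- %.1f kDa | MW_I(0) = %.1f +- %.1f kDa | MW_SEC = %.1f kDa\n",
    object@mwRals, object@mwRalsSd, object@mwI0, object@mwI0Sd,
    object@mwSec))
  cat(sprintf("  Rg = %.2f +- %.3f nm; consistency: %s\n",
    object@rg, object@rgSd, object@consistency$status))
})

#' @describeIn runSecPipeline molecular-weight summary accessor: a
#'   data.frame with one row per component.
#' @param report a pipeline run report.
#' @export
componentSummary <- function(report) {
  do.call(rbind, lapply(report$components, function(cp)
    data.frame(id = cp@id, nFrames = length(cp@frames),
      meanConc = cp@meanConc, mwRals = cp@mwRals, mwI0 = cp@mwI0,
      mwSec = cp@mwSec, rg = cp@rg, status = cp@consistency$status)))
}

#' Measure the forward-scattering reference on a standard run
#'
#' Runs the SEC pipeline on a standard-protein run and stores its
#' concentration-normalized forward scattering (I(0)/c of the main
#' component) in the calibration, enabling [mwFromI0()] for subsequent
#' samples measured under the same beam and geometry.
#'
#' @param report pipeline report of the standard run ([runSecPipeline()]).
#' @param cal a [TDACalibration-class].
#' @return The updated calibration.
#' @export
calibrateI0Reference <- function(report, cal) {
  stopIfNot(length(report$components) >= 1,
    "standard run yielded no component")
  main <- report$components[[which.max(vapply(report$components,
    function(cp) cp@meanConc * length(cp@frames), numeric(1)))]]
  i0PerC <- attr(main, "i0PerC")
  stopIfNot(is.finite(i0PerC), "standard component has no I(0)/c")
  cal@standardI0PerC <- i0PerC
  cal
}

# I(0) per concentration over selected frames as a ratio of sums (frames
# weighted by their concentration, so weak tail frames cannot dominate),
# with the spread of the per-frame ratios as dispersion
i0PerCOf <- function(trace, conc, selection) {
  ok <- selection[is.finite(trace$i0[selection]) &
    is.finite(conc[selection]) & conc[selection] > 0]
  if (!length(ok)) return(c(NA_real_, NA_real_))
  c(sum(trace$i0[ok]) / sum(conc[ok]),
    stats::sd(trace$i0[ok] / conc[ok]))
}

#' Run the automated SEC-SAXS/TDA analysis pipeline
#'
#' Orchestrates the full automated analysis of one SEC run:
#' normalization, buffer-frame identification, background subtraction,
#' per-frame Guinier (Rg/I(0)) trace, timeline alignment, per-frame
#' RI-based concentration, concentration normalization, peak detection,
#' consistent-frame selection, final component curves, the three
#' molecular-weight routes and the consistency verdict. Deterministic:
#' no stochastic steps.
#'
#' Without a chromatogram the pipeline degrades gracefully to
#' subtraction plus the Rg/I(0) trace (warning "no concentration
#' normalization").
#'
#' @param series a [FrameSeries-class] (or manifest path) of raw SEC
#'   frames.
#' @param chrom optional [Chromatogram-class] of the synchronized TDA
#'   traces.
#' @param cal optional [TDACalibration-class]; required for
#'   concentration, MW_RALS and MW_SEC.
#' @param bufferWindow optional explicit buffer frame positions
#'   (otherwise identified automatically).
#' @param minBufferWindow buffer window length, frames.
#' @param rgTolerance relative Rg-consistency tolerance for frame
#'   selection.
#' @param monomerMw optional monomer mass, kDa, for oligomer-ladder
#'   matching.
#' @param minConc concentration floor for normalization, mg/ml.
#' @param searchWindow alignment search half-width, s.
#' @return A \code{secRunReport} list: \code{bufferWindow}, \code{trace}
#'   (per-frame Rg/I(0)), \code{lag}, \code{concentration} (per frame),
#'   \code{peaks}, \code{components} (list of
#'   [ComponentReport-class]), \code{warnings}.
#' @export
runSecPipeline <- function(series, chrom = NULL, cal = NULL,
    bufferWindow = NULL, minBufferWindow = 50, rgTolerance = 0.05,
    monomerMw = NULL, minConc = 0.01, searchWindow = 60) {
  if (is.character(series)) series <- readFrameSeries(series)
  warnings <- character()
  norm <- normalizeFrames(series)
  if (is.null(bufferWindow))
    bufferWindow <- identifyBufferFrames(norm, chrom,
      minWindow = minBufferWindow)
  sub <- subtractSeries(norm, bufferWindow)
  trace <- rgTrace(sub)

  if (is.null(chrom) || is.null(cal)) {
    warnings <- c(warnings, "no concentration normalization")
    warning("no chromatogram/calibration: degraded mode, ",
      "subtraction + Rg trace only")
    return(structure(list(bufferWindow = bufferWindow, trace = trace,
      lag = NA_real_, concentration = NULL, peaks = NULL,
      components = list(), warnings = warnings),
      class = "secRunReport"))
  }

  lag <- alignTimelines(trace, chrom, searchWindow = searchWindow)
  conc <- perFrameConcentration(chrom, cal, frameTimes(sub), lag = lag)
  normc <- normalizeByConcentration(sub, conc, minConc = minConc)
  kept <- attr(normc, "kept")

  riCorr <- baselineCorrect(signalTrace(chrom, "ri"), chrom@volume)
  ralsCorr <- baselineCorrect(signalTrace(chrom, "rals"), chrom@volume)
  peaks <- detectPeaks(riCorr, chrom@volume)
  mwTrace <- mwRalsTrace(ralsCorr, riCorr, cal)

  components <- list()
  for (p in seq_len(nrow(peaks))) {
    pk <- peaks[p, ]
    tFirst <- chrom@time[pk$iStart] - lag
    tLast <- chrom@time[pk$iEnd] - lag
    inPeak <- which(sub@time >= tFirst & sub@time <= tLast)
    sel <- tryCatch(
      selectConsistentFrames(trace, inPeak, tolerance = rgTolerance),
      error = function(e) {
        warnings <<- c(warnings,
          sprintf("peak %d: %s", p, conditionMessage(e)))
        integer(0)
      })
    if (!length(sel)) next
    selNorm <- match(sel, kept)
    selNorm <- selNorm[!is.na(selNorm)]
    if (!length(selNorm)) next
    curve <- buildComponentCurve(normc, selNorm)
    # precision-weighted Rg: apex frames carry tight fits, tail frames
    # large uncertainties; equal weighting would bias the component Rg
    w <- 1 / pmax(trace$rgSd[sel], 1e-12)^2
    rgMean <- sum(w * trace$rg[sel]) / sum(w)
    chi2r <- if (length(sel) > 1)
      sum(w * (trace$rg[sel] - rgMean)^2) / (length(sel) - 1) else 1
    rgW <- list(mean = rgMean,
      sd = sqrt(max(1, chi2r) / sum(w)))
    mwPk <- mwTrace[pk$iStart:pk$iEnd]
    mwRals <- stats::median(mwPk, na.rm = TRUE)
    mwRalsSd <- stats::mad(mwPk, na.rm = TRUE)
    i0c <- i0PerCOf(trace, conc, sel)
    mwI0 <- mwI0Sd <- NA_real_
    if (is.finite(cal@standardI0PerC) && is.finite(i0c[1])) {
      mwI0 <- mwFromI0(i0c[1], cal@standardMw, cal@standardI0PerC)
      mwI0Sd <- if (is.finite(i0c[2]))
        mwI0 * i0c[2] / i0c[1] else NA_real_
    }
    mwS <- if (is.finite(cal@columnA))
      as.numeric(mwSec(pk$apex, cal)) else NA_real_
    verdict <- consistencyReport(mwRals, mwI0, mwS,
      monomerMw = monomerMw)
    cp <- new("ComponentReport", id = sprintf("peak%d", p),
      frames = as.integer(sel), meanConc = mean(conc[sel], na.rm = TRUE),
      mwRals = mwRals, mwRalsSd = mwRalsSd,
      mwI0 = mwI0, mwI0Sd = mwI0Sd, mwSec = mwS,
      rg = rgW$mean, rgSd = rgW$sd,
      curve = curve, consistency = verdict)
    attr(cp, "i0PerC") <- i0c[1]
    components[[length(components) + 1]] <- cp
  }
  structure(list(bufferWindow = bufferWindow, trace = trace,
    lag = as.numeric(lag), concentration = conc, peaks = peaks,
    mwTrace = mwTrace, components = components, warnings = warnings),
    class = "secRunReport")
}

#' @export
print.secRunReport <- function(x, ...) {
  cat(sprintf("SEC run report: buffer window %d..%d, lag %.2f s, %d component(s)\n",
    min(x$bufferWindow), max(x$bufferWindow), x$lag,
    length(x$components)))
  for (cp in x$components) show(cp)
  if (length(x$warnings))
    cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Run the batch-mode analysis pipeline
#'
#' Standard static-sample protocol: normalize the successive short
#' exposures, screen them for radiation damage, average the undamaged
#' frames, subtract the paired buffer measurement and run the automatic
#' Guinier analysis.
#'
#' @param series sample [FrameSeries-class] (>= 2 frames).
#' @param bufferSeries paired buffer [FrameSeries-class].
#' @param damageThreshold reduced-discrepancy threshold for
#'   [detectRadiationDamage()].
#' @return A \code{batchRunReport} list: \code{damage} report,
#'   \code{framesUsed}, \code{curve} (net solute curve), \code{fit}
#'   ([GuinierFit-class] or NULL), \code{warnings}.
#' @export
runBatchPipeline <- function(series, bufferSeries, damageThreshold = 4) {
  stopIfNot(nFrames(series) >= 2, "batch mode needs >= 2 frames")
  warnings <- character()
  norm <- normalizeFrames(series)
  bufNorm <- normalizeFrames(bufferSeries)
  damage <- detectRadiationDamage(norm, threshold = damageThreshold)
  used <- if (damage$damaged) seq_len(damage$firstIndex - 1)
    else seq_len(nFrames(norm))
  stopIfNot(length(used) >= 1, "all frames damaged")
  if (damage$damaged)
    warnings <- c(warnings, sprintf(
      "radiation damage from frame %d: averaged frames 1..%d only",
      damage$firstIndex, length(used)))
  sample <- averageFrames(norm, used)
  buffer <- averageFrames(bufNorm)
  net <- subtractBackground(sample, buffer)
  fit <- tryCatch(autoRg(net), error = function(e) {
    warnings <<- c(warnings, conditionMessage(e))
    NULL
  })
  structure(list(damage = damage, framesUsed = used, curve = net,
    fit = fit, warnings = warnings), class = "batchRunReport")
}

#' @export
print.batchRunReport <- function(x, ...) {
  cat(sprintf("Batch run report: %d frame(s) averaged%s\n",
    length(x$framesUsed),
    if (x$damage$damaged) sprintf(" (damage from frame %d)",
      x$damage$firstIndex) else ""))
  if (!is.null(x$fit)) show(x$fit)
  if (length(x$warnings))
    cat("warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Writes the numeric content of a SEC or batch run report (buffer
#' window, per-frame traces, peaks, per-component results, warnings) as
#' JSON with full provenance.
#'
#' @param report a \code{secRunReport} or \code{batchRunReport}.
#' @param path output path.
#' @export
writeRunReport <- function(report, path) {
  enc <- unclass(report)
  if (!is.null(enc$components))
    enc$components <- lapply(enc$components, function(cp) list(
      id = cp@id, frames = cp@frames, meanConc = cp@meanConc,
      mwRals = cp@mwRals, mwRalsSd = cp@mwRalsSd,
      mwI0 = cp@mwI0, mwI0Sd = cp@mwI0Sd, mwSec = cp@mwSec,
      rg = cp@rg, rgSd = cp@rgSd, consistency = cp@consistency))
  enc$curve <- NULL; enc$fit <- NULL
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  invisible(path)
}
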
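#' Align the SAXS frame timeline with the TDA chromatogram
#'
#' The SAXS capillary and the TDA detectors sit behind different dead
#' volumes after the flow split, so the same eluting component appears at
#' slightly different times in the I(0) trace and the chromatogram. The
#' lag is recovered as the shift maximizing the normalized
#' cross-correlation between the per-frame I(0) trace and the RI trace
#' (UV fallback when RI is absent) resampled to the frame time grid.
#'
#' Sign convention: a chromatogram feature at time \eqn{t} corresponds to
#' frames at \eqn{t - lag}; equivalently, frame \eqn{t} maps to
#' chromatogram time \eqn{t + lag}.
#'
#' @param i0Trace data.frame from [rgTrace()] (columns \code{time},
#'   \code{i0}); undetected frames enter as zero signal.
#' @param chrom a [Chromatogram-class].
#' @param searchWindow maximum |lag| searched, s.
#' @param step lag grid step, s; default a quarter of the frame spacing.
#' @return The lag in seconds (attribute \code{"correlation"} carries the
#'   peak normalized correlation).
#' @export
alignTimelines <- function(i0Trace, chrom, searchWindow = 60, step = NULL) {
  t <- i0Trace$time
  s <- ifelse(is.na(i0Trace$i0), 0, i0Trace$i0)
  stopIfNot(any(s > 0), "no detected I(0) peak to align")
  refSig <- if (hasSignal(chrom, "ri")) signalTrace(chrom, "ri")
    else signalTrace(chrom, "uv")
  refSig <- refSig - stats::median(refSig)
  if (is.null(step))
    step <- if (length(t) > 1) diff(t[1:2]) / 4 else 0.25
  lags <- seq(-searchWindow, searchWindow, by = step)
  s0 <- s - mean(s)
  corAt <- function(lag) {
    r <- interpNA(chrom@time, refSig, t + lag)
    ok <- !is.na(r)
    if (sum(ok) < 3) return(-Inf)
    r <- r[ok] - mean(r[ok])
    den <- sqrt(sum(s0[ok]^2) * sum(r^2))
    if (den == 0) return(-Inf)
    sum(s0[ok] * r) / den
  }
  cc <- vapply(lags, corAt, numeric(1))
  best <- which.max(cc)
  if (!is.finite(cc[best]) || cc[best] < 0.5)
    stop("alignment unreliable: correlation peak below 0.5", call. = FALSE)
  lag <- refineApex(lags, cc, best)
  attr(lag, "correlation") <- cc[best]
  lag
}

#' Per-frame solute concentration from the chromatogram
#'
#' Interpolates the RI-derived concentration trace onto the SAXS frame
#' midpoints after timeline alignment. Frames outside the chromatogram
#' coverage (or in the masked RI baseline) get \code{NA}.
#'
#' @param chrom a [Chromatogram-class] with an RI trace.
#' @param cal a [TDACalibration-class].
#' @param frameTimes frame midpoints, s (e.g. [frameTimes()]).
#' @param lag alignment lag from [alignTimelines()], s.
#' @param maskK RI signal-mask multiplier (see [concentrationFromRi()]).
#' @param correctBaseline set \code{FALSE} when the chromatogram already
#'   holds baseline-corrected traces.
#' @return Concentration per frame, mg/ml (NA where masked/uncovered).
#' @export
perFrameConcentration <- function(chrom, cal, frameTimes, lag = 0,
    maskK = 3, correctBaseline = TRUE) {
  ri <- signalTrace(chrom, "ri")
  if (correctBaseline) ri <- baselineCorrect(ri, chrom@volume)
  conc <- concentrationFromRi(ri, cal, maskK = maskK)
  # interpolate only across the unmasked peak region; NA elsewhere
  ok <- !is.na(conc)
  stopIfNot(any(ok), "concentration trace entirely masked")
  interpNA(chrom@time[ok], conc[ok], frameTimes + lag)
}

#' Normalize subtracted frames by concentration
#'
#' Divides every frame's net intensities (and uncertainties) by its
#' solute concentration, putting all frames on an intensity-per-(mg/ml)
#' scale so that frames of a pure species become directly comparable and
#' averageable. Frames with missing or sub-threshold concentration are
#' dropped.
#'
#' @param sub a [SubtractedSeries-class].
#' @param conc per-frame concentration, mg/ml (from
#'   [perFrameConcentration()]).
#' @param minConc minimum usable concentration, mg/ml.
#' @return A [SubtractedSeries-class] containing only the retained frames
#'   (attribute \code{"kept"} maps its columns to the input frame
#'   positions).
#' @export
normalizeByConcentration <- function(sub, conc, minConc = 0.01) {
  stopIfNot(length(conc) == nFrames(sub),
    "one concentration per frame required")
  keep <- which(!is.na(conc) & conc > minConc)
  stopIfNot(length(keep) > 0,
    "all frames masked or below the concentration threshold")
  out <- new("SubtractedSeries", q = sub@q,
    I = sweep(sub@I[, keep, drop = FALSE], 2, conc[keep], "/"),
    sigma = sweep(sub@sigma[, keep, drop = FALSE], 2, conc[keep], "/"),
    index = sub@index[keep], time = sub@time[keep],
    exposure = sub@exposure[keep], transmission = sub@transmission[keep],
    mode = sub@mode, bufferWindow = sub@bufferWindow,
    bufferAverage = sub@bufferAverage)
  attr(out, "kept") <- keep
  out
}

#' Molecular weight from calibrated forward scattering
#'
#' The forward scattering of an ideal dilute solution is proportional to
#' concentration x molecular weight, so against a standard measured under
#' the identical beam and geometry:
#' \eqn{MW = MW_{ref} \times \frac{I(0)/c}{(I(0)/c)_{ref}}.}
#'
#' @param i0PerC concentration-normalized forward scattering of the
#'   sample, intensity per (mg/ml).
#' @param refMw standard molecular weight, kDa.
#' @param refI0PerC concentration-normalized forward scattering of the
#'   standard.
#' @return MW, kDa.
#' @export
mwFromI0 <- function(i0PerC, refMw, refI0PerC) {
  stopIfNot(all(i0PerC > 0), "i0PerC must be > 0")
  stopIfNot(refMw > 0 && refI0PerC > 0, "reference values must be > 0")
  refMw * i0PerC / refI0PerC
}

#' Select frames with mutually consistent Rg
#'
#' Within a peak's frame range, keeps the frames whose fitted Rg lies
#' within tolerance of the running median — the set that is averaged into
#' the final component curve. The tolerance is the larger of a relative
#' bound and 2 x the frame's own Rg uncertainty. Contiguity is not
#' required.
#'
#' @param trace data.frame from [rgTrace()].
#' @param peakFrames frame positions (rows of \code{trace}) composing the
#'   peak.
#' @param tolerance relative Rg tolerance.
#' @return Integer frame positions; error when fewer than 3 frames
#'   qualify.
#' @export
selectConsistentFrames <- function(trace, peakFrames, tolerance = 0.05) {
  sel <- peakFrames[trace$status[peakFrames] == "ok"]
  stopIfNot(length(sel) >= 3,
    "peak too weak for averaging: fewer than 3 successful Guinier fits")
  med <- stats::median(trace$rg[sel])
  tol <- pmax(tolerance * med, 2 * trace$rgSd[sel])
  keep <- sel[abs(trace$rg[sel] - med) <= tol]
  stopIfNot(length(keep) >= 3,
    "peak too weak for averaging: fewer than 3 consistent frames")
  keep
}

#' Average selected frames into the final component curve
#'
#' @param normalized a concentration-normalized [SubtractedSeries-class].
#' @param selection frame positions to average (nonempty).
#' @return The averaged [ScatteringCurve-class].
#' @export
buildComponentCurve <- function(normalized, selection) {
  stopIfNot(length(selection) >= 1, "empty frame selection")
  averageFrames(normalized, selection)
}

#' Cross-compare the molecular-weight estimates of a component
#'
#' Pairwise relative comparison of the light-scattering, forward-
#' scattering and column-calibration molecular weights; disagreement
#' beyond tolerance may point to the composition of the sample. When an
#' expected oligomer ladder (multiples of a monomer mass) is supplied,
#' the best-matching oligomeric state is reported.
#'
#' @param mwRals,mwI0,mwSec the three estimates, kDa (NA when
#'   unavailable).
#' @param monomerMw optional monomer mass, kDa, defining the ladder.
#' @param tolerance relative tolerance for a consistent pair.
#' @param maxOligomer largest ladder state considered.
#' @return A list: \code{status} ("consistent", "inconsistent" or
#'   "insufficient estimates"), \code{pairs} (per-pair relative difference
#'   and verdict), \code{oligomer} (state, expected mass, relative
#'   deviation; NULL without a ladder).
#' @export
consistencyReport <- function(mwRals = NA, mwI0 = NA, mwSec = NA,
    monomerMw = NULL, tolerance = 0.10, maxOligomer = 12) {
  est <- c(rals = as.numeric(mwRals), i0 = as.numeric(mwI0),
    sec = as.numeric(mwSec))
  have <- est[is.finite(est) & est > 0]
  pairs <- list()
  if (length(have) >= 2) {
    nm <- names(have)
    for (i in seq_len(length(have) - 1)) for (j in (i + 1):length(have)) {
      rel <- abs(have[i] - have[j]) / mean(c(have[i], have[j]))
      pairs[[paste(nm[i], nm[j], sep = "-")]] <-
        list(relDiff = unname(rel), consistent = rel <= tolerance)
    }
    status <- if (all(vapply(pairs, `[[`, logical(1), "consistent")))
      "consistent" else "inconsistent"
  } else {
    status <- "insufficient estimates"
  }
  oligomer <- NULL
  if (!is.null(monomerMw) && length(have) >= 1) {
    mwMean <- mean(have)
    states <- seq_len(maxOligomer)
    dev <- abs(mwMean - states * monomerMw) / (states * monomerMw)
    b <- which.min(dev)
    oligomer <- list(state = b, expectedMw = b * monomerMw,
      relDeviation = dev[b])
  }
  list(status = status, estimates = est, pairs = pairs,
    oligomer = oligomer, tolerance = tolerance)
}
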
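#' Normalize frames for exposure time and transmission
#'
#' Divides every frame's intensities and uncertainties by
#' (exposure x transmission), putting all frames of a run on a common
#' rate scale. Idempotent: the returned series has exposure and
#' transmission set to 1.
#'
#' @param series a [FrameSeries-class].
#' @return A normalized [FrameSeries-class].
#' @export
normalizeFrames <- function(series) {
  stopIfNot(all(series@exposure > 0), "exposure must be > 0")
  stopIfNot(all(series@transmission > 0), "transmission must be > 0")
  f <- series@exposure * series@transmission
  series@I <- sweep(series@I, 2, f, "/")
  series@sigma <- sweep(series@sigma, 2, f, "/")
  series@exposure <- rep(1, nFrames(series))
  series@transmission <- rep(1, nFrames(series))
  series
}

#' Normalize a single curve for exposure and transmission
#'
#' Curve-level form of [normalizeFrames()].
#'
#' @param curve a [ScatteringCurve-class].
#' @param exposure exposure time, s, > 0.
#' @param transmission transmission factor, > 0.
#' @export
normalizeFrame <- function(curve, exposure, transmission = 1) {
  stopIfNot(exposure > 0, "exposure must be > 0")
  stopIfNot(transmission > 0, "transmission must be > 0")
  f <- exposure * transmission
  scatteringCurve(curve@q, curve@I / f, curve@sigma / f)
}

#' Reduced discrepancy score between two frames
#'
#' Mean over q points of \eqn{(I_a - I_b)^2 / (\sigma_a^2 + \sigma_b^2)}.
#' Statistically identical frames score about 1; the score grows with any
#' systematic difference. Points where both uncertainties are zero are
#' dropped; if no point carries an uncertainty the score falls back to the
#' relative RMS difference with a warning.
#'
#' @param a,b [ScatteringCurve-class] objects on the same q grid.
#' @return A single non-negative score.
#' @export
frameSimilarity <- function(a, b) {
  stopIfNot(length(a@q) == length(b@q) && all(a@q == b@q),
    "curves are on different q grids")
  v <- a@sigma^2 + b@sigma^2
  ok <- v > 0
  if (!any(ok)) {
    warning("all uncertainties zero; falling back to relative RMS difference")
    ref <- sqrt(mean(((a@I + b@I) / 2)^2))
    if (ref == 0) return(0)
    return(sqrt(mean((a@I - b@I)^2)) / ref)
  }
  mean((a@I[ok] - b@I[ok])^2 / v[ok])
}

# score of each frame in `idx` against the window mean
windowSimilarity <- function(series, idx) {
  avg <- averageFrames(series, idx)
  vapply(idx, function(i) frameSimilarity(frameCurve(series, i), avg),
    numeric(1))
}

#' Identify a stable buffer-frame window
#'
#' Finds a contiguous window of frames containing solely buffer
#' scattering, suitable for background averaging: the window must sit in
#' the low plateau of the smoothed total-intensity trace, its frames must
#' be mutually consistent (reduced discrepancy vs the window mean below
#' \code{simThreshold}), and, when an RI trace is supplied, must lie
#' within the RI baseline (|RI - baseline| < \code{riK} x baseline noise —
#' the RI baseline is a sensitive monitor of solvent composition). Among
#' admissible windows the earliest (pre-peak) is preferred; post-peak
#' windows are considered only with \code{allowPostPeak}.
#'
#' @param series a normalized [FrameSeries-class].
#' @param chrom optional [Chromatogram-class] with an RI trace.
#' @param minWindow window length in frames (default 50 for SEC runs; use
#'   ~5 for batch runs).
#' @param simThreshold reduced-discrepancy acceptance threshold.
#' @param riK RI baseline multiplier.
#' @param allowPostPeak consider windows after the global intensity
#'   maximum as well.
#' @return Integer vector of frame positions (contiguous).
#' @export
identifyBufferFrames <- function(series, chrom = NULL, minWindow = 50,
    simThreshold = 1.5, riK = 3, allowPostPeak = FALSE) {
  nf <- nFrames(series)
  stopIfNot(nf >= 2 * minWindow,
    sprintf("need >= %d frames for a %d-frame buffer window",
      2 * minWindow, minWindow))
  tot <- colSums(series@I)
  sm <- as.numeric(stats::runmed(tot, k = min(5, nf - (1 - nf %% 2))))
  wmean <- rollMean(sm, minWindow)
  starts <- seq_len(nf - minWindow + 1)
  centers <- starts + minWindow %/% 2
  level <- wmean[pmin(centers, nf)]
  floorLevel <- min(level)
  # plateau noise from frame-to-frame jitter in the quietest quartile
  quiet <- which(sm <= stats::quantile(sm, 0.25))
  noiseT <- stats::mad(diff(tot[quiet])) / sqrt(2)
  if (!is.finite(noiseT) || noiseT == 0) noiseT <- 1e-12 * max(abs(tot), 1)
  cand <- starts[level <= floorLevel + 2 * noiseT]
  if (!allowPostPeak) {
    apex <- which.max(sm)
    pre <- cand[cand + minWindow - 1 < apex]
    if (length(pre)) cand <- pre
  }
  riCorr <- NULL
  riNoise <- NULL
  if (!is.null(chrom) && hasSignal(chrom, "ri")) {
    riCorr <- baselineCorrect(signalTrace(chrom, "ri"), chrom@volume)
    riNoise <- baselineNoise(riCorr)
  }
  riOk <- function(idx) {
    if (is.null(riCorr)) return(TRUE)
    riF <- interpNA(chrom@time, riCorr, series@time[idx])
    all(is.na(riF) | abs(riF) < riK * riNoise)
  }
  for (s in cand) {
    idx <- s:(s + minWindow - 1)
    if (!riOk(idx)) next
    if (max(windowSimilarity(series, idx)) > simThreshold) next
    return(idx)
  }
  stop(paste("no stable buffer region found; consider selecting buffer",
    "frames manually"), call. = FALSE)
}

#' Average scattering curves
#'
#' Pointwise mean with propagated uncertainty
#' \eqn{\sigma_{avg} = \sqrt{\sum \sigma_i^2}/n}.
#'
#' @param x a list of [ScatteringCurve-class] objects on a common grid, or
#'   a [FrameSeries-class].
#' @param idx frame positions to average when \code{x} is a series
#'   (default: all).
#' @return A [ScatteringCurve-class].
#' @export
averageFrames <- function(x, idx = NULL) {
  if (is(x, "FrameSeries")) {
    if (is.null(idx)) idx <- seq_len(nFrames(x))
    stopIfNot(length(idx) >= 1, "cannot average an empty selection")
    n <- length(idx)
    return(scatteringCurve(x@q,
      rowMeans(x@I[, idx, drop = FALSE]),
      sqrt(rowSums(x@sigma[, idx, drop = FALSE]^2)) / n))
  }
  stopIfNot(is.list(x) && length(x) >= 1, "cannot average an empty list")
  q0 <- x[[1]]@q
  for (cv in x)
    stopIfNot(length(cv@q) == length(q0) && all(cv@q == q0),
      "curves are on different q grids")
  n <- length(x)
  I <- rowMeans(vapply(x, intensities, numeric(length(q0))))
  S <- sqrt(rowSums(matrix(vapply(x, sigmas, numeric(length(q0)))^2,
    nrow = length(q0)))) / n
  scatteringCurve(q0, I, S)
}

#' Subtract buffer background from a sample curve
#'
#' \eqn{I = I_s - I_b}, \eqn{\sigma = \sqrt{\sigma_s^2 + \sigma_b^2}}.
#' Negative net intensities are preserved, not clipped: clipping would
#' bias downstream Guinier fits.
#'
#' @param sample,buffer [ScatteringCurve-class] objects on the same grid.
#' @return The net solute [ScatteringCurve-class].
#' @export
subtractBackground <- function(sample, buffer) {
  stopIfNot(length(sample@q) == length(buffer@q) &&
    all(sample@q == buffer@q), "curves are on different q grids")
  scatteringCurve(sample@q, sample@I - buffer@I,
    sqrt(sample@sigma^2 + buffer@sigma^2))
}

#' Subtract an averaged buffer from every frame of a series
#'
#' @param series a normalized [FrameSeries-class].
#' @param bufferIdx frame positions of the buffer window (e.g. from
#'   [identifyBufferFrames()]); alternatively supply \code{buffer}.
#' @param buffer optional externally measured buffer
#'   [ScatteringCurve-class] (batch mode); \code{bufferIdx} may then be
#'   empty.
#' @return A [SubtractedSeries-class] carrying the buffer provenance.
#' @export
subtractSeries <- function(series, bufferIdx = integer(), buffer = NULL) {
  if (is.null(buffer)) {
    stopIfNot(length(bufferIdx) >= 1, "no buffer frames given")
    buffer <- averageFrames(series, bufferIdx)
  }
  I <- series@I - buffer@I
  S <- sqrt(series@sigma^2 + matrix(buffer@sigma^2, nrow = length(series@q),
    ncol = nFrames(series)))
  new("SubtractedSeries", q = series@q, I = I, sigma = S,
    index = series@index, time = series@time, exposure = series@exposure,
    transmission = series@transmission, mode = series@mode,
    bufferWindow = as.integer(bufferIdx), bufferAverage = buffer)
}

#' Screen successive exposures for radiation damage
#'
#' Compares each frame against the running average of the preceding
#' accepted frames via [frameSimilarity()]; the first index whose score
#' exceeds \code{threshold} for \code{minConsecutive} consecutive frames
#' is reported as the damage onset. Frames from the onset are not added to
#' the running average.
#'
#' @param series a [FrameSeries-class] with >= 2 frames (normalize first).
#' @param threshold reduced-discrepancy threshold.
#' @param minConsecutive consecutive exceedances required.
#' @return A list: \code{damaged} (logical), \code{firstIndex} (frame
#'   position of onset, NA if none), \code{scores} (per-frame scores,
#'   first frame NA).
#' @export
detectRadiationDamage <- function(series, threshold = 4,
    minConsecutive = 2) {
  nf <- nFrames(series)
  stopIfNot(nf >= 2, "need >= 2 frames to assess damage")
  scores <- rep(NA_real_, nf)
  accepted <- 1L
  streak <- 0L
  first <- NA_integer_
  for (f in 2:nf) {
    avg <- averageFrames(series, accepted)
    scores[f] <- frameSimilarity(frameCurve(series, f), avg)
    if (scores[f] > threshold) {
      streak <- streak + 1L
      if (is.na(first)) first <- f
      if (streak >= minConsecutive)
        return(list(damaged = TRUE, firstIndex = first,
          scores = scores))
    } else {
      streak <- 0L
      first <- NA_integer_
      accepted <- c(accepted, f)
    }
  }
  list(damaged = FALSE, firstIndex = NA_integer_, scores = scores)
}
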
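#' Construct a ScatteringCurve
#'
#' @param q strictly increasing momentum transfer, nm^-1, all > 0.
#' @param I intensities.
#' @param sigma 1-sigma uncertainties; defaults to zero (unweighted).
#' @return A [ScatteringCurve-class].
#' @examples
#' sc <- scatteringCurve(q = c(0.1, 0.2, 0.3), I = c(100, 80, 60))
#' qValues(sc)
#' @export
scatteringCurve <- function(q, I, sigma = rep(0, length(q))) {
  new("ScatteringCurve", q = as.numeric(q), I = as.numeric(I),
    sigma = as.numeric(sigma))
}

#' @describeIn scatteringCurve momentum-transfer grid accessor.
#' @param x a ScatteringCurve or FrameSeries.
#' @export
qValues <- function(x) x@q

#' @describeIn scatteringCurve intensity accessor (vector for a curve,
#'   matrix for a series).
#' @export
intensities <- function(x) x@I

#' @describeIn scatteringCurve uncertainty accessor.
#' @export
sigmas <- function(x) x@sigma

setMethod("length", "ScatteringCurve", function(x) length(x@q))

setMethod("show", "ScatteringCurve", function(object) {
  n <- length(object@q)
  cat(sprintf("ScatteringCurve: %d points, q %.4g..%.4g nm^-1\n",
    n, if (n) min(object@q) else NA, if (n) max(object@q) else NA))
})

#' Construct a FrameSeries
#'
#' @param q common momentum-transfer grid, nm^-1.
#' @param I intensity matrix (length(q) x nFrames).
#' @param sigma uncertainty matrix of the same shape.
#' @param time frame acquisition midpoints, s.
#' @param exposure exposure per frame, s (recycled).
#' @param transmission transmission per frame in (0,1] (recycled).
#' @param index frame numbers; default 1..nFrames.
#' @param mode "batch" or "sec".
#' @return A [FrameSeries-class].
#' @export
frameSeries <- function(q, I, sigma, time,
    exposure = 1, transmission = 1,
    index = seq_len(ncol(I)), mode = c("sec", "batch")) {
  mode <- match.arg(mode)
  nf <- ncol(I)
  new("FrameSeries", q = as.numeric(q), I = I, sigma = sigma,
    index = as.integer(index), time = as.numeric(time),
    exposure = rep_len(as.numeric(exposure), nf),
    transmission = rep_len(as.numeric(transmission), nf), mode = mode)
}

#' Number of frames in a series
#' @param series a [FrameSeries-class].
#' @export
nFrames <- function(series) ncol(series@I)

#' Extract one frame as a ScatteringCurve
#' @param series a [FrameSeries-class].
#' @param i frame position (column), 1-based.
#' @export
frameCurve <- function(series, i) {
  stopIfNot(i >= 1 && i <= nFrames(series), "frame position out of range")
  scatteringCurve(series@q, series@I[, i], series@sigma[, i])
}

#' Frame acquisition times
#' @param series a [FrameSeries-class].
#' @export
frameTimes <- function(series) series@time

setMethod("show", "FrameSeries", function(object) {
  cat(sprintf("FrameSeries (%s mode): %d frames x %d q points, t %.4g..%.4g s\n",
    object@mode, ncol(object@I), length(object@q),
    min(object@time), max(object@time)))
})

setMethod("show", "SubtractedSeries", function(object) {
  cat(sprintf(
    "SubtractedSeries: %d frames x %d q points; buffer window %d..%d (%d frames)\n",
    ncol(object@I), length(object@q),
    min(object@bufferWindow), max(object@bufferWindow),
    length(object@bufferWindow)))
})

#' @describeIn subtractSeries buffer window provenance accessor.
#' @export
bufferWindow <- function(sub) sub@bufferWindow

#' @describeIn subtractSeries averaged buffer curve accessor.
#' @export
bufferAverage <- function(sub) sub@bufferAverage
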
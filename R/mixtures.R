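#' Decompose a mixture curve into component volume fractions
#'
#' Oligomer-style constrained fit: the mixture curve is modeled as a
#' scaled convex combination of concentration-normalized component form
#' factors,
#' \deqn{\min_{k, f} \sum_q \left[\frac{I_{mix}(q) - k \sum_i f_i
#'   I_i(q)}{\sigma(q)}\right]^2, \quad f_i \ge 0,\ \sum_i f_i = 1,}
#' solved by non-negative least squares on the unnormalized weights
#' followed by normalization (the overall scale k absorbs the sum).
#' Component curves must be on the mixture's q grid and in
#' intensity-per-(mg/ml) units so the fitted weights are weight
#' fractions.
#'
#' @param mixture a [ScatteringCurve-class].
#' @param components list of >= 2 component [ScatteringCurve-class]
#'   objects (named list names label the fractions).
#' @param background include a flat free background term in the fit
#'   (compensates imperfect subtraction; off by default).
#' @return A [MixtureFit-class] with fractions, scale and reduced
#'   chi-square.
#' @export
fitVolumeFractions <- function(mixture, components, background = FALSE) {
  stopIfNot(is.list(components) && length(components) >= 2,
    "need >= 2 component curves")
  q0 <- mixture@q
  for (cmp in components)
    stopIfNot(length(cmp@q) == length(q0) && all(cmp@q == q0),
      "components must share the mixture q grid")
  m <- length(components)
  nm <- names(components)
  if (is.null(nm)) nm <- paste0("component", seq_len(m))
  A <- vapply(components, intensities, numeric(length(q0)))
  dim(A) <- c(length(q0), m)
  w <- ifelse(mixture@sigma > 0, 1 / mixture@sigma, 1)
  Aw <- A * w
  bw <- mixture@I * w
  if (background) {
    Aw <- cbind(Aw, w)  # flat background column
  }
  # degeneracy guard on column-normalized design
  An <- sweep(Aw, 2, sqrt(colSums(Aw^2)), "/")
  if (kappa(An, exact = TRUE) > 1e6)
    stop("component curves are collinear: mixture fit is degenerate",
      call. = FALSE)
  sol <- pracma::lsqnonneg(Aw, bw)
  x <- sol$x[seq_len(m)]
  k <- sum(x)
  stopIfNot(k > 0, "all-zero solution: mixture has no component signal")
  fractions <- x / k
  names(fractions) <- nm
  resid <- bw - Aw %*% sol$x
  dof <- max(1, length(q0) - length(sol$x))
  new("MixtureFit", fractions = fractions, scale = k,
    chi2 = sum(resid^2) / dof, window = c(NA_integer_, NA_integer_))
}

setMethod("show", "MixtureFit", function(object) {
  fr <- paste(sprintf("%s = %.3f", names(object@fractions),
    object@fractions), collapse = ", ")
  cat(sprintf("MixtureFit: %s (scale %.4g, reduced chi2 %.3g)\n",
    fr, object@scale, object@chi2))
})

#' @describeIn fitVolumeFractions fraction accessor.
#' @param fit a [MixtureFit-class].
#' @export
volumeFractions <- function(fit) fit@fractions

#' Rolling volume-fraction trace across a run
#'
#' Averages sliding non-overlapping windows of frames and fits each
#' averaged curve with [fitVolumeFractions()] — the frame-window analogue
#' of fitting distinct form-factor ratios across the elution profile.
#' Windows whose fit fails (e.g. no signal) are skipped.
#'
#' @param sub a background-subtracted (optionally concentration-
#'   normalized) [FrameSeries-class].
#' @param components component curves as in [fitVolumeFractions()].
#' @param window frames per window.
#' @param background see [fitVolumeFractions()].
#' @return A data.frame: window bounds (frame positions), center time,
#'   one fraction column per component, \code{chi2}.
#' @export
rollingFractionTrace <- function(sub, components, window = 10,
    background = FALSE) {
  nf <- nFrames(sub)
  stopIfNot(nf >= window, "fewer frames than one window")
  starts <- seq(1, nf - window + 1, by = window)
  m <- length(components)
  nm <- names(components)
  if (is.null(nm)) nm <- paste0("component", seq_len(m))
  rows <- list()
  for (s in starts) {
    idx <- s:(s + window - 1)
    avg <- averageFrames(sub, idx)
    fit <- tryCatch(
      fitVolumeFractions(avg, components, background = background),
      error = function(e) NULL)
    if (is.null(fit)) next
    row <- data.frame(firstFrame = s, lastFrame = s + window - 1,
      centerTime = mean(sub@time[idx]), chi2 = fit@chi2)
    for (i in seq_len(m)) row[[nm[i]]] <- fit@fractions[i]
    rows[[length(rows) + 1]] <- row
  }
  stopIfNot(length(rows) > 0, "no window produced a successful fit")
  do.call(rbind, rows)
}

#' Small-species fraction from the TDA molecular-weight trace
#'
#' Converts the RALS/RI molecular-weight trace of a two-state system into
#' the weight fraction of the smaller species. Two variants:
#' \describe{
#'   \item{weight_average}{\eqn{f_{small} = (MW_{big} - MW_w) /
#'     (MW_{big} - MW_{small})}, clipped to [0, 1] — the exact inversion
#'     of a two-state weight-average molecular weight
#'     \eqn{MW_w = f\,MW_{small} + (1-f)\,MW_{big}}.}
#'   \item{paper_literal}{\eqn{f_{small} = (MW_{big} - MW_w) /
#'     MW_{small}} — the ratio as printed alongside the original
#'     dimer/tetramer analysis; coincides with the exact inversion only
#'     when \eqn{MW_{big} \approx 2\,MW_{small}}. Retained unclipped for
#'     reproducing that analysis; not silently corrected.}
#' }
#'
#' @param mwTrace weight-average MW trace, kDa (NA allowed).
#' @param mwBig,mwSmall the two species masses, kDa, \code{mwBig >
#'   mwSmall > 0}.
#' @param variant which formula to apply.
#' @return Fraction trace (NA where \code{mwTrace} is NA).
#' @export
tdaDimerFraction <- function(mwTrace, mwBig, mwSmall,
    variant = c("weight_average", "paper_literal")) {
  variant <- match.arg(variant)
  stopIfNot(mwSmall > 0 && mwBig > mwSmall,
    "need mwBig > mwSmall > 0")
  if (variant == "weight_average")
    pmin(pmax((mwBig - mwTrace) / (mwBig - mwSmall), 0), 1)
  else
    (mwBig - mwTrace) / mwSmall
}

#' Cross-validate SAXS and TDA fraction traces
#'
#' Interpolates the TDA-derived fraction trace onto the SAXS rolling-
#' window centers and summarizes the agreement. Close agreement
#' demonstrates that the scattering and detector streams observe the same
#' separated components.
#'
#' @param saxsTrace data.frame from [rollingFractionTrace()].
#' @param component fraction column of \code{saxsTrace} to compare.
#' @param tdaFraction TDA fraction trace (e.g. [tdaDimerFraction()]).
#' @param tdaTimes chromatogram times of \code{tdaFraction}, s.
#' @param lag timeline lag (chromatogram minus frames), s.
#' @return A list: \code{rms}, \code{max} absolute fraction difference,
#'   \code{n} compared windows, \code{detail} data.frame.
#' @export
crossValidateFractions <- function(saxsTrace, component, tdaFraction,
    tdaTimes, lag = 0) {
  stopIfNot(component %in% names(saxsTrace),
    sprintf("column '%s' absent from the SAXS trace", component))
  ok <- is.finite(tdaFraction)
  stopIfNot(any(ok), "TDA fraction trace entirely missing")
  tda <- interpNA(tdaTimes[ok], tdaFraction[ok],
    saxsTrace$centerTime + lag)
  cmp <- data.frame(centerTime = saxsTrace$centerTime,
    saxs = saxsTrace[[component]], tda = tda)
  cmp <- cmp[is.finite(cmp$tda) & is.finite(cmp$saxs), ]
  stopIfNot(nrow(cmp) > 0,
    "no overlapping elution coverage between the traces")
  d <- cmp$saxs - cmp$tda
  list(rms = sqrt(mean(d^2)), max = max(abs(d)), n = nrow(cmp),
    detail = cmp)
}
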
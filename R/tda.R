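#' Construct a TDACalibration
#'
#' @param kRals,kRi TDA instrument calibration constants.
#' @param dnDc refractive index increment, mL/g (0.185 for unmodified
#'   protein).
#' @param columnA,columnB column calibration line
#'   \eqn{\log_{10} MW = a - b V_e} (NA until fitted).
#' @param columnRange elution range covered by the column standards, ml.
#' @param standardName,standardMw standard protein (the monomeric BSA
#'   standard by default, 66.5 kDa).
#' @param standardI0PerC concentration-normalized forward scattering of
#'   the standard under the same beam/geometry (NA until measured).
#' @param epsilonRegistry named numeric, protein name -> epsilon 1\%.
#' @return A [TDACalibration-class].
#' @export
tdaCalibration <- function(kRals, kRi, dnDc = 0.185,
    columnA = NA_real_, columnB = NA_real_,
    columnRange = c(NA_real_, NA_real_),
    standardName = "BSA", standardMw = 66.5,
    standardI0PerC = NA_real_,
    epsilonRegistry = c(BSA = 6.14, HSA = 5.8)) {
  new("TDACalibration", kRals = kRals, kRi = kRi, dnDc = dnDc,
    columnA = columnA, columnB = columnB,
    columnRange = as.numeric(columnRange),
    standardName = standardName, standardMw = standardMw,
    standardI0PerC = standardI0PerC,
    epsilonRegistry = epsilonRegistry)
}

setMethod("show", "TDACalibration", function(object) {
  cat(sprintf("TDACalibration: kRals = %.4g, kRi = %.4g, dn/dc = %.3f mL/g\n",
    object@kRals, object@kRi, object@dnDc))
  if (is.finite(object@columnA))
    cat(sprintf("  column: log10 MW = %.3f - %.3f Ve\n",
      object@columnA, object@columnB))
  if (is.finite(object@standardI0PerC))
    cat(sprintf("  I(0) reference: %s, %.1f kDa, I0/c = %.4g\n",
      object@standardName, object@standardMw, object@standardI0PerC))
})

#' Baseline-correct a detector trace
#'
#' Subtracts a straight line interpolated between two flat reference
#' windows. With explicit \code{regions} the line passes through the
#' medians of those windows; otherwise the flattest (lowest-variance)
#' windows of 5\% trace length in the first and last thirds are selected
#' automatically.
#'
#' @param signal raw detector trace (length >= 20).
#' @param elution matching elution axis (volume or time); defaults to the
#'   point index.
#' @param regions optional list of two index vectors (the reference
#'   windows).
#' @return Numeric corrected trace (attribute \code{"baselineRegions"}
#'   carries the windows used).
#' @export
baselineCorrect <- function(signal, elution = seq_along(signal),
    regions = NULL) {
  n <- length(signal)
  stopIfNot(n >= 20, "trace too short for baseline correction (< 20 points)")
  if (is.null(regions)) {
    w <- max(3L, as.integer(round(0.05 * n)))
    xw <- seq_len(w) - (w + 1) / 2
    sxx <- sum(xw^2)
    detrendVar <- function(y) {
      r <- y - mean(y) - (sum(xw * y) / sxx) * xw
      sum(r^2) / max(1, w - 2)
    }
    pickFlat <- function(from, to) {
      starts <- from:(to - w + 1)
      v <- vapply(starts, function(s) detrendVar(signal[s:(s + w - 1)]),
        numeric(1))
      m <- vapply(starts, function(s) stats::median(signal[s:(s + w - 1)]),
        numeric(1))
      # a low-amplitude peak apex is locally as flat as baseline, so among
      # near-minimal-variance windows take the lowest-lying one
      flat <- which(v <= 4 * min(v) + 1e-300)
      s <- starts[flat[which.min(m[flat])]]
      list(idx = s:(s + w - 1), var = v[match(s, starts)])
    }
    lo <- pickFlat(1L, max(w, as.integer(floor(n / 3))))
    hi <- pickFlat(min(n - w + 1L, as.integer(ceiling(2 * n / 3))), n)
    # flat means: residuals about a local line are no larger than the
    # point-to-point jitter of the trace
    sigma0 <- stats::mad(diff(signal)) / sqrt(2)
    if (min(sqrt(lo$var), sqrt(hi$var)) >
        3 * sigma0 + 1e-9 * max(abs(signal), 1e-300))
      stop(paste("automatic baseline selection failed (no flat windows);",
        "supply explicit regions"), call. = FALSE)
    regions <- list(lo$idx, hi$idx)
  }
  stopIfNot(is.list(regions) && length(regions) == 2,
    "regions must be a list of two index windows")
  x1 <- stats::median(elution[regions[[1]]])
  x2 <- stats::median(elution[regions[[2]]])
  y1 <- stats::median(signal[regions[[1]]])
  y2 <- stats::median(signal[regions[[2]]])
  base <- if (x2 == x1) rep(y1, n) else y1 + (y2 - y1) * (elution - x1) / (x2 - x1)
  out <- signal - base
  attr(out, "baselineRegions") <- regions
  out
}

# robust baseline noise of a corrected trace: MAD after masking points
# above 5 x an initial MAD estimate
baselineNoise <- function(corrected) {
  s0 <- stats::mad(corrected, center = 0)
  if (s0 == 0) return(max(1e-12 * max(abs(corrected), 1e-300), 0))
  keep <- abs(corrected) <= 5 * s0
  s1 <- stats::mad(corrected[keep], center = 0)
  max(s1, 1e-12 * max(abs(corrected)))
}

#' Detect elution peaks in a corrected trace
#'
#' Flags contiguous regions where the baseline-corrected signal exceeds
#' \code{k} x the baseline noise, extends each region outward to the first
#' crossing of 0.5 x noise, and splits merged regions at internal local
#' minima deeper than 20\% of the lower flanking apex. Apex positions are
#' refined by parabolic interpolation; areas are trapezoidal integrals
#' over the region.
#'
#' @param corrected baseline-corrected trace (from [baselineCorrect()]).
#' @param elution matching elution-volume axis, ml.
#' @param k detection threshold in baseline-noise units.
#' @return A data.frame with one row per peak: \code{start}, \code{apex},
#'   \code{end} (ml), \code{height}, \code{area} (signal x ml),
#'   \code{iStart}, \code{iApex}, \code{iEnd} (indices). Zero rows when
#'   nothing exceeds the threshold.
#' @export
detectPeaks <- function(corrected, elution = seq_along(corrected), k = 5) {
  n <- length(corrected)
  noise <- baselineNoise(corrected)
  above <- corrected > k * noise
  if (!any(above))
    return(data.frame(start = numeric(0), apex = numeric(0),
      end = numeric(0), height = numeric(0), area = numeric(0),
      iStart = integer(0), iApex = integer(0), iEnd = integer(0)))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  regions <- cbind(starts[r$values], ends[r$values])
  # extend to the first crossing of 0.5 x noise
  lowThr <- 0.5 * noise
  ext <- t(apply(regions, 1, function(rg) {
    a <- rg[1]; b <- rg[2]
    while (a > 1 && corrected[a - 1] > lowThr) a <- a - 1
    while (b < n && corrected[b + 1] > lowThr) b <- b + 1
    c(a, b)
  }))
  # merge overlapping extensions
  merged <- ext[order(ext[, 1]), , drop = FALSE]
  keep <- list(merged[1, ])
  if (nrow(merged) > 1) for (i in 2:nrow(merged)) {
    last <- keep[[length(keep)]]
    if (merged[i, 1] <= last[2] + 1)
      keep[[length(keep)]] <- c(last[1], max(last[2], merged[i, 2]))
    else keep[[length(keep) + 1]] <- merged[i, ]
  }
  # split merged components at deep internal minima (on a lightly
  # smoothed profile so single-point noise dips cannot split a peak)
  segments <- list()
  for (rg in keep) {
    idx <- rg[1]:rg[2]
    y <- rollMean(corrected[idx], 5)
    cuts <- integer(0)
    if (length(idx) >= 5) {
      interior <- 2:(length(y) - 1)
      mins <- interior[y[interior] < y[interior - 1] &
        y[interior] <= y[interior + 1]]
      for (m in mins) {
        apexL <- max(y[1:m]); apexR <- max(y[m:length(y)])
        if (min(apexL, apexR) > 2 * k * noise &&
            y[m] < 0.8 * min(apexL, apexR))
          cuts <- c(cuts, m)
      }
    }
    bounds <- c(1, sort(unique(cuts)), length(y))
    for (s in seq_len(length(bounds) - 1))
      segments[[length(segments) + 1]] <- idx[bounds[s]:bounds[s + 1]]
  }
  # a split shard must itself clear the detection threshold
  segments <- Filter(function(seg) max(corrected[seg]) > k * noise,
    segments)
  rows <- lapply(segments, function(seg) {
    y <- corrected[seg]
    iA <- seg[which.max(y)]
    # apex refinement: least-squares parabola on the log signal over the
    # upper half of the peak (exact for a Gaussian, noise-averaged over
    # many points); falls back to a 3-point parabola on narrow peaks
    top <- seg[y > 0.5 * max(y) & y > 0]
    apexRef <- NA_real_
    if (length(top) >= 5) {
      x <- elution[top] - elution[iA]
      cf <- tryCatch(stats::lm.fit(cbind(1, x, x^2), log(corrected[top]))$coefficients,
        error = function(e) NULL)
      if (!is.null(cf) && is.finite(cf[3]) && cf[3] < 0)
        apexRef <- elution[iA] - cf[2] / (2 * cf[3])
    }
    if (!is.finite(apexRef) || abs(apexRef - elution[iA]) >
        (elution[seg[length(seg)]] - elution[seg[1]]) / 4)
      apexRef <- refineApex(elution, corrected, iA)
    data.frame(start = elution[seg[1]],
      apex = apexRef,
      end = elution[seg[length(seg)]],
      height = max(y),
      area = trapz(elution[seg], y),
      iStart = seg[1], iApex = iA, iEnd = seg[length(seg)])
  })
  out <- do.call(rbind, rows)
  out[order(out$apex), , drop = FALSE]
}

#' Calibrate detector constants from a standard-protein run
#'
#' Derives the TDA calibration constants from a run of a narrow monomeric
#' standard of known mass and injected amount:
#' \eqn{k_{RI} = \int RI\, dV / (dn/dc \times m \times s)} where \eqn{m}
#' is the injected mass and \eqn{s} the split fraction (only \eqn{m s}
#' milligrams traverse the detectors in a split-stream configuration —
#' calibration constants derived through peak integration must be
#' re-derived whenever the split changes), and
#' \eqn{k_{RALS} = RALS_{apex} / (c_{apex} (dn/dc)^2 MW)} with the apex
#' concentration from the freshly derived \eqn{k_{RI}}. The apex (rather
#' than integral) RALS avoids band-broadening mismatch between detectors.
#'
#' @param chrom standard-run [Chromatogram-class] with RI and RALS.
#' @param standardMw standard molecular weight, kDa.
#' @param injectedMass injected mass, mg (> 0).
#' @param splitFraction fraction of the flow through the TDA branch.
#' @param dnDc refractive index increment, mL/g.
#' @param standardName label stored in the calibration.
#' @return A [TDACalibration-class].
#' @export
calibrateFromStandard <- function(chrom, standardMw = 66.5, injectedMass,
    splitFraction = 0.5, dnDc = 0.185, standardName = "BSA") {
  stopIfNot(injectedMass > 0, "injected mass must be > 0")
  ri <- baselineCorrect(signalTrace(chrom, "ri"), chrom@volume)
  rals <- baselineCorrect(signalTrace(chrom, "rals"), chrom@volume)
  peaks <- detectPeaks(ri, chrom@volume)
  stopIfNot(nrow(peaks) >= 1, "no elution peak found in the RI trace")
  pk <- peaks[which.max(peaks$area), ]
  kRi <- pk$area / (dnDc * injectedMass * splitFraction)
  stopIfNot(kRi > 0, "non-positive RI peak area")
  cApex <- ri[pk$iApex] / (dnDc * kRi)
  ralsPk <- detectPeaks(rals, chrom@volume)
  ralsApex <- if (nrow(ralsPk))
    max(rals[ralsPk$iApex]) else max(rals)
  kRals <- ralsApex / (cApex * dnDc^2 * standardMw)
  tdaCalibration(kRals = kRals, kRi = kRi, dnDc = dnDc,
    standardName = standardName, standardMw = standardMw)
}

#' Concentration trace from the RI signal
#'
#' \eqn{c = RI / (dn/dc \times k_{RI})}, clipped at zero; sub-noise points
#' (below \code{maskK} x baseline noise) are masked as \code{NA} rather
#' than reported as spurious small concentrations.
#'
#' @param ri baseline-corrected RI trace.
#' @param cal a [TDACalibration-class].
#' @param maskK noise multiplier for the signal mask; 0 disables masking.
#' @return Concentration trace, mg/ml, with NA outside the signal mask.
#' @export
concentrationFromRi <- function(ri, cal, maskK = 3) {
  conc <- pmax(as.numeric(ri), 0) / (cal@dnDc * cal@kRi)
  if (maskK > 0) {
    noise <- baselineNoise(as.numeric(ri))
    conc[ri <= maskK * noise] <- NA_real_
  }
  conc
}

#' Concentration from UV absorbance
#'
#' \eqn{c = 10 A / (\epsilon_{1\%} \times path)} with \eqn{\epsilon_{1\%}}
#' the absorbance of a 10 mg/ml solution over 1 cm.
#'
#' @param absorbance absorbance at 280 nm, AU.
#' @param epsilon1pct extinction coefficient, (10 mg/ml)^-1 cm^-1.
#' @param path cuvette/cell path length, cm.
#' @return Concentration, mg/ml.
#' @export
concentrationFromUv <- function(absorbance, epsilon1pct, path = 1) {
  stopIfNot(epsilon1pct > 0, "epsilon 1% must be > 0")
  stopIfNot(path > 0, "path length must be > 0")
  10 * absorbance / (epsilon1pct * path)
}

#' Molecular-weight trace from RALS and RI
#'
#' Point-by-point inversion of the detector equations:
#' \deqn{MW = \frac{RALS}{RI} \cdot \frac{k_{RI}}{k_{RALS} \, dn/dc}.}
#' The division is guarded by an RI signal mask (RI > \code{maskK} x
#' baseline noise): outside the elution peak the ratio is pure noise and
#' is masked as \code{NA}.
#'
#' @param rals,ri baseline-corrected traces on a shared grid.
#' @param cal a [TDACalibration-class].
#' @param maskK RI mask multiplier.
#' @return MW trace, kDa, NA where masked.
#' @export
mwRalsTrace <- function(rals, ri, cal, maskK = 5) {
  stopIfNot(length(rals) == length(ri),
    "RALS and RI traces must share the grid")
  noise <- baselineNoise(as.numeric(ri))
  ok <- ri > maskK * noise
  if (!any(ok)) stop("no quantifiable region: RI entirely below its mask",
    call. = FALSE)
  mw <- rep(NA_real_, length(ri))
  mw[ok] <- (rals[ok] / ri[ok]) * cal@kRi / (cal@kRals * cal@dnDc)
  mw
}

#' Fit the conventional column calibration line
#'
#' Least squares of \eqn{\log_{10} MW} versus retention volume for
#' proteins of known mass: \eqn{\log_{10} MW = a - b V_e}.
#'
#' @param standards data.frame with columns \code{ve} (retention volume,
#'   ml) and \code{mw} (kDa); >= 2 distinct volumes.
#' @return A list \code{a}, \code{b} (slope magnitude, > 0 for a normal
#'   column) and \code{range} (volume span of the standards).
#' @seealso [mwSec()], [setColumnCalibration()]
#' @export
fitColumnCalibration <- function(standards) {
  stopIfNot(is.data.frame(standards) &&
    all(c("ve", "mw") %in% names(standards)),
    "standards must be a data.frame with columns ve and mw")
  stopIfNot(nrow(standards) >= 2, "need >= 2 column standards")
  stopIfNot(length(unique(standards$ve)) >= 2,
    "column standards need distinct retention volumes")
  fit <- wlsLine(standards$ve, log10(standards$mw))
  list(a = fit$intercept, b = -fit$slope, range = range(standards$ve))
}

#' Store a column calibration in a TDACalibration
#'
#' @param cal a [TDACalibration-class].
#' @param column result of [fitColumnCalibration()].
#' @return The updated calibration.
#' @export
setColumnCalibration <- function(cal, column) {
  cal@columnA <- column$a
  cal@columnB <- column$b
  cal@columnRange <- column$range
  validObject(cal)
  cal
}

#' Column-calibration molecular weight
#'
#' \eqn{MW = 10^{a - b V_e}} from the conventional column calibration.
#' Retention volumes more than 20\% outside the calibrated range flag the
#' result with attribute \code{"extrapolated" = TRUE}.
#'
#' @param retention retention volume, ml.
#' @param cal a [TDACalibration-class] with a fitted column line.
#' @return MW, kDa.
#' @export
mwSec <- function(retention, cal) {
  stopIfNot(is.finite(cal@columnA) && is.finite(cal@columnB),
    "column calibration not fitted")
  mw <- 10^(cal@columnA - cal@columnB * retention)
  rng <- cal@columnRange
  if (all(is.finite(rng))) {
    slack <- 0.2 * diff(rng)
    if (retention < rng[1] - slack || retention > rng[2] + slack) {
      warning("retention volume far outside the column calibration range")
      attr(mw, "extrapolated") <- TRUE
    }
  }
  mw
}

#' Determine dn/dc from the RI signal at known mass
#'
#' With the RI constant calibrated and the in-detector mass known, the
#' refractive index increment of an arbitrary (e.g. ligand-bound or
#' conjugated) solute follows from the integrated RI peak:
#' \eqn{dn/dc = \int RI \, dV / (k_{RI} \times m)}.
#'
#' @param riPeakArea integrated baseline-corrected RI over the peak,
#'   detector units x ml.
#' @param massInDetector solute mass traversing the detector, mg (> 0);
#'   injected mass x split fraction in a split-stream run.
#' @param cal a [TDACalibration-class] (provides \eqn{k_{RI}}).
#' @return dn/dc, mL/g. Values below 0.05 mL/g are flagged implausible
#'   via attribute \code{"implausible" = TRUE}.
#' @export
dndcFromKnownConcentration <- function(riPeakArea, massInDetector, cal) {
  stopIfNot(massInDetector > 0, "mass must be > 0")
  dndc <- riPeakArea / (cal@kRi * massInDetector)
  if (dndc < 0.05) attr(dndc, "implausible") <- TRUE
  dndc
}
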
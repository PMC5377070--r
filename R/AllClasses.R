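#' @import methods
NULL

#' One-dimensional scattering profile
#'
#' A single reduced small-angle scattering curve: momentum transfer
#' \eqn{q = 4\pi \sin\theta / \lambda} (nm\eqn{^{-1}}), intensities
#' (arbitrary or calibrated units) and their 1-sigma uncertainties.
#'
#' @slot q numeric, strictly increasing momentum transfer, nm^-1, all > 0.
#' @slot I numeric intensities, same length as \code{q}.
#' @slot sigma numeric non-negative 1-sigma uncertainties, same units as
#'   \code{I}; all zero is allowed (unweighted downstream fits).
#'
#' @seealso [scatteringCurve()], [readDat()], [writeDat()]
#' @exportClass ScatteringCurve
setClass("ScatteringCurve",
  representation(q = "numeric", I = "numeric", sigma = "numeric"))

setValidity("ScatteringCurve", function(object) {
  msg <- character()
  n <- length(object@q)
  if (length(object@I) != n || length(object@sigma) != n)
    msg <- c(msg, "q, I and sigma must have equal length")
  if (n > 0) {
    if (any(!is.finite(object@q)) || any(object@q <= 0))
      msg <- c(msg, "all q must be finite and > 0")
    else if (n > 1 && any(diff(object@q) <= 0))
      msg <- c(msg, "q must be strictly increasing")
    if (any(object@sigma < 0, na.rm = TRUE))
      msg <- c(msg, "all sigma must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Time-stamped series of scattering frames on a common q grid
#'
#' Column-per-frame storage of a frame series (batch or SEC mode) together
#' with acquisition metadata. Intensities are stored as recorded; use
#' [normalizeFrames()] to divide by exposure time and transmission.
#'
#' @slot q common momentum-transfer grid, nm^-1.
#' @slot I intensity matrix, \code{length(q)} rows, one column per frame.
#' @slot sigma matching uncertainty matrix.
#' @slot index unique integer frame numbers.
#' @slot time acquisition midpoints, s, non-decreasing.
#' @slot exposure per-frame exposure, s, > 0.
#' @slot transmission per-frame transmission factor in (0, 1].
#' @slot mode \code{"batch"} or \code{"sec"}.
#'
#' @seealso [frameSeries()], [readFrameSeries()], [simulateSecRun()]
#' @exportClass FrameSeries
setClass("FrameSeries",
  representation(q = "numeric", I = "matrix", sigma = "matrix",
    index = "integer", time = "numeric", exposure = "numeric",
    transmission = "numeric", mode = "character"))

setValidity("FrameSeries", function(object) {
  msg <- character()
  nf <- ncol(object@I)
  nq <- length(object@q)
  if (nrow(object@I) != nq || !identical(dim(object@I), dim(object@sigma)))
    msg <- c(msg, "I and sigma must be length(q) x n_frames matrices")
  for (s in c("index", "time", "exposure", "transmission"))
    if (length(slot(object, s)) != nf)
      msg <- c(msg, sprintf("%s must have one entry per frame", s))
  if (anyDuplicated(object@index))
    msg <- c(msg, "frame indices must be unique")
  if (length(object@time) > 1 && any(diff(object@time) < 0))
    msg <- c(msg, "frame times must be non-decreasing")
  if (any(object@exposure <= 0)) msg <- c(msg, "exposure must be > 0")
  if (any(object@transmission <= 0 | object@transmission > 1))
    msg <- c(msg, "transmission must be in (0, 1]")
  if (!object@mode %in% c("batch", "sec"))
    msg <- c(msg, "mode must be 'batch' or 'sec'")
  if (length(msg)) msg else TRUE
})

#' Background-subtracted frame series
#'
#' A [FrameSeries-class] whose frames have had the averaged buffer curve
#' subtracted, carrying the provenance of the buffer window used.
#'
#' @slot bufferWindow integer indices (into the original series) of the
#'   frames averaged as buffer.
#' @slot bufferAverage the averaged buffer [ScatteringCurve-class].
#'
#' @seealso [subtractSeries()], [identifyBufferFrames()]
#' @exportClass SubtractedSeries
setClass("SubtractedSeries", contains = "FrameSeries",
  representation(bufferWindow = "integer", bufferAverage = "ScatteringCurve"))

#' Synchronized triple-detector chromatogram
#'
#' RALS, RI and UV traces on a common elution grid. The elution axis is the
#' volume pumped through the detector stream (ml); the acquisition time axis
#' (s) is kept alongside for fusion with the SAXS frame timeline. Absent
#' detector signals are stored as zero-length vectors, never as zeros.
#'
#' @slot volume strictly increasing elution volume, ml (detector stream).
#' @slot time acquisition time, s (same length as \code{volume}).
#' @slot rals,ri,uv detector traces (arbitrary detector units / AU);
#'   each either \code{length(volume)} long or length 0 if absent.
#'
#' @seealso [chromatogram()], [readChromatogram()]
#' @exportClass Chromatogram
setClass("Chromatogram",
  representation(volume = "numeric", time = "numeric",
    rals = "numeric", ri = "numeric", uv = "numeric"))

setValidity("Chromatogram", function(object) {
  msg <- character()
  n <- length(object@volume)
  if (n < 2) msg <- c(msg, "elution axis needs >= 2 points")
  else if (any(diff(object@volume) <= 0))
    msg <- c(msg, "elution volume must be strictly increasing")
  if (length(object@time) != n)
    msg <- c(msg, "time axis must match the volume axis length")
  for (s in c("rals", "ri", "uv")) {
    len <- length(slot(object, s))
    if (!len %in% c(0L, n))
      msg <- c(msg, sprintf("%s must be absent (length 0) or length %d", s, n))
  }
  if (length(msg)) msg else TRUE
})

#' Triple-detector and column calibration
#'
#' Instrument constants tying detector signals to physical quantities:
#' \eqn{RALS = c \cdot (dn/dc)^2 \cdot MW \cdot k_{RALS}} and
#' \eqn{RI = c \cdot (dn/dc) \cdot k_{RI}}, the conventional column
#' calibration line \eqn{\log_{10} MW = a - b V_e}, the standard-protein
#' reference (for detector and forward-scattering calibration) and a
#' registry of \eqn{\epsilon_{1\%}} extinction coefficients.
#'
#' @slot kRals,kRi instrument calibration constants, detector units per
#'   physical combination; > 0.
#' @slot dnDc refractive index increment, mL/g (0.185 for unmodified
#'   protein).
#' @slot columnA,columnB column calibration intercept and slope magnitude
#'   (log10 kDa, log10 kDa per ml); \code{NA} until fitted.
#' @slot columnRange elution-volume range (ml) spanned by the column
#'   standards; \code{NA} until fitted.
#' @slot standardName,standardMw standard protein label and mass, kDa.
#' @slot standardI0PerC concentration-normalized forward scattering of the
#'   standard, intensity per (mg/ml); \code{NA} until measured.
#' @slot epsilonRegistry named numeric, protein -> epsilon 1\% (absorbance
#'   of a 10 mg/ml solution, 1 cm path).
#'
#' @seealso [tdaCalibration()], [calibrateFromStandard()],
#'   [fitColumnCalibration()]
#' @exportClass TDACalibration
setClass("TDACalibration",
  representation(kRals = "numeric", kRi = "numeric", dnDc = "numeric",
    columnA = "numeric", columnB = "numeric", columnRange = "numeric",
    standardName = "character", standardMw = "numeric",
    standardI0PerC = "numeric", epsilonRegistry = "numeric"))

setValidity("TDACalibration", function(object) {
  msg <- character()
  if (length(object@kRals) != 1 || !is.finite(object@kRals) || object@kRals <= 0)
    msg <- c(msg, "kRals must be a single positive number")
  if (length(object@kRi) != 1 || !is.finite(object@kRi) || object@kRi <= 0)
    msg <- c(msg, "kRi must be a single positive number")
  if (length(object@dnDc) != 1 || !is.finite(object@dnDc) || object@dnDc <= 0)
    msg <- c(msg, "dnDc must be a single positive number")
  if (is.finite(object@columnB) && object@columnB <= 0)
    msg <- c(msg, "columnB must be > 0 when set")
  if (length(msg)) msg else TRUE
})

#' Guinier fit result
#'
#' Radius of gyration and forward scattering from a weighted linear fit of
#' \eqn{\ln I} versus \eqn{q^2} (Guinier law
#' \eqn{I(q) = I(0) \exp(-q^2 R_g^2 / 3)}).
#'
#' @slot rg radius of gyration, nm.
#' @slot i0 forward scattering intensity, curve units.
#' @slot rgSd,i0Sd 1-sigma uncertainties from the fit covariance.
#' @slot window first and last point index of the fitted window.
#' @slot qminRg,qmaxRg dimensionless window bounds \eqn{q R_g}.
#' @slot quality score in [0, 1] (only meaningful for [autoRg()] results).
#'
#' @seealso [guinierFit()], [autoRg()]
#' @exportClass GuinierFit
setClass("GuinierFit",
  representation(rg = "numeric", i0 = "numeric", rgSd = "numeric",
    i0Sd = "numeric", window = "integer", qminRg = "numeric",
    qmaxRg = "numeric", quality = "numeric"))

setValidity("GuinierFit", function(object) {
  msg <- character()
  if (!is.finite(object@rg) || object@rg <= 0)
    msg <- c(msg, "rg must be positive")
  if (length(object@window) != 2 || diff(object@window) < 1)
    msg <- c(msg, "window must be two increasing indices")
  if (length(msg)) msg else TRUE
})

#' Constrained mixture decomposition result
#'
#' Volume (weight) fractions from fitting a mixture scattering curve as a
#' scaled convex combination of component form factors.
#'
#' @slot fractions named non-negative weights summing to 1.
#' @slot scale overall scale factor k (>= 0).
#' @slot chi2 reduced goodness of fit.
#' @slot window frame-index range the fitted curve was averaged over
#'   (\code{NA} for a single curve).
#'
#' @seealso [fitVolumeFractions()], [rollingFractionTrace()]
#' @exportClass MixtureFit
setClass("MixtureFit",
  representation(fractions = "numeric", scale = "numeric",
    chi2 = "numeric", window = "integer"))

setValidity("MixtureFit", function(object) {
  msg <- character()
  if (any(object@fractions < -1e-12))
    msg <- c(msg, "fractions must be >= 0")
  if (abs(sum(object@fractions) - 1) > 1e-9)
    msg <- c(msg, "fractions must sum to 1")
  if (is.finite(object@chi2) && object@chi2 < 0)
    msg <- c(msg, "chi2 must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-component analysis report
#'
#' Everything the pipeline derives for one separated sample component: the
#' frame range used, mean concentration, the three molecular-weight routes
#' (RALS/RI, I(0) calibration, column calibration), the averaged
#' concentration-normalized scattering curve and the consistency verdicts.
#'
#' @slot id component label (peak number).
#' @slot frames frame indices averaged into the final curve.
#' @slot meanConc mean solute concentration over those frames, mg/ml.
#' @slot mwRals,mwRalsSd light-scattering molecular weight, kDa.
#' @slot mwI0,mwI0Sd forward-scattering molecular weight, kDa.
#' @slot mwSec column-calibration molecular weight, kDa.
#' @slot rg,rgSd mean radius of gyration over selected frames, nm.
#' @slot curve final averaged curve in intensity-per-(mg/ml) units.
#' @slot consistency verdict list from [consistencyReport()].
#'
#' @seealso [runSecPipeline()]
#' @exportClass ComponentReport
setClass("ComponentReport",
  representation(id = "character", frames = "integer", meanConc = "numeric",
    mwRals = "numeric", mwRalsSd = "numeric", mwI0 = "numeric",
    mwI0Sd = "numeric", mwSec = "numeric", rg = "numeric", rgSd = "numeric",
    curve = "ScatteringCurve", consistency = "list"))
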
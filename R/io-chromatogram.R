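#' Construct a Chromatogram
#'
#' @param volume elution volume, ml, strictly increasing (detector-stream
#'   axis). If only \code{time} is known, convert with
#'   \code{volume = time * flowRate * splitFraction / 60}.
#' @param time acquisition time, s; defaults to the volume axis values
#'   when omitted.
#' @param rals,ri,uv detector traces; \code{NULL} marks a detector absent.
#' @return A [Chromatogram-class].
#' @export
chromatogram <- function(volume, time = NULL, rals = NULL, ri = NULL,
    uv = NULL) {
  if (is.null(time)) time <- as.numeric(volume)
  sig <- function(x) if (is.null(x)) numeric(0) else as.numeric(x)
  new("Chromatogram", volume = as.numeric(volume), time = as.numeric(time),
    rals = sig(rals), ri = sig(ri), uv = sig(uv))
}

#' Does the chromatogram carry a given detector signal?
#' @param chrom a [Chromatogram-class].
#' @param signal one of "rals", "ri", "uv".
#' @export
hasSignal <- function(chrom, signal = c("rals", "ri", "uv")) {
  signal <- match.arg(signal)
  length(slot(chrom, signal)) > 0
}

#' Extract a detector trace
#' @inheritParams hasSignal
#' @return numeric trace; error if the detector is absent.
#' @export
signalTrace <- function(chrom, signal = c("rals", "ri", "uv")) {
  signal <- match.arg(signal)
  stopIfNot(hasSignal(chrom, signal),
    sprintf("detector '%s' absent from chromatogram", signal))
  slot(chrom, signal)
}

#' Elution-volume axis accessor
#' @param chrom a [Chromatogram-class].
#' @export
elutionVolume <- function(chrom) chrom@volume

#' Elution-time axis accessor
#' @param chrom a [Chromatogram-class].
#' @export
elutionTime <- function(chrom) chrom@time

setMethod("show", "Chromatogram", function(object) {
  sigs <- c("rals", "ri", "uv")
  present <- sigs[vapply(sigs, function(s) hasSignal(object, s), logical(1))]
  cat(sprintf("Chromatogram: %d points, V %.4g..%.4g ml, signals: %s\n",
    length(object@volume), min(object@volume), max(object@volume),
    if (length(present)) paste(present, collapse = ", ") else "none"))
})

#' Read a triple-detector chromatogram from CSV
#'
#' Expects a header row; column names are matched case-insensitively
#' against \code{time_s}, \code{volume_ml}, \code{rals}, \code{ri},
#' \code{uv} (an elution axis plus at least one detector signal is
#' required). Missing detector columns are flagged absent, never filled
#' with zeros. A time-only axis is converted to detector-stream volume via
#' \code{flowRate * splitFraction}.
#'
#' @param path CSV file path.
#' @param flowRate column flow rate, ml/min (used only to convert a
#'   time-only axis).
#' @param splitFraction fraction of the post-column flow through the
#'   detector stream.
#' @return A [Chromatogram-class].
#' @export
readChromatogram <- function(path, flowRate = 0.4, splitFraction = 0.5) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- tolower(trimws(names(df)))
  pick <- function(nm) if (nm %in% names(df)) as.numeric(df[[nm]]) else NULL
  tm <- pick("time_s"); vol <- pick("volume_ml")
  stopIfNot(!is.null(tm) || !is.null(vol),
    sprintf("%s: no elution axis (time_s or volume_ml) found", path))
  rals <- pick("rals"); ri <- pick("ri"); uv <- pick("uv")
  stopIfNot(!is.null(rals) || !is.null(ri) || !is.null(uv),
    sprintf("%s: no recognizable signal column (rals/ri/uv)", path))
  if (is.null(vol)) {
    stopIfNot(splitFraction > 0 && splitFraction <= 1,
      "splitFraction must be in (0, 1]")
    vol <- tm * flowRate * splitFraction / 60
  }
  if (is.null(tm)) tm <- vol * 60 / (flowRate * splitFraction)
  if (any(diff(vol) <= 0))
    stop(sprintf("%s: elution axis not strictly increasing", path),
      call. = FALSE)
  chromatogram(vol, time = tm, rals = rals, ri = ri, uv = uv)
}

#' Write a chromatogram to CSV
#'
#' Inverse of [readChromatogram()]: writes \code{time_s}, \code{volume_ml}
#' and the present detector columns.
#'
#' @param chrom a [Chromatogram-class].
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeChromatogram <- function(chrom, path) {
  df <- data.frame(time_s = chrom@time, volume_ml = chrom@volume)
  for (s in c("rals", "ri", "uv"))
    if (hasSignal(chrom, s)) df[[s]] <- slot(chrom, s)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
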
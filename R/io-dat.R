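#' Read a 3-column scattering .dat file
#'
#' Parses the de-facto standard ASCII format for reduced small-angle
#' scattering curves: '#'-prefixed comment/header lines followed by
#' whitespace-separated numeric rows \code{q I sigma}. Two-column files are
#' accepted with \code{sigma = 0} and a warning (downstream weighted fits
#' then fall back to unweighted). Scientific notation and plain decimals
#' are both accepted; parsing is locale-independent.
#'
#' @param path file path.
#' @param qUnit \code{"nm"} (default, q in nm^-1) or \code{"angstrom"}
#'   (q in A^-1, converted to nm^-1 by x10). A single internal q unit
#'   avoids silent factor-of-10 errors.
#' @return A [ScatteringCurve-class].
#' @seealso [writeDat()]
#' @export
readDat <- function(path, qUnit = c("nm", "angstrom")) {
  qUnit <- match.arg(qUnit)
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  stopIfNot(length(lines) >= 2, sprintf("%s: fewer than 2 data rows", path))
  rows <- strsplit(trimws(lines), "\\s+")
  ncols <- lengths(rows)
  bad <- which(ncols < 2)
  if (length(bad))
    stop(sprintf("%s: malformed row at line %d (need >= 2 columns)",
      path, lineNo[bad[1]]), call. = FALSE)
  parse1 <- function(k) {
    v <- suppressWarnings(as.numeric(vapply(rows, `[`, "", k)))
    v
  }
  q <- parse1(1); I <- parse1(2)
  nonnum <- which(!is.finite(q) | !is.finite(I))
  if (length(nonnum))
    stop(sprintf("%s: non-numeric value at line %d", path, lineNo[nonnum[1]]),
      call. = FALSE)
  if (all(ncols >= 3)) {
    sigma <- parse1(3)
    nonnum <- which(!is.finite(sigma))
    if (length(nonnum))
      stop(sprintf("%s: non-numeric sigma at line %d", path, lineNo[nonnum[1]]),
        call. = FALSE)
  } else {
    warning(sprintf("%s: 2-column file, assuming sigma = 0", path))
    sigma <- rep(0, length(q))
  }
  if (qUnit == "angstrom") q <- q * 10
  if (any(diff(q) <= 0))
    stop(sprintf("%s: q not strictly increasing", path), call. = FALSE)
  scatteringCurve(q, I, sigma)
}

#' Write a scattering curve as a 3-column .dat file
#'
#' @param curve a [ScatteringCurve-class].
#' @param path output file path.
#' @param header character vector of header lines (written '#'-prefixed);
#'   a single provenance line is written when empty.
#' @return \code{path}, invisibly.
#' @seealso [readDat()]
#' @export
writeDat <- function(curve, path, header = character()) {
  stopIfNot(is(curve, "ScatteringCurve"), "curve must be a ScatteringCurve")
  validObject(curve)
  if (!length(header)) header <- "secsaxstda scattering curve"
  body <- sprintf("%.15e %.15e %.15e", curve@q, curve@I, curve@sigma)
  ok <- tryCatch({
    writeLines(c(paste0("# ", header), body), path)
    TRUE
  }, error = function(e) FALSE)
  stopIfNot(ok, sprintf("cannot write %s", path))
  invisible(path)
}
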
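#' Read a run manifest
#'
#' A run manifest is a YAML key/value file describing one acquisition:
#' \preformatted{
#' mode: sec                 # or batch
#' frame_interval: 1.0       # s
#' exposure: 1.0             # s
#' flow_rate: 0.4            # column flow, ml/min
#' split_fraction: 0.5       # fraction of flow to the TDA branch
#' q_unit: nm                # or angstrom
#' frames:                   # .dat paths ordered by frame index
#'   - frames/frame_0001.dat
#'   - frames/frame_0002.dat
#' }
#' Relative frame paths are resolved against the manifest directory.
#'
#' @param path manifest file path.
#' @return A named list with the fields above (defaults filled in).
#' @seealso [readFrameSeries()]
#' @export
readManifest <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  m <- yaml::read_yaml(path)
  m$mode <- match.arg(m$mode %||% "sec", c("sec", "batch"))
  m$frame_interval <- as.numeric(m$frame_interval %||% 1)
  m$exposure <- as.numeric(m$exposure %||% m$frame_interval)
  m$flow_rate <- as.numeric(m$flow_rate %||% 0.4)
  m$split_fraction <- as.numeric(m$split_fraction %||% 0.5)
  m$q_unit <- match.arg(m$q_unit %||% "nm", c("nm", "angstrom"))
  stopIfNot(m$flow_rate > 0, "flow_rate must be > 0")
  stopIfNot(m$split_fraction > 0 && m$split_fraction <= 1,
    "split_fraction must be in (0, 1]")
  m$frames <- as.character(unlist(m$frames))
  dir <- dirname(path)
  rel <- !grepl("^(/|[A-Za-z]:)", m$frames)
  m$frames[rel] <- file.path(dir, m$frames[rel])
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a frame series from a manifest
#'
#' Loads every frame .dat file named in the manifest, asserts a common q
#' grid (1e-9 relative) and assembles a [FrameSeries-class] with frame
#' times spaced by the manifest's frame interval.
#'
#' @param manifest a manifest path or the list returned by
#'   [readManifest()].
#' @param transmission per-frame transmission factor(s), default 1.
#' @return A [FrameSeries-class].
#' @export
readFrameSeries <- function(manifest, transmission = 1) {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  paths <- manifest$frames
  stopIfNot(length(paths) > 0, "no frames listed in manifest")
  curves <- lapply(paths, readDat, qUnit = manifest$q_unit)
  q0 <- curves[[1]]@q
  for (i in seq_along(curves)) {
    qi <- curves[[i]]@q
    if (length(qi) != length(q0) ||
        any(abs(qi - q0) > 1e-9 * pmax(abs(q0), 1e-300)))
      stop(sprintf("q-grid mismatch in frame %d (%s)", i, paths[i]),
        call. = FALSE)
  }
  nf <- length(curves)
  I <- vapply(curves, intensities, numeric(length(q0)))
  S <- vapply(curves, sigmas, numeric(length(q0)))
  dim(I) <- dim(S) <- c(length(q0), nf)
  frameSeries(q0, I, S,
    time = (seq_len(nf) - 0.5) * manifest$frame_interval,
    exposure = manifest$exposure, transmission = transmission,
    mode = manifest$mode)
}

#' Write a simulated run to a directory
#'
#' Emits the on-disk convention [readFrameSeries()] consumes: a
#' \code{manifest.yaml}, one .dat file per frame, the chromatogram as
#' \code{chromatogram.csv} and the ground truth as JSON.
#'
#' @param run a list as returned by [simulateSecRun()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeRunDirectory <- function(run, dir) {
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  fs <- run$frames
  nf <- nFrames(fs)
  rel <- sprintf("frames/frame_%04d.dat", seq_len(nf))
  for (i in seq_len(nf))
    writeDat(frameCurve(fs, i), file.path(dir, rel[i]),
      header = sprintf("frame %d t=%.3f s", i, fs@time[i]))
  inst <- run$truth$instrument
  yaml::write_yaml(list(
    mode = fs@mode,
    frame_interval = if (nf > 1) diff(fs@time[1:2]) else fs@exposure[1],
    exposure = fs@exposure[1],
    flow_rate = inst$flowRate, split_fraction = inst$splitFraction,
    q_unit = "nm", frames = as.list(rel)),
    file.path(dir, "manifest.yaml"))
  if (!is.null(run$chromatogram))
    writeChromatogram(run$chromatogram, file.path(dir, "chromatogram.csv"))
  truth <- run$truth
  truth$concFrames <- NULL; truth$fracFrames <- NULL  # large matrices
  truth$instrument <- unclass(truth$instrument)
  truth$instrument$bufferProfile <- NULL
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
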
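#' Sphere form factor
#'
#' Normalized scattering form factor of a homogeneous sphere of radius R,
#' \deqn{P(q) = \left[\frac{3(\sin qR - qR\cos qR)}{(qR)^3}\right]^2,}
#' with \eqn{P(0) = 1}. The radius of gyration of a sphere is
#' \eqn{R_g = \sqrt{3/5}\,R}.
#'
#' @param q momentum transfer, nm^-1, all >= 0.
#' @param R sphere radius, nm, > 0.
#' @return Normalized intensities, same length as \code{q}.
#' @examples
#' sphereFormFactor(0, 4)            # 1 by normalization
#' @export
sphereFormFactor <- function(q, R) {
  stopIfNot(is.numeric(R) && length(R) == 1 && is.finite(R) && R > 0,
    "R must be a single positive radius")
  stopIfNot(all(q >= 0), "q must be >= 0")
  x <- q * R
  p <- ifelse(x < 1e-4,
    1 - x^2 / 10,             # series limit, avoids 0/0
    (3 * (sin(x) - x * cos(x)) / x^3))
  p^2
}

#' Specify a simulated species
#'
#' One macromolecular species for [simulateSecRun()] /
#' [simulateBatchRun()]: mass, size, elution position and injected amount.
#'
#' @param name label.
#' @param mw molecular weight, kDa.
#' @param rg radius of gyration, nm; derived from \code{R} when omitted.
#' @param R sphere radius, nm (\eqn{R_g = \sqrt{3/5} R}); derived from
#'   \code{rg} when omitted.
#' @param center Gaussian elution peak center, ml (detector-stream volume
#'   axis).
#' @param sigma elution peak standard deviation, ml.
#' @param mass injected mass, mg.
#' @param shape \code{"sphere"} (realistic globular form factor) or
#'   \code{"guinier"} (pure exponential \eqn{\exp(-q^2 R_g^2/3)}; exact
#'   Guinier behaviour at all q, used for identity checks).
#' @param epsilon extinction coefficient epsilon 1\% for the UV trace.
#' @return A \code{speciesSpec} list.
#' @export
speciesSpec <- function(name, mw, rg = NULL, R = NULL,
    center = 1.0, sigma = 0.08, mass = 0.5,
    shape = c("sphere", "guinier"), epsilon = 10) {
  shape <- match.arg(shape)
  if (is.null(rg) && is.null(R)) stop("give rg or R")
  if (is.null(rg)) rg <- sqrt(3 / 5) * R
  if (is.null(R)) R <- rg / sqrt(3 / 5)
  stopIfNot(mw > 0, "mw must be > 0")
  stopIfNot(rg > 0, "rg must be > 0")
  stopIfNot(sigma > 0, "elution sigma must be > 0")
  stopIfNot(mass >= 0, "injected mass must be >= 0")
  structure(list(name = name, mw = mw, rg = rg, R = R, center = center,
    sigma = sigma, mass = mass, shape = shape, epsilon = epsilon),
    class = "speciesSpec")
}

#' Specify the simulated instrument
#'
#' Parameters of the split-stream SEC-SAXS/TDA instrument model. Defaults
#' follow the beamline configuration: 0.4 ml/min column flow split equally
#' between the TDA and the SAXS capillary, 10-12 ul detector-chamber dead
#' volumes plus a 2.8 ul splitter, dn/dc = 0.185 mL/g for unmodified
#' protein, 1 s frames.
#'
#' @param flowRate column flow rate, ml/min.
#' @param splitFraction fraction of the post-column flow diverted to the
#'   TDA branch (the SAXS capillary receives the complement), in (0, 1).
#' @param deadVolumes named ul volumes \code{c(splitter, uv, rals, ri)}.
#'   Inter-detector dead volumes act as pure delays; one common Gaussian
#'   broadening with sigma_V equal to the summed TDA dead volume is applied
#'   to all TDA traces. Set to zeros for an ideal instrument.
#' @param kRi,kRals TDA calibration constants (detector units).
#' @param dnDc refractive index increment, mL/g.
#' @param frameExposure,frameInterval SAXS exposure and frame spacing, s.
#' @param transmission sample transmission factor in (0, 1].
#' @param countsScale expected photon counts per second at unit
#'   concentration-weighted intensity (c x MW x P = 1).
#' @param bufferLevel flat buffer scattering level, counts/s (overridden
#'   pointwise by \code{bufferProfile}).
#' @param bufferProfile optional [ScatteringCurve-class] buffer scattering
#'   rate on the simulation q grid, counts/s.
#' @param noiseFractionTda relative Gaussian noise on TDA traces (fraction
#'   of each trace maximum).
#' @param seed default RNG seed for runs simulated with this instrument.
#' @return An \code{instrumentSpec} list.
#' @export
instrumentSpec <- function(flowRate = 0.4, splitFraction = 0.5,
    deadVolumes = c(splitter = 2.8, uv = 10, rals = 11, ri = 12),
    kRi = 1000, kRals = 5, dnDc = 0.185,
    frameExposure = 1, frameInterval = 1, transmission = 1,
    countsScale = 100, bufferLevel = 2000, bufferProfile = NULL,
    noiseFractionTda = 0.01, seed = 1L) {
  stopIfNot(flowRate > 0, "flowRate must be > 0")
  stopIfNot(splitFraction > 0 && splitFraction < 1,
    "splitFraction must be in (0, 1)")
  stopIfNot(all(deadVolumes >= 0), "dead volumes must be >= 0")
  stopIfNot(dnDc > 0, "dnDc must be > 0")
  dv <- deadVolumes
  for (nm in c("splitter", "uv", "rals", "ri"))
    if (!nm %in% names(dv)) dv[nm] <- 0
  structure(list(flowRate = flowRate, splitFraction = splitFraction,
    deadVolumes = dv[c("splitter", "uv", "rals", "ri")],
    kRi = kRi, kRals = kRals, dnDc = dnDc,
    frameExposure = frameExposure, frameInterval = frameInterval,
    transmission = transmission, countsScale = countsScale,
    bufferLevel = bufferLevel, bufferProfile = bufferProfile,
    noiseFractionTda = noiseFractionTda, seed = as.integer(seed)),
    class = "instrumentSpec")
}

# Default q grid: 0.035..2 nm^-1, fine enough that globular proteins of
# 2.5-4.5 nm Rg keep >= 20 points below the 10%-of-maximum intensity drop.
defaultQGrid <- function() seq(0.035, 2.0, length.out = 120)

speciesFormFactor <- function(sp, q) {
  if (sp$shape == "guinier") exp(-q^2 * sp$rg^2 / 3)
  else sphereFormFactor(q, sp$R)
}

bufferRate <- function(inst, q) {
  if (!is.null(inst$bufferProfile)) {
    interpNA(inst$bufferProfile@q, inst$bufferProfile@I, q)
  } else {
    # mild low-q excess emulating residual capillary/window scattering
    inst$bufferLevel * (0.8 + 0.2 * exp(-q))
  }
}

#' Simulate a split-stream SEC-SAXS/TDA run
#'
#' Generates a frame series, a synchronized triple-detector chromatogram
#' and the generating ground truth. The model: each species elutes as a
#' Gaussian in detector-stream volume whose integrated concentration
#' equals injected mass x split fraction; noiseless detector responses are
#' \eqn{RI = (dn/dc)\, k_{RI} \sum_i c_i} and
#' \eqn{RALS = (dn/dc)^2 k_{RALS} \sum_i c_i MW_i}; the SAXS photon rate is
#' \eqn{countsScale \sum_i c_i MW_i P_i(q) + buffer(q)}, Poisson-sampled
#' over the exposure with \eqn{\sigma = \sqrt{counts}}; TDA traces are
#' delayed and broadened by the dead volumes and carry additive Gaussian
#' noise. Identical seeds give identical output.
#'
#' @param species list of [speciesSpec()] objects.
#' @param inst an [instrumentSpec()].
#' @param nFrames number of SAXS frames (>= 10).
#' @param q simulation q grid, nm^-1.
#' @param noise logical; \code{FALSE} produces the noiseless detector
#'   equations exactly (uncertainties still set to sqrt(expected counts)).
#' @param seed RNG seed; defaults to the instrument seed.
#' @param simulateFrames logical; \code{FALSE} skips SAXS frame generation
#'   (TDA-only studies), returning \code{NULL} frames.
#' @return A list with elements \code{frames} ([FrameSeries-class]),
#'   \code{chromatogram} ([Chromatogram-class]) and \code{truth} (a
#'   \code{GroundTruth} list: species table, per-frame true concentrations
#'   and weight fractions at the SAXS capillary, detector delays, the
#'   SAXS-to-RI lag in seconds, instrument echo).
#' @export
simulateSecRun <- function(species, inst = instrumentSpec(), nFrames = 480,
    q = defaultQGrid(), noise = TRUE, seed = inst$seed,
    simulateFrames = TRUE) {
  if (inherits(species, "speciesSpec")) species <- list(species)
  stopIfNot(nFrames >= 10, "nFrames must be >= 10")
  set.seed(seed)

  flowCol <- inst$flowRate / 60                      # ml/s
  flowTda <- flowCol * inst$splitFraction            # ml/s, TDA branch
  flowSax <- flowCol * (1 - inst$splitFraction)      # ml/s, capillary
  tFrame <- (seq_len(nFrames) - 0.5) * inst$frameInterval
  tEnd <- nFrames * inst$frameInterval

  dv <- inst$deadVolumes / 1000                      # ml
  delaySax <- dv[["splitter"]] / flowSax             # s
  # exported TDA traces are inter-detector aligned (as vendor software
  # aligns the serial chambers onto one retention axis), so all three
  # share the total dead-volume delay and a common Gaussian broadening
  delayTda <- stats::setNames(rep(sum(dv) / flowTda, length(dv)),
    names(dv))
  sigmaTdaMl <- sum(dv)                              # common broadening, ml
  sigmaTdaS <- sigmaTdaMl / flowTda

  spDf <- do.call(rbind, lapply(species, function(sp)
    data.frame(name = sp$name, mw = sp$mw, rg = sp$rg, R = sp$R,
      center = sp$center, sigma = sp$sigma, mass = sp$mass,
      shape = sp$shape, epsilon = sp$epsilon)))

  # concentration of species i at time t after traversing delay d (s) and
  # extra broadening sb (s); areas conserve injected mass x split fraction
  # on the TDA-stream volume axis
  concAt <- function(sp, t, d = 0, sb = 0) {
    tc <- sp$center / flowTda + d
    st <- sqrt((sp$sigma / flowTda)^2 + sb^2)
    sp$mass / flowCol * stats::dnorm(t, tc, st)
  }
  for (sp in species) {
    tc <- sp$center / flowTda
    if (sp$mass > 0 && (tc < 4 * sp$sigma / flowTda ||
        tc > tEnd - 2 * sp$sigma / flowTda))
      stop(sprintf("species '%s' elutes outside the simulated window",
        sp$name), call. = FALSE)
  }

  # --- TDA chromatogram on the frame time grid ---
  tChrom <- tFrame
  mkTrace <- function(detector, weight) {
    tr <- rep(0, length(tChrom))
    for (sp in species)
      tr <- tr + weight(sp) * concAt(sp, tChrom, delayTda[[detector]],
        sigmaTdaS)
    tr
  }
  ri <- inst$dnDc * inst$kRi * mkTrace("ri", function(sp) 1)
  rals <- inst$dnDc^2 * inst$kRals * mkTrace("rals", function(sp) sp$mw)
  uv <- mkTrace("uv", function(sp) sp$epsilon / 10)  # 1 cm path, AU
  if (noise && inst$noiseFractionTda > 0) {
    addNoise <- function(x) x + stats::rnorm(length(x),
      sd = inst$noiseFractionTda * max(x, 1e-12))
    ri <- addNoise(ri); rals <- addNoise(rals); uv <- addNoise(uv)
  }
  chrom <- chromatogram(volume = tChrom * flowTda, time = tChrom,
    rals = rals, ri = ri, uv = uv)

  # --- ground-truth concentrations at the SAXS capillary ---
  concFrames <- vapply(species, function(sp)
    concAt(sp, tFrame, delaySax), numeric(nFrames))
  dim(concFrames) <- c(nFrames, length(species))
  colnames(concFrames) <- spDf$name
  totc <- rowSums(concFrames)
  fracFrames <- concFrames / ifelse(totc > 0, totc, NA_real_)

  # --- SAXS frames ---
  frames <- NULL
  if (simulateFrames) {
    buf <- bufferRate(inst, q)
    P <- vapply(species, speciesFormFactor, numeric(length(q)), q = q)
    dim(P) <- c(length(q), length(species))
    # rate matrix (q x frames), counts/s
    rate <- P %*% t(concFrames * rep(spDf$mw, each = nFrames)) *
      inst$countsScale + buf
    expCounts <- rate * inst$frameExposure * inst$transmission
    if (noise) {
      counts <- matrix(stats::rpois(length(expCounts), lambda = expCounts),
        nrow = nrow(expCounts))
      sig <- sqrt(pmax(counts, 1))
    } else {
      counts <- expCounts
      sig <- sqrt(pmax(expCounts, 1e-12))
    }
    frames <- frameSeries(q, counts, sig, time = tFrame,
      exposure = inst$frameExposure, transmission = inst$transmission,
      mode = "sec")
  }

  truth <- list(species = spDf, concFrames = concFrames,
    fracFrames = fracFrames, frameTimes = tFrame,
    lagSeconds = unname(delayTda[["ri"]] - delaySax),
    tdaDelaySeconds = as.list(delayTda), saxDelaySeconds = unname(delaySax),
    tdaSigmaMl = sigmaTdaMl, flowTda = flowTda, flowSax = flowSax,
    countsScale = inst$countsScale, seed = seed,
    instrument = inst)
  list(frames = frames, chromatogram = chrom, truth = truth)
}

#' True species concentrations seen by the TDA
#'
#' Evaluates the noiseless, dead-volume-delayed and broadened per-species
#' concentration profiles at given chromatogram volumes, as seen by one
#' TDA detector. Used as a test oracle for chromatogram-side quantities.
#'
#' @param truth the \code{truth} element of [simulateSecRun()] output.
#' @param volume elution volumes, ml (detector-stream axis).
#' @param detector which detector's delay to apply.
#' @return Matrix, one column per species, mg/ml.
#' @export
trueTdaConcentrations <- function(truth, volume,
    detector = c("ri", "rals", "uv")) {
  detector <- match.arg(detector)
  inst <- truth$instrument
  flowTda <- truth$flowTda
  t <- volume / flowTda
  d <- truth$tdaDelaySeconds[[detector]]
  sb <- truth$tdaSigmaMl / flowTda
  flowCol <- inst$flowRate / 60
  out <- vapply(seq_len(nrow(truth$species)), function(i) {
    sp <- truth$species[i, ]
    tc <- sp$center / flowTda + d
    st <- sqrt((sp$sigma / flowTda)^2 + sb^2)
    sp$mass / flowCol * stats::dnorm(t, tc, st)
  }, numeric(length(t)))
  dim(out) <- c(length(t), nrow(truth$species))
  colnames(out) <- truth$species$name
  out
}

#' Simulate a batch-mode run
#'
#' Stationary sample in the capillary, a series of short successive
#' exposures (the standard batch protocol: twenty 50 ms exposures).
#' Optional linear inflation of every species' size across frames emulates
#' progressive radiation damage.
#'
#' @param species list of [speciesSpec()] objects (elution fields unused).
#' @param concentrations per-species concentrations, mg/ml (recycled).
#' @param inst an [instrumentSpec()].
#' @param nFrames number of exposures (>= 2).
#' @param exposure exposure per frame, s.
#' @param damageRate relative Rg growth per frame (0 = no damage); frame f
#'   scatters with \eqn{R_g (1 + damageRate (f - 1))}.
#' @param q simulation q grid.
#' @param noise Poisson counting noise on/off.
#' @param seed RNG seed.
#' @return A [FrameSeries-class] in batch mode.
#' @export
simulateBatchRun <- function(species, concentrations, inst = instrumentSpec(),
    nFrames = 20, exposure = 0.05, damageRate = 0, q = defaultQGrid(),
    noise = TRUE, seed = inst$seed) {
  if (inherits(species, "speciesSpec")) species <- list(species)
  stopIfNot(nFrames >= 2, "nFrames must be >= 2 in batch mode")
  concentrations <- rep_len(concentrations, length(species))
  stopIfNot(all(concentrations >= 0), "concentrations must be >= 0")
  stopIfNot(damageRate > -1 / max(1, nFrames - 1),
    "damageRate would drive Rg non-positive before the last frame")
  set.seed(seed)
  buf <- bufferRate(inst, q)
  expCounts <- matrix(0, length(q), nFrames)
  for (f in seq_len(nFrames)) {
    g <- 1 + damageRate * (f - 1)
    rate <- buf
    for (i in seq_along(species)) {
      sp <- species[[i]]
      spf <- sp; spf$rg <- sp$rg * g; spf$R <- sp$R * g
      rate <- rate + inst$countsScale * concentrations[i] * sp$mw *
        speciesFormFactor(spf, q)
    }
    expCounts[, f] <- rate * exposure * inst$transmission
  }
  if (noise) {
    counts <- matrix(stats::rpois(length(expCounts), expCounts),
      nrow = length(q))
    sig <- sqrt(pmax(counts, 1))
  } else {
    counts <- expCounts
    sig <- sqrt(pmax(expCounts, 1e-12))
  }
  frameSeries(q, counts, sig,
    time = (seq_len(nFrames) - 0.5) * exposure,
    exposure = exposure, transmission = inst$transmission, mode = "batch")
}
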
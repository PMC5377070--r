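mkGaussTrace <- function(center, times = seq(0.5, 480, by = 1)) {
  data.frame(time = times, i0 = 1000 * exp(-(times - center)^2 / (2 * 20^2)))
}

test_that("timeline alignment recovers pure delays", {
  tr <- mkGaussTrace(200)
  mk <- function(delay) chromatogram(volume = tr$time * 0.4 * 0.5 / 60,
    time = tr$time, ri = 50 * exp(-(tr$time - 200 - delay)^2 / (2 * 20^2)))
  lag30 <- alignTimelines(tr, mk(30))
  expect_equal(as.numeric(lag30), 30, tolerance = 1)
  lag0 <- alignTimelines(tr, mk(0))
  expect_equal(as.numeric(lag0), 0, tolerance = 1)
  expect_gte(attr(lag30, "correlation"), 0.99)
  # uncorrelated traces are rejected
  set.seed(61)
  bad <- chromatogram(volume = tr$time / 60, time = tr$time,
    ri = rnorm(nrow(tr)))
  expect_error(alignTimelines(tr, bad), "unreliable")
})

test_that("alignment recovers the dead-volume lag of a simulated run", {
  run <- simulateSecRun(bsaSpec(), instrumentSpec(seed = 62),
    nFrames = 480, seed = 621)
  norm <- normalizeFrames(run$frames)
  sub <- subtractSeries(norm, identifyBufferFrames(norm, run$chromatogram,
    minWindow = 50))
  tr <- rgTrace(sub)
  lag <- alignTimelines(tr, run$chromatogram)
  expect_equal(as.numeric(lag), run$truth$lagSeconds, tolerance = 1)
})

test_that("per-frame concentration interpolates and masks correctly", {
  # constant 2 mg/ml plateau across the covered window
  times <- seq(0.5, 100, by = 1)
  cal <- tdaCalibration(kRals = 1, kRi = 1, dnDc = 0.5)
  ch <- chromatogram(volume = times / 60, time = times,
    ri = rep(1, length(times)))
  conc <- perFrameConcentration(ch, cal, c(10, 50, 90), lag = 0, maskK = 0,
    correctBaseline = FALSE)
  expect_equal(conc, rep(2, 3))
  # frames beyond the chromatogram end are masked, not extrapolated
  concOut <- perFrameConcentration(ch, cal, c(50, 150), lag = 0, maskK = 0,
    correctBaseline = FALSE)
  expect_true(is.na(concOut[2]))
  expect_equal(concOut[1], 2)
})

test_that("per-frame concentration matches simulation truth at the apex", {
  # ideal instrument: no band broadening between column and detectors
  run <- simulateSecRun(bsaSpec(), idealInstrument(seed = 63),
    nFrames = 480, seed = 631)
  cal <- tdaCalibration(kRals = 5, kRi = 1000)
  conc <- perFrameConcentration(run$chromatogram, cal,
    run$truth$frameTimes, lag = 0)
  apx <- which.max(run$truth$concFrames[, 1])
  expect_equal(conc[apx], unname(run$truth$concFrames[apx, 1]),
    tolerance = 0.02)
  # recovered per-frame concentration tracks truth tightly overall
  ok <- !is.na(conc) & run$truth$concFrames[, 1] > 0.05 * max(run$truth$concFrames)
  expect_gt(cor(conc[ok], run$truth$concFrames[ok, 1]), 0.99)
})

test_that("concentration normalization is exact and linear", {
  fs <- flatSeries(nf = 6, nq = 20, level = 900, mode = "sec", seed = 64)
  sub <- subtractSeries(fs, 1:2)
  idn <- normalizeByConcentration(sub, rep(1, 6), minConc = 0.1)
  expect_equal(intensities(idn), intensities(sub))
  cvec <- c(NA, NA, 2, 2, 4, NA)
  nrm <- normalizeByConcentration(sub, cvec, minConc = 0.1)
  expect_equal(nFrames(nrm), 3)
  expect_equal(attr(nrm, "kept"), 3:5)
  expect_equal(intensities(nrm)[, 1], intensities(sub)[, 3] / 2)
  expect_error(normalizeByConcentration(sub, rep(NA_real_, 6)),
    "masked")
  # noiseless run: normalized pure-species frames are identical pointwise
  run <- simulateSecRun(bsaSpec(), idealInstrument(), nFrames = 480,
    noise = FALSE)
  norm <- normalizeFrames(run$frames)
  s <- subtractSeries(norm, 1:50)
  ctru <- run$truth$concFrames[, 1]
  sel <- which(ctru > 0.2 * max(ctru))
  nrm2 <- normalizeByConcentration(s, ctru, minConc = 0.01)
  kept <- attr(nrm2, "kept")
  cols <- match(sel, kept)
  ref <- intensities(nrm2)[, cols[1]]
  for (cc in cols[-1])
    expect_equal(intensities(nrm2)[, cc], ref, tolerance = 1e-9)
})

test_that("forward-scattering MW is a pure ratio against the standard", {
  expect_equal(mwFromI0(5000, 66.5, 5000), 66.5)
  expect_equal(mwFromI0(3.33 * 5000, 66.5, 5000), 221.445)
  expect_error(mwFromI0(-1, 66.5, 5000), "> 0")
  expect_error(mwFromI0(1, 66.5, 0), "> 0")
})

test_that("consistent-frame selection tracks the median and drops outliers", {
  tr <- data.frame(frame = 1:10, time = 1:10,
    rg = rep(3, 10), rgSd = rep(0.01, 10), i0 = 100, i0Sd = 1,
    quality = 1, status = "ok")
  expect_equal(selectConsistentFrames(tr, 1:10), 1:10)
  tr$rg[5] <- 6
  expect_equal(selectConsistentFrames(tr, 1:10), setdiff(1:10, 5))
  tr$status[1:8] <- "failed"
  expect_error(selectConsistentFrames(tr, 1:10), "fewer than 3")
})

test_that("component curve building averages the selection", {
  fs <- flatSeries(nf = 5, nq = 15, level = 2500, mode = "sec", seed = 65)
  sub <- subtractSeries(fs, 1:1)
  one <- buildComponentCurve(sub, 3)
  expect_equal(intensities(one), intensities(sub)[, 3])
  avg <- buildComponentCurve(sub, 1:5)
  expect_equal(intensities(avg), rowMeans(intensities(sub)))
  expect_error(buildComponentCurve(sub, integer()), "empty")
})

test_that("MW consistency verdicts mirror the tetramer case", {
  # 230 / 225 kDa with a 55 kDa monomer ladder: consistent tetramer
  rep1 <- consistencyReport(230, 225, NA, monomerMw = 55)
  expect_equal(rep1$status, "consistent")
  expect_equal(rep1$oligomer$state, 4)
  expect_equal(rep1$oligomer$expectedMw, 220)
  # grossly discordant estimates are flagged
  rep2 <- consistencyReport(100, 210)
  expect_equal(rep2$status, "inconsistent")
  # a single estimate cannot be cross-checked
  rep3 <- consistencyReport(230)
  expect_equal(rep3$status, "insufficient estimates")
})
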
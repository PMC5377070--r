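test_that("baseline correction removes constants, lines and sim baselines", {
  expect_equal(max(abs(baselineCorrect(rep(7, 100)))), 0)
  ramp <- seq(2, 5, length.out = 100)
  expect_lt(max(abs(baselineCorrect(ramp))), 1e-9)
  expect_error(baselineCorrect(rep(1, 10)), "too short")
  # simulated RI trace: residual baseline well under 0.1% of peak height
  run <- simulateSecRun(bsaSpec(), instrumentSpec(seed = 51),
    nFrames = 480, simulateFrames = FALSE, seed = 511)
  ri <- signalTrace(run$chromatogram, "ri")
  corr <- baselineCorrect(ri, elutionVolume(run$chromatogram))
  base <- c(corr[1:40], corr[441:480])
  expect_lt(abs(mean(base)), 0.005 * max(corr))
})

test_that("peak detection: nothing on flat noise, exact Gaussians found", {
  set.seed(52)
  v <- seq(0, 2, length.out = 400)
  noise <- rnorm(400, sd = 1)
  expect_equal(nrow(detectPeaks(noise, v)), 0)
  # one Gaussian, SNR 100: apex within a grid step, area within 1%
  g <- 100 * dnorm(v, 1, 0.1) / dnorm(0, 0, 0.1) + rnorm(400, sd = 1)
  pk <- detectPeaks(g, v)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$apex - 1), diff(v[1:2]))
  # analytic Gaussian integral: height x sigma x sqrt(2 pi)
  expect_equal(pk$area, 100 * 0.1 * sqrt(2 * pi), tolerance = 0.01)
  # two separated Gaussians come back in elution order
  g2 <- 100 * exp(-(v - 0.6)^2 / (2 * 0.05^2)) +
    60 * exp(-(v - 1.4)^2 / (2 * 0.05^2)) + rnorm(400, sd = 1)
  pk2 <- detectPeaks(g2, v)
  expect_equal(nrow(pk2), 2)
  expect_lt(pk2$apex[1], pk2$apex[2])
  expect_equal(pk2$apex, c(0.6, 1.4), tolerance = 0.01)
})

test_that("peak areas are additive for merged Gaussians", {
  v <- seq(0, 2, length.out = 1000)
  a <- 80 * exp(-(v - 0.9)^2 / (2 * 0.06^2))
  b <- 50 * exp(-(v - 1.1)^2 / (2 * 0.06^2))
  set.seed(53)
  merged <- a + b + rnorm(1000, sd = 0.3)
  pks <- detectPeaks(merged, v)
  expect_equal(sum(pks$area),
    (80 + 50) * 0.06 * sqrt(2 * pi), tolerance = 0.02)
})

test_that("calibration from a noiseless standard recovers the constants", {
  inst <- idealInstrument()
  run <- simulateSecRun(bsaSpec(), inst, nFrames = 720, noise = FALSE,
    simulateFrames = FALSE)
  cal <- calibrateFromStandard(run$chromatogram, standardMw = 66.5,
    injectedMass = 0.5, splitFraction = 0.5, dnDc = 0.185)
  expect_equal(cal@kRi, inst$kRi, tolerance = 0.005)
  expect_equal(cal@kRals, inst$kRals, tolerance = 0.005)
  expect_error(calibrateFromStandard(run$chromatogram,
    injectedMass = 0), "> 0")
})

test_that("halving the split fraction is compensated exactly", {
  run <- simulateSecRun(bsaSpec(), idealInstrument(), nFrames = 720,
    noise = FALSE, simulateFrames = FALSE)
  c1 <- calibrateFromStandard(run$chromatogram, 66.5, 0.5,
    splitFraction = 0.5)
  c2 <- calibrateFromStandard(run$chromatogram, 66.5, 0.5,
    splitFraction = 0.25)
  expect_equal(c2@kRi, 2 * c1@kRi, tolerance = 1e-12)
})

test_that("concentration follows the printed RI relation", {
  cal <- tdaCalibration(kRals = 1, kRi = 1, dnDc = 0.185)
  expect_equal(concentrationFromRi(0.185, cal, maskK = 0), 1.0)
  expect_equal(concentrationFromRi(0, cal, maskK = 0), 0)
  # simulated run: apex concentration against the detector-side truth
  run <- simulateSecRun(bsaSpec(), instrumentSpec(seed = 54),
    nFrames = 480, simulateFrames = FALSE, seed = 541)
  ch <- run$chromatogram
  calS <- tdaCalibration(kRals = 5, kRi = 1000)
  conc <- concentrationFromRi(baselineCorrect(signalTrace(ch, "ri"),
    elutionVolume(ch)), calS)
  ctru <- trueTdaConcentrations(run$truth, elutionVolume(ch), "ri")[, 1]
  apx <- which.max(ctru)
  expect_equal(conc[apx], ctru[apx], tolerance = 0.02)
})

test_that("UV absorbance converts through the epsilon-1% definition", {
  expect_equal(concentrationFromUv(6.14, 6.14, 1), 10)   # BSA
  expect_equal(concentrationFromUv(0.58, 5.8, 1), 1.0)   # HSA
  expect_equal(concentrationFromUv(0, 6.14), 0)
  expect_error(concentrationFromUv(1, -1), "> 0")
  expect_error(concentrationFromUv(1, 6.14, 0), "> 0")
})

test_that("the MW trace inverts the two detector equations", {
  cal <- tdaCalibration(kRals = 1, kRi = 1, dnDc = 0.185)
  n <- 60
  ri <- c(rep(0, 20), rep(1, 20), rep(0, 20)) + 1e-4 * sin(1:n)
  rals <- 42.55 * ri
  mw <- mwRalsTrace(rals, ri, cal)
  expect_equal(unique(round(mw[21:40], 6)), 230)
  expect_true(all(is.na(mw[1:19])))
  expect_error(mwRalsTrace(rep(0.001, 60) * runif(60), rep(0.001, 60),
    tdaCalibration(kRals = 1, kRi = 1)), "no quantifiable region")
})

test_that("MW trace is invariant to common rescaling and concentration", {
  run <- simulateSecRun(list(tetSpec(), dimerSpec()),
    instrumentSpec(seed = 55), nFrames = 480, simulateFrames = FALSE,
    seed = 551)
  ch <- run$chromatogram
  v <- elutionVolume(ch)
  ri <- baselineCorrect(signalTrace(ch, "ri"), v)
  rals <- baselineCorrect(signalTrace(ch, "rals"), v)
  cal <- tdaCalibration(kRals = 5, kRi = 1000)
  mw <- mwRalsTrace(rals, ri, cal)
  mwScaled <- mwRalsTrace(3 * rals, 3 * ri, cal)
  expect_equal(mw, mwScaled, tolerance = 1e-12)
  # plateau at the tetramer mass across the main peak, lower trailing
  # plateau at the dimer mass
  ctru <- trueTdaConcentrations(run$truth, v, "ri")
  fr <- ctru / rowSums(ctru)
  tetRegion <- which(fr[, 1] > 0.99 & ctru[, 1] > 0.5 * max(ctru[, 1]))
  expect_equal(median(mw[tetRegion], na.rm = TRUE), 220, tolerance = 0.05)
  dimRegion <- which(fr[, 2] > 0.8)
  expect_equal(median(mw[dimRegion], na.rm = TRUE), 110, tolerance = 0.1)
})

test_that("column calibration is the textbook log-linear line", {
  col <- fitColumnCalibration(data.frame(ve = c(10, 15), mw = c(100, 10)))
  expect_equal(col$a, 4, tolerance = 1e-12)
  expect_equal(col$b, 0.2, tolerance = 1e-12)
  cal <- setColumnCalibration(tdaCalibration(kRals = 1, kRi = 1), col)
  expect_equal(as.numeric(mwSec(12.5, cal)), 10^1.5, tolerance = 1e-12)
  expect_equal(suppressWarnings(as.numeric(mwSec(col$a / col$b, cal))), 1)
  # monotone decreasing in retention volume
  expect_true(all(diff(vapply(10:15, function(v)
    as.numeric(mwSec(v, cal)), numeric(1))) < 0))
  # round trip for points on the line
  expect_equal(as.numeric(mwSec((4 - log10(42)) / 0.2, cal)), 42,
    tolerance = 1e-9)
  # three collinear points fit exactly
  col3 <- fitColumnCalibration(data.frame(ve = c(8, 10, 12),
    mw = 10^(4 - 0.2 * c(8, 10, 12))))
  expect_equal(col3$b, 0.2, tolerance = 1e-12)
  expect_error(fitColumnCalibration(data.frame(ve = 1, mw = 10)), ">= 2")
  expect_error(fitColumnCalibration(data.frame(ve = c(1, 1),
    mw = c(10, 20))), "distinct")
  expect_warning(mwSec(30, cal), "outside")
})

test_that("dn/dc is recovered from a run of known mass", {
  run <- simulateSecRun(bsaSpec(), idealInstrument(), nFrames = 720,
    noise = FALSE, simulateFrames = FALSE)
  ch <- run$chromatogram
  ri <- baselineCorrect(signalTrace(ch, "ri"), elutionVolume(ch))
  pk <- detectPeaks(ri, elutionVolume(ch))
  cal <- tdaCalibration(kRals = 5, kRi = 1000)
  dndc <- dndcFromKnownConcentration(pk$area, 0.5 * 0.5, cal)
  expect_equal(as.numeric(dndc), 0.185, tolerance = 0.002 / 0.185)
  # doubling the mass halves the increment
  half <- dndcFromKnownConcentration(pk$area, 0.5, cal)
  expect_equal(as.numeric(half), as.numeric(dndc) / 2)
  # zero area is flagged implausible
  z <- dndcFromKnownConcentration(0, 0.25, cal)
  expect_true(isTRUE(attr(z, "implausible")))
  expect_error(dndcFromKnownConcentration(1, 0, cal), "> 0")
})
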
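mkComponents <- function(nq = 60) {
  q <- seq(0.04, 1.6, length.out = nq)
  list(
    tetramer = scatteringCurve(q, 220 * sphereFormFactor(q, 5.03)),
    dimer = scatteringCurve(q, 110 * sphereFormFactor(q, 4.0)))
}

test_that("exact mixtures decompose to exact fractions", {
  cmp <- mkComponents()
  q <- qValues(cmp$tetramer)
  mixI <- 0.3 * intensities(cmp$tetramer) + 0.7 * intensities(cmp$dimer)
  fit <- fitVolumeFractions(scatteringCurve(q, 5 * mixI), cmp)
  expect_equal(unname(volumeFractions(fit)), c(0.3, 0.7),
    tolerance = 1e-9)
  expect_equal(fit@scale, 5, tolerance = 1e-9)
  expect_lt(fit@chi2, 1e-15)
  pure <- fitVolumeFractions(cmp$tetramer, cmp)
  expect_equal(unname(volumeFractions(pure)), c(1, 0), tolerance = 1e-9)
})

test_that("fractions are a simplex point and collinearity is rejected", {
  cmp <- mkComponents()
  q <- qValues(cmp$tetramer)
  set.seed(71)
  for (k in 1:10) {
    fTrue <- runif(1)
    mixI <- fTrue * intensities(cmp$tetramer) +
      (1 - fTrue) * intensities(cmp$dimer)
    noisy <- scatteringCurve(q, mixI + rnorm(length(q), sd = 0.5),
      rep(0.5, length(q)))
    fit <- fitVolumeFractions(noisy, cmp)
    expect_true(all(volumeFractions(fit) >= 0))
    expect_equal(sum(volumeFractions(fit)), 1, tolerance = 1e-9)
  }
  dup <- list(a = cmp$tetramer,
    b = scatteringCurve(q, 2 * intensities(cmp$tetramer)))
  expect_error(fitVolumeFractions(cmp$dimer, dup), "collinear")
  expect_error(fitVolumeFractions(cmp$dimer, cmp["dimer"]), ">= 2")
})

test_that("NNLS solution matches the exhaustive lattice oracle", {
  cmp <- mkComponents()
  q <- qValues(cmp$tetramer)
  set.seed(72)
  for (fTrue in c(0.2, 0.5, 0.85)) {
    mixI <- fTrue * intensities(cmp$tetramer) +
      (1 - fTrue) * intensities(cmp$dimer)
    noisy <- scatteringCurve(q, mixI + rnorm(length(q), sd = 2),
      rep(2, length(q)))
    fit <- fitVolumeFractions(noisy, cmp)
    lattice <- oracleLatticeFractions(noisy, cmp, by = 0.01)
    expect_lt(abs(volumeFractions(fit)[[1]] - lattice[[1]]), 0.011)
  }
  # three components on a coarse simplex lattice
  cmp3 <- c(cmp, list(monomer = scatteringCurve(q,
    55 * sphereFormFactor(q, 3.2))))
  mixI <- 0.5 * intensities(cmp3[[1]]) + 0.2 * intensities(cmp3[[2]]) +
    0.3 * intensities(cmp3[[3]])
  noisy <- scatteringCurve(q, mixI + rnorm(length(q), sd = 1),
    rep(1, length(q)))
  fit3 <- fitVolumeFractions(noisy, cmp3)
  lattice3 <- oracleLatticeFractions(noisy, cmp3, by = 0.02)
  expect_true(all(abs(unname(volumeFractions(fit3)) -
    unname(lattice3)) < 0.021))
})

test_that("chi2 never worsens when the full generating set is offered", {
  cmp <- mkComponents()
  q <- qValues(cmp$tetramer)
  set.seed(73)
  mixI <- 0.6 * intensities(cmp$tetramer) + 0.4 * intensities(cmp$dimer)
  noisy <- scatteringCurve(q, mixI + rnorm(length(q), sd = 1),
    rep(1, length(q)))
  filler <- scatteringCurve(q, 40 * sphereFormFactor(q, 2.0))
  full <- fitVolumeFractions(noisy, cmp)
  subset <- fitVolumeFractions(noisy, list(tetramer = cmp$tetramer,
    filler = filler))
  expect_lte(full@chi2, subset@chi2 * (1 + 1e-9))
})

test_that("noisy 50:50 mixtures recover both fractions within 0.05", {
  cmp <- list(tetramer = pureComponentCurve(tetSpec()),
    dimer = pureComponentCurve(dimerSpec()))
  devs <- vapply(1:20, function(s) {
    set.seed(700 + s)
    q <- qValues(cmp$tetramer)
    # apex-like statistics: c*MW products at a 50:50 weight mixture
    mu <- 100 * 0.3 * (0.5 * 220 * sphereFormFactor(q, tetSpec()$R) +
      0.5 * 110 * sphereFormFactor(q, dimerSpec()$R)) + 2000
    cnt <- rpois(length(q), mu)
    net <- scatteringCurve(q, cnt - 2000, sqrt(cnt + 2000))
    fit <- fitVolumeFractions(net, cmp)
    abs(volumeFractions(fit)[["dimer"]] - 0.5)
  }, numeric(1))
  expect_lt(median(devs), 0.05)
})

test_that("rolling windows resolve the pure and transition regions", {
  run <- simulateSecRun(list(tetSpec(), dimerSpec()),
    instrumentSpec(seed = 74), nFrames = 480, seed = 741)
  norm <- normalizeFrames(run$frames)
  sub <- subtractSeries(norm, 1:50)
  cmp <- list(tetramer = pureComponentCurve(tetSpec()),
    dimer = pureComponentCurve(dimerSpec()))
  tr <- rollingFractionTrace(sub, cmp, window = 10)
  fr <- run$truth$fracFrames
  conc <- rowSums(run$truth$concFrames)
  winFrac <- vapply(seq_len(nrow(tr)), function(i) {
    idx <- tr$firstFrame[i]:tr$lastFrame[i]
    sum(fr[idx, 2] * conc[idx]) / sum(conc[idx])
  }, numeric(1))
  strong <- conc[round((tr$firstFrame + tr$lastFrame) / 2)] >
    0.02 * max(conc)
  pureTet <- strong & !is.na(winFrac) & winFrac < 0.01
  expect_true(all(tr$dimer[pureTet] < 0.05))
  # dimer fraction rises across the trailing region
  tail <- which(strong & !is.na(winFrac) & winFrac > 0.2)
  expect_gt(length(tail), 2)
  expect_gt(cor(tr$dimer[tail], winFrac[tail]), 0.9)
  expect_error(rollingFractionTrace(sub, cmp, window = 1000),
    "fewer frames")
})

test_that("the two fraction formulas behave as documented", {
  expect_equal(tdaDimerFraction(220, 220, 110), 0)
  expect_equal(tdaDimerFraction(110, 220, 110), 1)
  expect_equal(tdaDimerFraction(110, 220, 110, "paper_literal"), 1)
  # the printed ratio and the exact two-state inversion agree only
  # because the large species is twice the small one
  expect_equal(tdaDimerFraction(165, 220, 110), 0.5)
  expect_equal(tdaDimerFraction(165, 220, 110, "paper_literal"), 0.5)
  expect_equal(tdaDimerFraction(100, 300, 110, "paper_literal"),
    (300 - 100) / 110)
  # exact inversion of the weight-average identity
  f <- 0.37
  mwW <- f * 110 + (1 - f) * 220
  expect_equal(tdaDimerFraction(mwW, 220, 110), f, tolerance = 1e-12)
  expect_error(tdaDimerFraction(100, 110, 220), "mwBig > mwSmall")
})

test_that("identical traces cross-validate to zero and disjoint ones fail", {
  tr <- data.frame(firstFrame = 1, lastFrame = 10,
    centerTime = c(10, 20, 30), chi2 = 0, dimer = c(0.1, 0.5, 0.9))
  cv <- crossValidateFractions(tr, "dimer", c(0.1, 0.5, 0.9),
    c(10, 20, 30))
  expect_equal(cv$rms, 0)
  expect_equal(cv$max, 0)
  expect_error(crossValidateFractions(tr, "dimer", c(0.1, 0.5),
    c(500, 600)), "overlap")
})
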
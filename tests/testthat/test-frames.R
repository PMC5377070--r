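test_that("normalization divides intensities and uncertainties alike", {
  q <- seq(0.1, 1, length.out = 10)
  sc <- scatteringCurve(q, rep(10, 10), rep(2, 10))
  expect_equal(intensities(normalizeFrame(sc, 1, 1)), rep(10, 10))
  n <- normalizeFrame(sc, 0.05, 0.5)
  expect_equal(intensities(n), rep(10 * 40, 10))
  expect_equal(sigmas(n), rep(2 * 40, 10))
  expect_error(normalizeFrame(sc, 0.05, 0), "> 0")

  fs <- frameSeries(q, matrix(10, 10, 3), matrix(2, 10, 3),
    time = 1:3, exposure = 0.5, transmission = 0.8)
  nf <- normalizeFrames(fs)
  expect_equal(intensities(nf)[1, ], rep(25, 3))
  expect_equal(sigmas(nf)[1, ], rep(5, 3))
})

test_that("frame similarity scores identical, noisy and mismatched input", {
  a <- scatteringCurve(1:10 / 10, rnorm(10, 100, 1), rep(1, 10))
  expect_equal(frameSimilarity(a, a), 0)
  b <- scatteringCurve(1:9 / 10, rnorm(9, 100), rep(1, 9))
  expect_error(frameSimilarity(a, b), "different q grids")
  z <- scatteringCurve(1:10 / 10, rep(5, 10), rep(0, 10))
  expect_warning(s <- frameSimilarity(z, z), "relative RMS")
  expect_equal(s, 0)
})

test_that("similarity of independent Poisson frames concentrates near 1", {
  # 1000 trials of paired 120-point Poisson realizations of one
  # expectation: 99%+ of reduced scores must fall inside [0.5, 1.5]
  set.seed(77)
  q <- seq(0.05, 1.5, length.out = 120)
  lam <- 500 * exp(-q) + 100
  scores <- replicate(1000, {
    x <- rpois(120, lam); y <- rpois(120, lam)
    frameSimilarity(scatteringCurve(q, x, sqrt(pmax(x, 1))),
      scatteringCurve(q, y, sqrt(pmax(y, 1))))
  })
  expect_gte(mean(scores >= 0.5 & scores <= 1.5), 0.99)
  expect_equal(median(scores), 1, tolerance = 0.05)
})

test_that("averaging reduces uncertainty as sqrt(n) and is exact", {
  q <- 1:20 / 10
  cs <- list(scatteringCurve(q, rep(0, 20), rep(1, 20)),
    scatteringCurve(q, rep(2, 20), rep(1, 20)))
  avg <- averageFrames(cs)
  expect_equal(intensities(avg), rep(1, 20))
  expect_equal(sigmas(avg), rep(sqrt(2) / 2, 20))
  one <- averageFrames(cs[1])
  expect_equal(intensities(one), intensities(cs[[1]]))
  n <- 9
  avg9 <- averageFrames(rep(cs[2], n))
  expect_equal(sigmas(avg9), rep(1 / sqrt(n), 20))
  expect_error(averageFrames(list()), "empty")
})

test_that("background subtraction propagates and is anti-symmetric", {
  q <- 1:15 / 10
  a <- scatteringCurve(q, rnorm(15, 100), rep(2, 15))
  b <- scatteringCurve(q, rnorm(15, 90), rep(1, 15))
  d <- subtractBackground(a, b)
  expect_equal(intensities(d), intensities(a) - intensities(b))
  expect_equal(sigmas(d), rep(sqrt(5), 15))
  d2 <- subtractBackground(b, a)
  expect_equal(intensities(d2), -intensities(d))
  same <- subtractBackground(a, a)
  expect_equal(intensities(same), rep(0, 15))
  expect_equal(sigmas(same), sqrt(2) * sigmas(a))
  expect_error(subtractBackground(a,
    scatteringCurve(q + 0.01, rep(1, 15))), "different q grids")
})

test_that("subtraction and averaging commute on a common grid", {
  set.seed(5)
  fs <- flatSeries(nf = 8, nq = 25, level = 400)
  buf <- averageFrames(fs, 1:3)
  sub <- subtractSeries(fs, 1:3)
  lhs <- averageFrames(sub, 4:8)
  rhs <- subtractBackground(averageFrames(fs, 4:8), buf)
  expect_equal(intensities(lhs), intensities(rhs), tolerance = 1e-12)
})

test_that("subtracted apex frames match the generating model within noise", {
  inst <- instrumentSpec(seed = 8)
  run <- simulateSecRun(tetSpec(), inst, nFrames = 480, seed = 81)
  norm <- normalizeFrames(run$frames)
  buf <- averageFrames(norm, 1:60)
  apx <- which.max(run$truth$concFrames[, 1])
  net <- subtractBackground(frameCurve(norm, apx), buf)
  model <- inst$countsScale * run$truth$concFrames[apx, 1] * 220 *
    sphereFormFactor(qValues(net), tetSpec()$R)
  z <- (intensities(net) - model) / sigmas(net)
  expect_gte(mean(abs(z) < 3), 0.99)
})

test_that("buffer identification finds a pre-peak window free of solute", {
  run <- simulateSecRun(bsaSpec(), instrumentSpec(seed = 21),
    nFrames = 480, seed = 211)
  norm <- normalizeFrames(run$frames)
  bw <- identifyBufferFrames(norm, run$chromatogram, minWindow = 50)
  expect_length(bw, 50)
  expect_equal(bw, min(bw):max(bw))   # contiguous
  apexC <- max(run$truth$concFrames)
  expect_lt(max(run$truth$concFrames[bw, ]), 0.01 * apexC)
  # short series is a hard error
  expect_error(identifyBufferFrames(flatSeries(nf = 5), minWindow = 10),
    "frames")
})

test_that("an all-buffer run yields some valid buffer window", {
  sp <- bsaSpec(); sp$mass <- 0
  run <- simulateSecRun(list(sp), instrumentSpec(seed = 22), nFrames = 200,
    q = seq(0.05, 1.2, length.out = 40), seed = 221)
  bw <- identifyBufferFrames(normalizeFrames(run$frames),
    run$chromatogram, minWindow = 50)
  expect_length(bw, 50)
})

test_that("damage screening flags drifting series and passes clean ones", {
  inst <- instrumentSpec(seed = 31)
  clean <- normalizeFrames(simulateBatchRun(bsaSpec(), 4.5, inst,
    nFrames = 20, seed = 311))
  repC <- detectRadiationDamage(clean)
  expect_false(repC$damaged)
  # drift that doubles Rg by mid-run must be caught in the first half
  dmg <- normalizeFrames(simulateBatchRun(bsaSpec(), 4.5, inst,
    nFrames = 20, damageRate = 1 / 9, seed = 312))
  repD <- detectRadiationDamage(dmg)
  expect_true(repD$damaged)
  expect_lte(repD$firstIndex, 10)
  # two identical frames: no damage
  q <- 1:30 / 10
  two <- frameSeries(q, matrix(100, 30, 2), matrix(10, 30, 2), time = 1:2)
  expect_false(detectRadiationDamage(two)$damaged)
  expect_error(detectRadiationDamage(frameSeries(q,
    matrix(1, 30, 1), matrix(1, 30, 1), time = 1)), ">= 2")
})
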
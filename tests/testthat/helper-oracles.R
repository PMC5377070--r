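# Independent oracles and shared fixture builders. Oracles deliberately
# use a different computational route than the package implementation.

# Brute-force weighted least squares of y ~ a + b x via the normal
# equations assembled as explicit matrices (oracle for the prefix-sum
# implementation inside the Guinier module).
oracleLine <- function(x, y, w = rep(1, length(x))) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  beta <- solve(XtWX, t(X) %*% (w * y))
  list(intercept = beta[1], slope = beta[2])
}

# Exhaustive Guinier window search on a fine criterion: among all
# windows obeying the qRg bounds, the widest window whose per-point
# ln-residuals stay below `tol` (oracle for autoRg on smooth curves).
oracleGuinierSearch <- function(curve, minPoints = 5, qmaxRgMax = 1.3,
    tol = 2e-3) {
  q <- qValues(curve); I <- intensities(curve)
  n <- length(q)
  best <- NULL
  for (i in seq_len(n - minPoints + 1)) {
    for (j in (i + minPoints - 1):n) {
      qq <- q[i:j]; II <- I[i:j]
      if (any(II <= 0)) break
      f <- oracleLine(qq^2, log(II))
      if (f$slope >= 0) next
      rg <- sqrt(-3 * f$slope)
      if (qq[length(qq)] * rg > qmaxRgMax || qq[1] * rg > 1.0) next
      resid <- log(II) - f$intercept - f$slope * qq^2
      if (max(abs(resid)) > tol) next
      if (is.null(best) || (j - i) > (best$j - best$i))
        best <- list(i = i, j = j, rg = rg, i0 = exp(f$intercept))
    }
  }
  best
}

# Exhaustive lattice search over the fraction simplex (step `by`) with
# the optimal scale computed in closed form per lattice point (oracle
# for the NNLS volume-fraction fit; 2-3 components only).
oracleLatticeFractions <- function(mixture, components, by = 0.01) {
  w <- ifelse(sigmas(mixture) > 0, 1 / sigmas(mixture), 1)
  b <- intensities(mixture) * w
  A <- vapply(components, intensities,
    numeric(length(qValues(mixture)))) * w
  m <- length(components)
  grid <- if (m == 2) {
    f1 <- seq(0, 1, by = by)
    cbind(f1, 1 - f1)
  } else {
    f1 <- seq(0, 1, by = by)
    do.call(rbind, lapply(f1, function(a) {
      f2 <- seq(0, 1 - a, by = by)
      cbind(a, f2, 1 - a - f2)
    }))
  }
  sse <- apply(grid, 1, function(f) {
    mf <- A %*% f
    k <- sum(b * mf) / sum(mf^2)
    if (!is.finite(k) || k < 0) k <- 0
    sum((b - k * mf)^2)
  })
  grid[which.min(sse), ]
}

# Bisection root of tan(x) = x in (pi, 3pi/2): the first zero of the
# sphere form factor amplitude occurs at x = qR solving this equation.
oracleSphereFirstZero <- function() {
  f <- function(x) sin(x) - x * cos(x)  # zero of the amplitude numerator
  lo <- pi; hi <- 3 * pi / 2
  for (k in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Exact Guinier-law curve I(q) = i0 exp(-q^2 rg^2 / 3).
exactGuinierCurve <- function(rg = 3, i0 = 100,
    q = seq(0.02, 1.3 / rg, length.out = 40), sigma = 0) {
  scatteringCurve(q, i0 * exp(-q^2 * rg^2 / 3),
    rep_len(sigma, length(q)))
}

# Small deterministic frame series around a single scattering level.
flatSeries <- function(nf = 6, nq = 30, level = 100, mode = "batch",
    seed = 1) {
  set.seed(seed)
  q <- seq(0.05, 1.5, length.out = nq)
  counts <- matrix(rpois(nq * nf, level), nq, nf)
  frameSeries(q, counts, sqrt(pmax(counts, 1)),
    time = seq_len(nf) - 0.5, mode = mode)
}

# Standard simulated study conditions used across tests: the protein
# standard and the tetramer/dimer system on the default instrument.
bsaSpec <- function(...) speciesSpec("bsa", mw = 66.5, rg = 2.78,
  center = 1.2, sigma = 0.08, mass = 0.5, ...)
tetSpec <- function(...) speciesSpec("tetramer", mw = 220, rg = 3.9,
  center = 1.0, sigma = 0.08, mass = 0.45, ...)
dimerSpec <- function(...) speciesSpec("dimer", mw = 110, rg = 3.1,
  center = 1.3, sigma = 0.07, mass = 0.05, ...)

idealInstrument <- function(...) instrumentSpec(
  deadVolumes = c(splitter = 0, uv = 0, rals = 0, ri = 0), ...)

# Concentration-normalized reference curve of one species from an ideal
# noiseless run (component library for mixture fits).
pureComponentCurve <- function(sp, nFrames = 480) {
  r <- simulateSecRun(sp, idealInstrument(), nFrames = nFrames,
    noise = FALSE)
  n <- normalizeFrames(r$frames)
  s <- subtractSeries(n, 1:50)
  apx <- which.max(r$truth$concFrames[, 1])
  cc <- r$truth$concFrames[apx, 1]
  scatteringCurve(qValues(s), intensities(s)[, apx] / cc,
    sigmas(s)[, apx] / cc)
}
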
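# Internal numeric helpers shared across modules.

# Linear interpolation returning NA outside the support.
interpNA <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", rule = 1,
    ties = "ordered")$y
}

# Trapezoidal quadrature.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Weighted straight-line fit y ~ a + b x with weights w = 1/var(y).
# Returns coefficients and their variances from the weighted normal
# equations; if `unweighted`, residual variance scales the covariance.
wlsLine <- function(x, y, w = NULL) {
  unweighted <- is.null(w)
  if (unweighted) w <- rep(1, length(x))
  S <- sum(w); Sx <- sum(w * x); Sy <- sum(w * y)
  Sxx <- sum(w * x^2); Sxy <- sum(w * x * y)
  delta <- S * Sxx - Sx^2
  if (delta <= 0) stop("degenerate abscissa in line fit")
  slope <- (S * Sxy - Sx * Sy) / delta
  intercept <- (Sxx * Sy - Sx * Sxy) / delta
  res <- y - intercept - slope * x
  rss <- sum(w * res^2)
  scale2 <- if (unweighted) rss / max(1, length(x) - 2) else 1
  list(slope = slope, intercept = intercept,
    slopeVar = scale2 * S / delta, interceptVar = scale2 * Sxx / delta,
    rss = rss, n = length(x))
}

# Centered rolling mean, partial at the edges.
rollMean <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Parabolic refinement of a discrete maximum: apex abscissa from the
# vertex of the parabola through (x[i-1..i+1], y[i-1..i+1]).
refineApex <- function(x, y, i) {
  n <- length(x)
  if (i <= 1 || i >= n) return(x[i])
  d1 <- (y[i + 1] - y[i - 1]) / 2
  d2 <- y[i + 1] - 2 * y[i] + y[i - 1]
  if (!is.finite(d2) || d2 >= 0) return(x[i])
  off <- -d1 / d2
  if (abs(off) > 1) off <- sign(off)
  # assumes locally uniform grid spacing
  x[i] + off * (x[min(i + 1, n)] - x[i])
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
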
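# Independent oracles, kept deliberately naive.

# Closed-form Gaussian integral: area of A * exp(-(x-mu)^2 / (2 s^2)).
gaussAreaClosedForm <- function(amplitude, sigma) amplitude * sigma * sqrt(2 * pi)

# Brute-force two-Gaussian fit: exhaustive grid over (mu1, mu2), with
# amplitudes solved by linear least squares at fixed widths. Independent of
# the package's nonlinear fitter.
bruteForceTwoGauss <- function(profile, sigma, muGrid) {
  x <- positions(profile); y <- intensities(profile)
  best <- list(rss = Inf)
  for (m1 in muGrid) for (m2 in muGrid) {
    if (m2 <= m1) next
    X <- cbind(1, exp(-(x - m1)^2 / (2 * sigma^2)),
               exp(-(x - m2)^2 / (2 * sigma^2)))
    cf <- qr.coef(qr(X), y)
    rss <- sum((y - X %*% cf)^2)
    if (rss < best$rss) best <- list(rss = rss, mu = c(m1, m2), coef = cf)
  }
  best
}

# Trapezoid integral of a fitted Gaussian component over the profile grid.
trapezoidComponentArea <- function(band, profile) {
  x <- positions(profile)
  y <- band$amplitude * exp(-(x - band$mu)^2 / (2 * band$sigma^2))
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}
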
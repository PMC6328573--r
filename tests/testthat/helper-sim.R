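# Shared fixtures: acquisition specs and a synthetic profile builder.

# Ideal acquisition: no camera noise, no registration jitter.
noiselessAcq <- function(...) {
  acquisitionSpec(noiseSd = 0, positionJitterUm = 0, ...)
}

# A bare Profile on a uniform grid (um) from a vector of intensities.
mkProfile <- function(y, dx = 0.65, channel = "test") {
  new("Profile", positions = (seq_along(y) - 1) * dx, intensities = y,
      channel = channel)
}

# Synthetic profile holding sum-of-Gaussian peaks plus constant baseline.
gaussProfile <- function(mus, sigmas, areas, baseline = 0, n = 3200, dx = 0.65,
                         noiseSd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- (seq_len(n) - 1) * dx
  y <- rep(baseline, n)
  for (i in seq_along(mus))
    y <- y + areas[i] * dnorm(x, mus[i], sigmas[i])
  if (noiseSd > 0) y <- y + rnorm(n, 0, noiseSd)
  mkProfile(y, dx)
}

# Render a scenario frame and analyze it with its matched options.
runScenario <- function(name, seed, t = NULL, acq = NULL) {
  sc <- simScenario(name)
  if (!is.null(acq)) sc$acq <- acq
  if (is.null(t)) t <- sc$acq@frameTimes[1]
  fr <- renderFrame(sc$truths, sc$model, sc$acq, t, seed = seed)
  res <- suppressWarnings(analyzeFrame(fr$image, repeatsizer:::.scenarioOpts(sc)))
  list(scenario = sc, frame = fr, result = res)
}
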
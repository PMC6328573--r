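test_that("profile extraction reduces the strip and orients by constriction distance", {
  img <- matrix(7, 50, 100)
  roi <- list(rows = c(10, 20), cols = c(1, 100))
  p <- extractProfile(img, roi, pixelSizeUm = 0.65, constrictionCol = 5)
  expect_equal(intensities(p), rep(7, 100))
  expect_equal(positions(p)[6], 0)           # constriction column maps to 0 um
  expect_gt(diff(positions(p))[1], 0)        # increases away from it
  expect_error(extractProfile(img, list(rows = c(40, 60), cols = c(1, 100)), 0.65),
               "ROI")
  # max reduction picks the brightest transverse pixel
  img[15, 30] <- 100
  pm <- extractProfile(img, roi, 0.65, reduce = "max")
  expect_equal(intensities(pm)[30], 100)
})

test_that("noise-free simulated band peaks at the truth position", {
  acq <- noiselessAcq()
  m <- defaultPositionModel("100bp")
  fr <- renderFrame(bandTruth(600, 50, 8, "sample"), m, acq, 30, seed = 1)
  p <- extractProfile(fr$image, defaultRois(acq)$sample, acq@pixelSizeUm,
                      acq@constrictionCol)
  argmax <- positions(p)[which.max(intensities(p))]
  expect_lt(abs(argmax - fr$truth$position_um), acq@pixelSizeUm)
})

test_that("identical ladders in both channels give near-identical profiles", {
  acq <- noiselessAcq()
  sc <- simScenario("ladder100_dual")
  fr <- renderFrame(sc$truths, sc$model, acq, 30, seed = 1)
  rois <- defaultRois(acq)
  pr <- extractProfile(fr$image, rois$reference, acq@pixelSizeUm, acq@constrictionCol)
  ps <- extractProfile(fr$image, rois$sample, acq@pixelSizeUm, acq@constrictionCol)
  expect_gt(cor(intensities(pr), intensities(ps)), 0.99)
})

test_that("background subtraction is exact against itself and recovers areas on a gradient", {
  p <- gaussProfile(800, 8, 5000, baseline = 120, noiseSd = 3, seed = 1)
  z <- subtractBackground(p, reference = p)
  expect_equal(intensities(z), rep(0, length(positions(p))))
  expect_error(subtractBackground(p, reference = mkProfile(1:10)), "grid")

  # band on a linear gradient: model-mode subtraction preserves the area
  acq <- acquisitionSpec(noiseSd = 2, positionJitterUm = 0,
                         background = c(200, 0.05))
  m <- defaultPositionModel("100bp")
  fr <- renderFrame(bandTruth(500, 80, 8, "sample"), m, acq, 30, seed = 7)
  prof <- extractProfile(fr$image, defaultRois(acq)$sample, acq@pixelSizeUm,
                         acq@constrictionCol)
  corr <- subtractBackground(prof, polyOrder = 1)
  bands <- fitBands(corr, detectPeaks(corr, 5))
  expect_equal(bands$area, fr$truth$area_counts, tolerance = 0.02)
})

test_that("frame differencing reveals all 8 detection-limit bands", {
  sc <- simScenario("ladder100_lod")
  ser <- renderSeries(sc$truths, sc$model, sc$acq, times = c(0, 300), seed = 5)
  roi <- defaultRois(sc$acq)$reference
  p0 <- extractProfile(ser$images[[1]], roi, sc$acq@pixelSizeUm, sc$acq@constrictionCol)
  p5 <- extractProfile(ser$images[[2]], roi, sc$acq@pixelSizeUm, sc$acq@constrictionCol)
  diffProf <- subtractBackground(p5, reference = p0)
  seeds <- detectPeaks(diffProf, minSnr = 5)
  expect_length(seeds, 8)
  expect_true(all(vapply(ser$truths[[2]]$position_um,
                         function(mu) min(abs(seeds - mu)) < 5, logical(1))))
})

test_that("pure-noise profiles rarely yield false peak detections", {
  falsePos <- vapply(1:100, function(s) {
    p <- gaussProfile(numeric(0), numeric(0), numeric(0), baseline = 0,
                      n = 1600, noiseSd = 5, seed = s)
    length(detectPeaks(p, minSnr = 5))
  }, numeric(1))
  expect_gte(mean(falsePos == 0), 0.95)
})

test_that("peaks closer than the separation radius merge to the stronger one", {
  p <- gaussProfile(c(500, 508), c(6, 6), c(4000, 2000), noiseSd = 0)
  seeds <- detectPeaks(p, minSnr = 3, minSeparationUm = 20)
  expect_length(seeds, 1)
  expect_lt(abs(seeds - 500), 4)   # the higher peak wins
  # well-separated peaks both survive
  p2 <- gaussProfile(c(400, 700), c(6, 6), c(4000, 2000), noiseSd = 0.01, seed = 1)
  expect_length(detectPeaks(p2, minSnr = 3, minSeparationUm = 20), 2)
})

test_that("simulated ladder at operating SNR yields exactly one seed per band", {
  sc <- simScenario("ladder100_dual")
  fr <- renderFrame(sc$truths, sc$model, sc$acq, 30, seed = 9)
  p <- extractProfile(fr$image, defaultRois(sc$acq)$reference, sc$acq@pixelSizeUm,
                      sc$acq@constrictionCol)
  seeds <- detectPeaks(subtractBackground(p, polyOrder = 1), minSnr = 5)
  expect_length(seeds, 11)
})

test_that("single-peak fits recover mu, sigma and area to 1e-3 relative", {
  p <- gaussProfile(421.3, 7.6, 52000, baseline = 10, noiseSd = 0)
  b <- fitBands(p, detectPeaks(p, 3))
  expect_equal(b$mu, 421.3, tolerance = 1e-3)
  expect_equal(b$sigma, 7.6, tolerance = 1e-3)
  expect_equal(b$area, 52000, tolerance = 1e-3)
  expect_equal(b$area, gaussAreaClosedForm(b$amplitude, b$sigma))
})

test_that("two overlapping peaks match the brute-force grid oracle", {
  # 4 sigma separation at SNR ~50
  sig <- 8; mus <- c(600, 600 + 4 * sig)
  p <- gaussProfile(mus, c(sig, sig), c(40000, 28000), noiseSd = 10, seed = 21)
  b <- fitBands(p, detectPeaks(p, 5))
  expect_equal(nrow(b), 2)
  oracle <- bruteForceTwoGauss(p, sig, seq(590, 645, by = 0.25))
  expect_lt(max(abs(b$mu - oracle$mu)), 0.5)
  expect_lt(max(abs(b$mu - mus)), 0.5)
})

test_that("fitted area agrees with the trapezoid integral of the component", {
  p <- gaussProfile(c(300, 900), c(8, 12), c(30000, 60000), noiseSd = 5, seed = 3)
  b <- fitBands(p, detectPeaks(p, 5))
  for (i in seq_len(nrow(b)))
    expect_equal(b$area[i], trapezoidComponentArea(b[i, ], p), tolerance = 5e-3)
})

test_that("fitting is idempotent and returns bands sorted by position", {
  p <- gaussProfile(c(700, 350, 980), c(8, 8, 8), c(3e4, 2e4, 4e4),
                    noiseSd = 4, seed = 8)
  b <- fitBands(p, detectPeaks(p, 5))
  expect_false(is.unsorted(b$mu, strictly = TRUE))
  b2 <- fitBands(p, b$mu)
  expect_lt(max(abs(b2$mu - b$mu)), 1e-6)
})

test_that("weak or absurdly broad components are dropped with a warning", {
  p <- gaussProfile(500, 8, 40000, noiseSd = 5, seed = 2)
  # a spurious seed in flat noise has no amplitude to fit
  expect_warning(b <- fitBands(p, c(500, 1500)), "rejected|converge")
  expect_equal(nrow(b), 1)
  expect_lt(abs(b$mu - 500), 0.5)
})

test_that("same ladder fitted in both channels stays within 2 um", {
  sc <- simScenario("ladder100_dual")
  run <- runScenario("ladder100_dual", seed = 31)
  cc <- channelConcordance(run$result$ladder,
                           run$result$report[, names(repeatsizer:::.emptyBands())])
  expect_true(cc$pass)
  expect_lt(cc$max_abs_um, 2)
})

test_that("repeated runs reproduce peak positions within 4 um", {
  mus <- sapply(1:4, function(s) {
    run <- runScenario("ladder100_dual", seed = 100 + s)
    run$result$ladder$mu
  })
  sds <- apply(mus, 1, sd)
  expect_lt(max(sds), 4)
})
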
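test_that("position model honors the 80 um 400/500 bp spacing and stays monotone", {
  m <- defaultPositionModel("100bp")
  expect_equal(predictPosition(m, 500) - predictPosition(m, 400), 80,
               tolerance = 1 / 80)
  x <- predictPosition(m, seq(100, 1000, by = 100))
  expect_true(all(diff(x) > 0))
  expect_true(all(x >= 0))
  # covers the full working range
  expect_equal(positionRange(m), c(100, 4000))
  # both sides of each internal knot agree to < 0.5 um
  seg <- m@segments
  for (i in seq_len(nrow(seg) - 1)) {
    k <- seg$size_max[i]
    xl <- seg$prefactor[i] * k^seg$exponent[i]
    xr <- seg$prefactor[i + 1] * k^seg$exponent[i + 1]
    expect_lt(abs(xl - xr), 0.5)
  }
  expect_error(defaultPositionModel("10bp"))
  expect_error(predictPosition(m, 50), "outside")
})

test_that("accumulated mass is linear in time and matches the delivered total", {
  acq <- acquisitionSpec()  # 0.09 uL/min
  # 100 fg/uL for 5 min -> 45 fg (the ~50 fg headline at 1 significant figure)
  expect_equal(accumulatedMass(100, acq, 300), 45)
  expect_equal(accumulatedMass(100, acq, 0), 0)
  expect_equal(accumulatedMass(7, acq, 120), 2 * accumulatedMass(7, acq, 60))
  expect_error(accumulatedMass(100, acq, -1))
  # 1 pg/uL split over 8 equimolar-intensity bands: per-band mass is total/8
  total <- accumulatedMass(1, acq, 300)
  perBand <- accumulatedMass(rep(1 / 8, 8), acq, 300)
  expect_equal(sum(perBand), total)
  expect_equal(perBand, rep(total / 8, 8))
})

test_that("rendered band intensity conserves dye_gain x mass", {
  acq <- noiselessAcq()
  m <- defaultPositionModel("100bp")
  tr <- bandTruth(500, 80, 8, "sample")
  fr <- renderFrame(tr, m, acq, 30, seed = 1)
  roi <- defaultRois(acq)$sample
  prof <- extractProfile(fr$image, roi, acq@pixelSizeUm, acq@constrictionCol)
  bg <- acq@background[1] + acq@background[2] * pmax(positions(prof), 0)
  area <- sum(intensities(prof) - bg) * acq@pixelSizeUm
  expect_equal(area, fr$truth$area_counts, tolerance = 1e-3)
  # multi-band conservation: total above-background intensity = sum of areas
  tr2 <- rbind(bandTruth(c(300, 500, 700), c(40, 80, 20), 8, "sample"))
  fr2 <- renderFrame(tr2, m, acq, 30, seed = 1)
  prof2 <- extractProfile(fr2$image, roi, acq@pixelSizeUm, acq@constrictionCol)
  area2 <- sum(intensities(prof2) - bg) * acq@pixelSizeUm
  expect_equal(area2, sum(fr2$truth$area_counts), tolerance = 5e-3)
})

test_that("empty truth tables render background-only frames", {
  acq <- noiselessAcq()
  m <- defaultPositionModel("100bp")
  fr <- renderFrame(bandTruth(numeric(0), numeric(0)), m, acq, 30, seed = 1)
  expect_equal(nrow(fr$truth), 0)
  prof <- extractProfile(fr$image, defaultRois(acq)$sample, acq@pixelSizeUm,
                         acq@constrictionCol)
  corr <- subtractBackground(prof, polyOrder = 1)
  expect_lt(max(abs(intensities(corr))), 1)
  expect_length(detectPeaks(corr, 5), 0)
})

test_that("band amplitudes grow linearly with enrichment time", {
  sc <- simScenario("ladder100_lod")
  acq <- `slot<-`(sc$acq, "noiseSd", value = 0)
  acq <- `slot<-`(acq, "positionJitterUm", value = 0)
  ser <- renderSeries(sc$truths, sc$model, acq, times = c(150, 300), seed = 4)
  roi <- defaultRois(acq)$reference
  amp <- lapply(ser$images, function(img) {
    p <- extractProfile(img, roi, acq@pixelSizeUm, acq@constrictionCol)
    vapply(ser$truths[[1]]$position_um, function(mu)
      max(intensities(p)[abs(positions(p) - mu) < 10]) -
        (acq@background[1] + acq@background[2] * mu), numeric(1))
  })
  expect_equal(amp[[2]] / amp[[1]], rep(2, 8), tolerance = 0.02)
  # monotone non-decreasing over time
  expect_true(all(amp[[2]] >= amp[[1]]))
})

test_that("identical seeds give bit-identical frames, different seeds differ", {
  sc <- simScenario("calibration_trio")
  a <- renderFrame(sc$truths, sc$model, sc$acq, 30, seed = 11)
  b <- renderFrame(sc$truths, sc$model, sc$acq, 30, seed = 11)
  d <- renderFrame(sc$truths, sc$model, sc$acq, 30, seed = 12)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$image, d$image))
})

test_that("renderFrame rejects bands outside the model range, naming them", {
  m <- defaultPositionModel("100bp")
  tr <- bandTruth(c(500, 4500), c(10, 10))
  expect_error(renderFrame(tr, m, acquisitionSpec(), 30, seed = 1), "4500")
})

test_that("scenario registry is deterministic and matches declared contents", {
  expect_setequal(
    grep("_25cyc$", listScenarios(), value = TRUE),
    paste0(c("NA13506", "NA13512", "GM03620", "GM14044", "GM02168",
             "GM04604", "NA05164", "GM03756A"), "_25cyc"))
  trio <- simScenario("calibration_trio")
  smp <- trio$truths[trio$truths$channel == "sample", ]
  expect_equal(smp$size_bp, c(466, 798, 1512))
  expect_equal(smp$concentration, rep(80, 3))
  gm <- simScenario("GM03620_25cyc")
  expect_equal(gm$truths$size_bp[gm$truths$channel == "sample"], c(455, 581))
  expect_identical(simScenario("kb_pair"), simScenario("kb_pair"))
  expect_error(simScenario("nope"), "calibration_trio")
})
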
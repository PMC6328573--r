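#' Construct an acquisition specification
#'
#' Defaults emulate the published operating point: a 6.5 um camera pixel
#' behind a 10x objective (0.65 um in the sample plane), a field of view of
#' ~2 mm along the channel axis, a flow rate of 0.09 uL/min, and additive
#' Gaussian camera noise. The two channels are horizontal strips of the
#' same frame (reference on top, sample below) sharing the constriction
#' column.
#'
#' @param pixelSizeUm pixel pitch in the sample plane (um).
#' @param imageShape c(rows, cols) of the rendered frame.
#' @param constrictionCol 0-based pixel column of the constriction.
#' @param referenceRows,sampleRows 1-based c(first, last) row spans of the
#'   channel strips.
#' @param noiseSd additive Gaussian noise sd (counts).
#' @param background c(offset, slope) background model: counts plus
#'   counts-per-um gradient along the axis.
#' @param flowRate volumetric flow rate (uL/min).
#' @param dyeGain integrated counts*um per fg of DNA delivered to a band.
#' @param positionJitterUm per-band position jitter sd (um); models
#'   run-to-run registration error between channels and repeats.
#' @param frameTimes acquisition times (s).
#' @return an [AcquisitionSpec-class].
#' @export
acquisitionSpec <- function(pixelSizeUm = 0.65,
                            imageShape = c(160L, 3200L),
                            constrictionCol = 40,
                            referenceRows = c(21L, 60L),
                            sampleRows = c(101L, 140L),
                            noiseSd = 5,
                            background = c(100, 0.005),
                            flowRate = 0.09,
                            dyeGain = 20,
                            positionJitterUm = 0.5,
                            frameTimes = 30) {
  new("AcquisitionSpec", pixelSizeUm = pixelSizeUm,
      imageShape = as.integer(imageShape), constrictionCol = constrictionCol,
      referenceRows = as.integer(referenceRows),
      sampleRows = as.integer(sampleRows), noiseSd = noiseSd,
      background = background, flowRate = flowRate, dyeGain = dyeGain,
      positionJitterUm = positionJitterUm, frameTimes = frameTimes)
}

#' Ground-truth band table constructor
#'
#' @param size_bp fragment lengths (bp), >= 50.
#' @param concentration per-band concentrations (pg/uL) in the analyzed
#'   dilution.
#' @param sigma_um Gaussian band sd (um); the default 8 um models sharp
#'   amplicons, heterogeneous expanded alleles get inflated values.
#' @param channel "reference" or "sample", recycled.
#' @return data.frame with one row per band.
#' @export
bandTruth <- function(size_bp, concentration, sigma_um = 8,
                      channel = "sample") {
  stopifnot(all(size_bp >= 50), all(concentration >= 0), all(sigma_um > 0))
  data.frame(channel = rep_len(as.character(channel), length(size_bp)),
             size_bp = as.numeric(size_bp),
             concentration = rep_len(as.numeric(concentration), length(size_bp)),
             sigma_um = rep_len(as.numeric(sigma_um), length(size_bp)))
}

#' DNA mass accumulated in a band after a given enrichment time
#'
#' Band stacking concentrates all fragments of one length delivered by the
#' flow at a single position, so the accumulated mass is simply
#' concentration x flow rate x time: linear in time and zero at t = 0.
#' At the published operating point (100 fg/uL per band, 0.09 uL/min,
#' 5 min) each band holds 45 fg, the "~50 fg" headline figure.
#'
#' @param concentration band concentration (pg/uL or fg/uL; output shares
#'   the mass unit of the input).
#' @param acq an [AcquisitionSpec-class] providing the flow rate.
#' @param tSeconds enrichment time (s), >= 0.
#' @return accumulated mass, in the input's mass unit.
#' @export
accumulatedMass <- function(concentration, acq, tSeconds) {
  if (any(tSeconds < 0)) stop("enrichment time must be >= 0")
  concentration * acq@flowRate * (tSeconds / 60)
}

# Column-center axial coordinates (um from constriction) of a frame.
.axisUm <- function(acq) {
  (seq_len(acq@imageShape[2]) - 1 - acq@constrictionCol) * acq@pixelSizeUm
}

.channelRows <- function(acq, channel) {
  rr <- if (channel == "reference") acq@referenceRows else acq@sampleRows
  seq.int(rr[1], rr[2])
}

#' Render a synthetic dual-channel micrograph
#'
#' Each band becomes a Gaussian ridge along the channel axis, centered at
#' the model-predicted position (plus seeded registration jitter), with a
#' top-hat transverse profile filling its channel strip. The per-pixel
#' intensity is scaled so the integrated profile area (counts*um, averaged
#' over the strip) equals dyeGain x accumulated mass. A constant-plus-
#' gradient background and additive Gaussian noise are applied, and counts
#' are clipped to the 16-bit range.
#'
#' @param truths data.frame from [bandTruth()] (columns channel, size_bp,
#'   concentration, sigma_um).
#' @param model a [PositionModel-class]; all truth sizes must lie in range.
#' @param acq an [AcquisitionSpec-class].
#' @param tSeconds enrichment time (s).
#' @param seed integer seed; identical seeds give bit-identical frames.
#' @return list(image = numeric matrix of counts,
#'   truth = data.frame(channel, size_bp, position_um, sigma_um,
#'   concentration_pg_per_uL, mass_fg, area_counts)).
#' @export
renderFrame <- function(truths, model, acq, tSeconds = 30, seed = 1L) {
  rng <- positionRange(model)
  bad <- truths$size_bp < rng[1] | truths$size_bp > rng[2]
  if (any(bad))
    stop(sprintf("band size(s) outside position-model range [%g, %g] bp: %s",
                 rng[1], rng[2], paste(truths$size_bp[bad], collapse = ", ")))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  nr <- acq@imageShape[1]; nc <- acq@imageShape[2]
  x <- .axisUm(acq)
  img <- matrix(rep(acq@background[1] + acq@background[2] * pmax(x, 0),
                    each = nr), nr, nc)
  n <- nrow(truths)
  tr <- data.frame(channel = character(0), size_bp = numeric(0),
                   position_um = numeric(0), sigma_um = numeric(0),
                   concentration_pg_per_uL = numeric(0), mass_fg = numeric(0),
                   area_counts = numeric(0))
  if (n > 0) {
    mu <- predictPosition(model, truths$size_bp) +
      stats::rnorm(n, 0, acq@positionJitterUm)
    mass_fg <- accumulatedMass(truths$concentration, acq, tSeconds) * 1000 # pg -> fg
    area <- acq@dyeGain * mass_fg
    for (i in seq_len(n)) {
      rows <- .channelRows(acq, truths$channel[i])
      ridge <- area[i] * stats::dnorm(x, mu[i], truths$sigma_um[i])
      img[rows, ] <- img[rows, ] + rep(ridge, each = length(rows))
    }
    tr <- data.frame(channel = truths$channel, size_bp = truths$size_bp,
                     position_um = mu, sigma_um = truths$sigma_um,
                     concentration_pg_per_uL = truths$concentration,
                     mass_fg = mass_fg, area_counts = area)
    tr <- tr[order(tr$channel, tr$position_um), , drop = FALSE]
    rownames(tr) <- NULL
  }
  if (acq@noiseSd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, acq@noiseSd), nr, nc)
  img <- pmin(pmax(round(img), 0), 65535)
  list(image = img, truth = tr)
}

#' Render a time series of frames
#'
#' Frames share the band position jitter (the bands do not move between
#' exposures of one run) but have independent camera noise; amplitudes grow
#' linearly with enrichment time.
#'
#' @inheritParams renderFrame
#' @param times acquisition times (s).
#' @return list(images = list of matrices, truths = list of truth tables,
#'   times = times).
#' @export
renderSeries <- function(truths, model, acq, times = acq@frameTimes, seed = 1L) {
  # reuse one jitter draw: render each frame with the same seed for band
  # placement, then overwrite noise with a per-frame stream
  frames <- vector("list", length(times))
  truthTabs <- vector("list", length(times))
  for (k in seq_along(times)) {
    noiseless <- `slot<-`(acq, "noiseSd", value = 0)
    fr <- renderFrame(truths, model, noiseless, times[k], seed = seed)
    if (acq@noiseSd > 0) {
      set.seed((as.integer(seed) + 7919L * k) %% .Machine$integer.max)
      nr <- acq@imageShape[1]; nc <- acq@imageShape[2]
      fr$image <- pmin(pmax(round(fr$image +
        matrix(stats::rnorm(nr * nc, 0, acq@noiseSd), nr, nc)), 0), 65535)
    }
    frames[[k]] <- fr$image
    truthTabs[[k]] <- fr$truth
  }
  list(images = frames, truths = truthTabs, times = times)
}
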
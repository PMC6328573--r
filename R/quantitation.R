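#' Estimate band concentration against the reference ladder
#'
#' Compares the fitted Gaussian area ("total intensity") of a sample band
#' to that of its nearest ladder neighbor of known concentration: because
#' accumulated mass — and hence integrated fluorescence — is linear in
#' concentration at fixed flow and time, the concentration ratio equals the
#' area ratio. The neighbor is chosen by position (|delta mu|), ties broken
#' toward the lower-MW band. Fitted areas (not raw window sums) are used so
#' overlapping neighbors do not contaminate the estimate.
#'
#' @param sampleBand single-row fitted band (the analyte).
#' @param ladderBands fitted ladder band table.
#' @param ladderConc declared per-band ladder concentrations (pg/uL), one
#'   per ladder band.
#' @param dilution dilution factor from the stock to the analyzed solution.
#' @param areaRelSe optional relative standard errors of the two areas
#'   c(sample, ladder) combined in quadrature; defaults to 0.
#' @return list(concentration pg/uL in the analyzed dilution, undiluted
#'   ng/uL, reference_index, reference_size position, relative_se).
#' @export
estimateConcentration <- function(sampleBand, ladderBands, ladderConc,
                                  dilution = 1, areaRelSe = c(0, 0)) {
  stopifnot(nrow(ladderBands) == length(ladderConc))
  d <- abs(ladderBands$mu - sampleBand$mu)
  j <- which(d == min(d))[1]   # ties resolve to the smaller position (lower MW)
  if (!is.finite(ladderBands$area[j]) || ladderBands$area[j] <= 0)
    stop("reference ladder band has zero/invalid area (saturated or failed fit)")
  conc <- ladderConc[j] * sampleBand$area / ladderBands$area[j]
  list(concentration = conc,
       undiluted_ng_per_uL = conc * dilution / 1000,
       reference_index = j,
       reference_mu = ladderBands$mu[j],
       relative_se = sqrt(sum(areaRelSe^2)))
}

#' Per-cycle PCR amplification factor
#'
#' The geometric per-cycle growth of amplicon concentration between two
#' cycle numbers: g = (c2/c1)^(1/(n2-n1)). Efficient exponential
#' amplification gives g close to 2 (two copies per cycle); late-cycle
#' saturation drives g toward 1.
#'
#' @param c1,c2 concentrations at cycles n1 and n2 (any common unit), > 0.
#' @param n1,n2 cycle numbers, n2 > n1.
#' @return per-cycle factor g.
#' @export
amplificationFactor <- function(c1, n1, c2, n2) {
  if (n2 <= n1) stop("n2 must exceed n1")
  if (c1 <= 0 || c2 <= 0) stop("concentrations must be positive")
  (c2 / c1)^(1 / (n2 - n1))
}

#' Volume, mass and molecule count delivered by the flow
#'
#' Bookkeeping for sensitivity arithmetic: the analyzed volume is flow rate
#' x time; the delivered mass is concentration x volume; the molecule count
#' uses the standard 650 g/mol per bp of double-stranded DNA.
#'
#' @param concentration fg/uL.
#' @param flowRate uL/min.
#' @param minutes analysis duration (min).
#' @param lengthBp fragment length for the molecule count.
#' @return list(volume_uL, mass_fg, molecules).
#' @export
deliveredMass <- function(concentration, flowRate, minutes, lengthBp = 1000) {
  stopifnot(concentration >= 0, flowRate >= 0, minutes >= 0)
  vol <- flowRate * minutes
  mass <- concentration * vol
  molecules <- mass * 1e-15 * 6.02214076e23 / (lengthBp * 650)
  list(volume_uL = vol, mass_fg = mass, molecules = molecules)
}

#' Sensitivity fold-change between two instruments
#'
#' Given each instrument's limit of detection (concentration) and processed
#' volume, returns the concentration fold and the mass fold (concentration
#' x volume) of instrument A relative to instrument B.
#'
#' @param lodConcA,lodConcB detection-limit concentrations (same unit).
#' @param volA,volB processed volumes (same unit).
#' @return list(concentration_fold = lodConcB/lodConcA,
#'   mass_fold = lodConcB*volB / (lodConcA*volA)).
#' @export
sensitivityRatio <- function(lodConcA, volA, lodConcB, volB) {
  stopifnot(lodConcA > 0, lodConcB > 0, volA > 0, volB > 0)
  list(concentration_fold = lodConcB / lodConcA,
       mass_fold = (lodConcB * volB) / (lodConcA * volA))
}
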
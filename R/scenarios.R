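# Scenario registry: deterministic (truths, model, acq) bundles mirroring
# the published experiments, used by closed-loop tests and the CLI.

# Table of patient-derived samples after 25 PCR cycles: expected allele
# sizes (bp) and measured stock concentrations (ng/uL). Expanded alleles
# (sigma inflated 2.5x vs the default sharp band) are flagged.
.patientSamples <- list(
  NA13506  = list(ladder = "100bp", sizes = c(446, 545),  conc_ng = c(0.05, 0.05), expanded = c(FALSE, FALSE), locus = "HTT"),
  NA13512  = list(ladder = "100bp", sizes = c(449, 539),  conc_ng = c(0.2, 0.3),   expanded = c(FALSE, FALSE), locus = "HTT"),
  GM03620  = list(ladder = "100bp", sizes = c(455, 581),  conc_ng = c(0.4, 0.2),   expanded = c(FALSE, FALSE), locus = "HTT"),
  GM14044  = list(ladder = "1kb",   sizes = c(458, 2193), conc_ng = c(0.5, 0.2),   expanded = c(FALSE, TRUE),  locus = "HTT"),
  GM02168  = list(ladder = "100bp", sizes = c(446, 491),  conc_ng = c(0.1, 0.2),   expanded = c(FALSE, FALSE), locus = "HTT"),
  GM04604  = list(ladder = "1kb",   sizes = c(1051),      conc_ng = c(0.5),        expanded = FALSE,           locus = "DMPK"),
  NA05164  = list(ladder = "1kb",   sizes = c(1099, 2167), conc_ng = c(0.4, 0.1),  expanded = c(FALSE, TRUE),  locus = "DMPK"),
  GM03756A = list(ladder = "1kb",   sizes = c(1051, 2386), conc_ng = c(0.2, 0.1),  expanded = c(FALSE, TRUE),  locus = "DMPK")
)

.SHARP_SIGMA <- 8       # um, sharp amplicon bands
.BROAD_FACTOR <- 2.5    # width inflation of heterogeneous expanded alleles

.ladderTruth <- function(kind, perBandConc, channel = "reference") {
  bandTruth(ladderSizes(kind), perBandConc, .SHARP_SIGMA, channel)
}

.patientScenario <- function(name) {
  s <- .patientSamples[[name]]
  sig <- ifelse(s$expanded, .SHARP_SIGMA * .BROAD_FACTOR, .SHARP_SIGMA)
  # stocks are diluted ~100x into the separation buffer: ng/uL -> 10 pg/uL
  truths <- rbind(
    .ladderTruth(s$ladder, 15),
    bandTruth(s$sizes, s$conc_ng * 10, sig, "sample"))
  list(truths = truths, model = defaultPositionModel(s$ladder),
       acq = acquisitionSpec(frameTimes = 100), ladder_kind = s$ladder,
       ladder_conc = rep(15, length(ladderSizes(s$ladder))),
       locus = s$locus, dilution = 100)
}

.scenarioRegistry <- function() {
  reg <- list(
    calibration_trio = function() {
      truths <- rbind(.ladderTruth("100bp", 40),
                      bandTruth(c(466, 798, 1512), 80, .SHARP_SIGMA, "sample"))
      list(truths = truths, model = defaultPositionModel("100bp"),
           acq = acquisitionSpec(), ladder_kind = "100bp",
           ladder_conc = rep(40, 11), locus = NA_character_, dilution = 1)
    },
    kb_pair = function() {
      truths <- rbind(.ladderTruth("1kb", 40),
                      bandTruth(c(1091, 3314), 100, .SHARP_SIGMA, "sample"))
      list(truths = truths, model = defaultPositionModel("1kb"),
           acq = acquisitionSpec(frameTimes = 60), ladder_kind = "1kb",
           ladder_conc = rep(40, 6), locus = NA_character_, dilution = 1)
    },
    ladder100_dual = function() {
      truths <- rbind(.ladderTruth("100bp", 40, "reference"),
                      .ladderTruth("100bp", 40, "sample"))
      list(truths = truths, model = defaultPositionModel("100bp"),
           acq = acquisitionSpec(), ladder_kind = "100bp",
           ladder_conc = rep(40, 11), locus = NA_character_, dilution = 1)
    },
    ladder100_lod = function() {
      # detection-limit run: 1 pg/uL total over 8 equimolar bands,
      # followed from t = 0 to 300 s
      sizes <- seq(100, 800, by = 100)
      truths <- bandTruth(sizes, 1 / 8, .SHARP_SIGMA, "reference")
      list(truths = truths, model = defaultPositionModel("100bp"),
           acq = acquisitionSpec(frameTimes = c(0, 150, 300)),
           ladder_kind = "100bp", ladder_conc = rep(1 / 8, 8),
           locus = NA_character_, dilution = 1)
    }
  )
  for (nm in names(.patientSamples)) {
    local({
      n0 <- nm
      reg[[paste0(n0, "_25cyc")]] <<- function() .patientScenario(n0)
    })
  }
  reg
}

#' List registered simulation scenarios
#' @return character vector of scenario names.
#' @export
listScenarios <- function() sort(names(.scenarioRegistry()))

#' Retrieve a deterministic simulation scenario
#'
#' Scenarios bundle a ground-truth band table, a position model and an
#' acquisition spec mirroring the published experiments: the three-fragment
#' sizing calibration (466/798/1512 bp at 80 pg/uL against the 100 bp
#' ladder), the high-MW pair (1091/3314 bp against the 1 kb ladder), the
#' same-ladder-in-both-channels concordance run, the detection-limit time
#' series (8 bands at 0.125 pg/uL each), and each patient-derived sample
#' after 25 PCR cycles with its expected allele sizes; heterogeneous
#' expanded alleles carry a 2.5x inflated band width.
#'
#' @param name scenario name; see [listScenarios()].
#' @return list with elements truths, model, acq, ladder_kind, ladder_conc,
#'   locus, dilution. Identical names yield identical contents.
#' @export
simScenario <- function(name) {
  reg <- .scenarioRegistry()
  if (!name %in% names(reg))
    stop(sprintf("unknown scenario '%s'; available: %s",
                 name, paste(sort(names(reg)), collapse = ", ")))
  reg[[name]]()
}
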
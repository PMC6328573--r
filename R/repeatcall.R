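# Shipped locus registry. Anchors are printed (repeat count, amplicon
# length) pairs; flanks are derived. The DMPK locus carries two
# conventions because the published conversions are mutually inconsistent:
# "DMPK" uses the per-allele flank (1051 bp for 5 repeats -> flank 1036),
# "DMPK_subtractive" counts repeats in excess of the 5-repeat normal
# amplicon taken as a 1051 bp baseline (repeats = (size - 1051)/3).
.locusRegistry <- function() {
  list(
    HTT  = new("LocusModel", name = "HTT",  anchorRepeats = 15, anchorLength = 446, unit = 3),
    GFP  = new("LocusModel", name = "GFP",  anchorRepeats = 15, anchorLength = 672, unit = 3),
    DMPK = new("LocusModel", name = "DMPK", anchorRepeats = 5,  anchorLength = 1051, unit = 3),
    DMPK_subtractive = new("LocusModel", name = "DMPK_subtractive",
                           anchorRepeats = 0, anchorLength = 1051, unit = 3)
  )
}

#' List shipped repeat loci
#' @return character vector of locus names.
#' @export
listLoci <- function() names(.locusRegistry())

#' Retrieve a shipped locus model
#'
#' Shipped loci: HTT (15 CAGs -> 446 bp amplicon; the adjacent polymorphic
#' CCG tract is folded into the flank), GFP (the CAG-bearing GFP transgene,
#' 15 CAGs -> 672 bp), DMPK (5 CTGs -> 1051 bp per-allele amplicon) and
#' DMPK_subtractive (repeats counted in excess of the 1051 bp normal-allele
#' baseline).
#'
#' @param name locus name; see [listLoci()].
#' @return a [LocusModel-class].
#' @export
getLocus <- function(name) {
  reg <- .locusRegistry()
  if (!name %in% names(reg))
    stop(sprintf("unknown locus '%s'; available: %s",
                 name, paste(names(reg), collapse = ", ")))
  reg[[name]]
}

#' Construct a custom locus model
#'
#' @param name locus identifier.
#' @param anchorRepeats repeat count of the anchor allele.
#' @param anchorLength amplicon length (bp) of the anchor allele.
#' @param unit repeat unit (bp), 3 for trinucleotide repeats.
#' @return a [LocusModel-class].
#' @export
locusModel <- function(name, anchorRepeats, anchorLength, unit = 3) {
  new("LocusModel", name = name, anchorRepeats = anchorRepeats,
      anchorLength = anchorLength, unit = unit)
}

#' Expected amplicon length for a repeat count
#'
#' length = flank + unit x repeats, with the flank derived from the locus
#' anchor; exact at the anchor by construction.
#'
#' @param locus a [LocusModel-class].
#' @param repeats repeat count(s), >= 0.
#' @return amplicon length(s) in bp.
#' @export
expectedLength <- function(locus, repeats) {
  if (any(repeats < 0)) stop("repeat counts must be >= 0")
  locusFlank(locus) + locus@unit * repeats
}

#' Call a repeat count from an amplicon size
#'
#' repeats = (size - flank) / unit, rounded to the nearest integer
#' (default) or floored. Sizes at or below the flank yield a zero-repeat
#' call with a warning, never a negative count. The repeat-count standard
#' error is the size standard error divided by the unit length.
#'
#' @param locus a [LocusModel-class].
#' @param sizeBp measured amplicon size (bp).
#' @param seBp size standard error (bp).
#' @param mode "nearest" or "floor".
#' @return list(repeats, repeat_se, raw = un-rounded value, below_flank).
#' @export
repeatCount <- function(locus, sizeBp, seBp = 0, mode = c("nearest", "floor")) {
  mode <- match.arg(mode)
  raw <- (sizeBp - locusFlank(locus)) / locus@unit
  below <- raw < 0
  if (any(below)) {
    warning(sprintf("size(s) below the %s flank (%g bp); zero-repeat call",
                    locus@name, locusFlank(locus)))
    raw[below] <- 0
  }
  reps <- if (mode == "nearest") round(raw) else floor(raw)
  list(repeats = as.integer(reps), repeat_se = seBp / locus@unit,
       raw = raw, below_flank = below)
}

#' Allele heterogeneity score from band broadening
#'
#' An unstable expanded allele is a population of lengths, so its band is
#' broader than a sharp ladder band at the same position. The score is the
#' width ratio of the sample band to a matched ladder band; through the
#' local calibration slope it converts to a length spread in bp and
#' repeats.
#'
#' @param band single-row fitted sample band.
#' @param ladderBand single-row fitted ladder band at a comparable
#'   position.
#' @param localSlope local calibration slope (bp/um) at the band position.
#' @param threshold width ratio at or above which the band is labeled
#'   heterogeneous.
#' @return list(width_ratio, spread_bp, spread_repeats, heterogeneous).
#' @export
heterogeneityScore <- function(band, ladderBand, localSlope, threshold = 1.8) {
  if (!is.finite(ladderBand$sigma) || ladderBand$sigma <= 0)
    stop("matched ladder band has zero/invalid width")
  ratio <- band$sigma / ladderBand$sigma
  spread <- band$sigma * abs(localSlope)
  list(width_ratio = ratio, spread_bp = spread, spread_repeats = spread / 3,
       heterogeneous = ratio >= threshold)
}
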
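#' @import methods
NULL

#' Piecewise power-law band-position model
#'
#' Maps DNA fragment length (bp) to the equilibrium distance of its band
#' from the chip constriction (um). Each segment is a power law
#' x(L) = prefactor * L^exponent over a size range; segments join
#' continuously. Position increases strictly with fragment length: longer
#' fragments equilibrate further from the constriction.
#'
#' @slot segments data.frame with columns \code{size_min}, \code{size_max}
#'   (bp), \code{prefactor} (um), \code{exponent} (unitless).
#' @slot constrictionUm distance (um) of the constriction from the image
#'   origin along the channel axis; band coordinates are reported relative
#'   to the constriction.
#'
#' @seealso [defaultPositionModel()], [predictPosition()]
#' @export
setClass("PositionModel",
  representation(segments = "data.frame", constrictionUm = "numeric"),
  validity = function(object) {
    seg <- object@segments
    need <- c("size_min", "size_max", "prefactor", "exponent")
    if (!all(need %in% names(seg)))
      return(sprintf("segments must have columns %s", paste(need, collapse = ", ")))
    if (nrow(seg) < 1L) return("at least one segment required")
    if (any(seg$prefactor <= 0)) return("prefactors must be positive")
    if (any(seg$size_min >= seg$size_max)) return("segment size ranges must be non-empty")
    if (nrow(seg) > 1L) {
      # segments must tile the range and join continuously (< 0.5 um at knots)
      for (i in seq_len(nrow(seg) - 1L)) {
        if (seg$size_max[i] != seg$size_min[i + 1L])
          return("segments must be contiguous in size")
        knot <- seg$size_max[i]
        xl <- seg$prefactor[i] * knot^seg$exponent[i]
        xr <- seg$prefactor[i + 1L] * knot^seg$exponent[i + 1L]
        if (abs(xl - xr) >= 0.5)
          return(sprintf("segments discontinuous at %g bp (gap %.3g um)", knot, abs(xl - xr)))
      }
    }
    # strict monotonicity over a dense grid of the full range
    L <- seq(min(seg$size_min), max(seg$size_max), length.out = 512L)
    x <- .evalSegments(seg, L)
    if (any(diff(x) <= 0)) return("predicted position must increase strictly with size")
    if (any(x < 0)) return("predicted positions must be non-negative")
    TRUE
  }
)

#' One-dimensional fluorescence intensity profile
#'
#' The intensity trace along a channel's symmetry axis, on a uniform grid of
#' positions expressed in um from the constriction.
#'
#' @slot positions numeric, strictly increasing, uniformly spaced (um).
#' @slot intensities numeric, same length (counts; may be negative after
#'   background subtraction).
#' @slot channel character scalar, e.g. "reference" or "sample".
#' @slot meta list of provenance (source image, ROI, frame time, ...).
#' @export
setClass("Profile",
  representation(positions = "numeric", intensities = "numeric",
                 channel = "character", meta = "list"),
  prototype(channel = NA_character_, meta = list()),
  validity = function(object) {
    n <- length(object@positions)
    if (n != length(object@intensities))
      return("positions and intensities must have equal length")
    if (n >= 2L) {
      d <- diff(object@positions)
      if (any(d <= 0)) return("positions must be strictly increasing")
      if (max(d) - min(d) > 1e-6 * mean(d))
        return("positions must be uniformly spaced")
    }
    TRUE
  }
)

#' Acquisition and rendering parameters for synthetic micrographs
#'
#' Describes the virtual camera and chip geometry used by the simulator:
#' pixel pitch in the sample plane, frame geometry, the two channel strips,
#' additive Gaussian camera noise, a smooth background (constant plus linear
#' gradient along the axis), the volumetric flow rate driving band
#' enrichment, and the dye gain converting accumulated DNA mass to
#' integrated fluorescence counts.
#'
#' @slot pixelSizeUm pixel pitch in the sample plane (um).
#' @slot imageShape integer c(rows, cols).
#' @slot constrictionCol 0-based pixel column of the constriction.
#' @slot referenceRows,sampleRows integer c(first, last) 1-based row span of
#'   each channel strip.
#' @slot noiseSd additive Gaussian camera noise sd (counts).
#' @slot background c(offset, slope): counts and counts per um along x.
#' @slot flowRate volumetric flow rate (uL/min).
#' @slot dyeGain integrated counts*um per fg of DNA.
#' @slot positionJitterUm sd of the per-band position jitter emulating
#'   run-to-run registration error (um); 0 for ideal frames.
#' @slot frameTimes default acquisition times (s).
#' @export
setClass("AcquisitionSpec",
  representation(pixelSizeUm = "numeric", imageShape = "integer",
                 constrictionCol = "numeric", referenceRows = "integer",
                 sampleRows = "integer", noiseSd = "numeric",
                 background = "numeric", flowRate = "numeric",
                 dyeGain = "numeric", positionJitterUm = "numeric",
                 frameTimes = "numeric"),
  validity = function(object) {
    if (object@pixelSizeUm <= 0) return("pixelSizeUm must be positive")
    if (length(object@imageShape) != 2L || any(object@imageShape < 1L))
      return("imageShape must be c(rows, cols)")
    if (object@flowRate < 0) return("flowRate must be >= 0")
    if (object@dyeGain <= 0) return("dyeGain must be positive")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    if (object@positionJitterUm < 0) return("positionJitterUm must be >= 0")
    if (length(object@background) != 2L) return("background must be c(offset, slope)")
    for (rr in list(object@referenceRows, object@sampleRows)) {
      if (length(rr) != 2L || rr[1] < 1L || rr[2] > object@imageShape[1] || rr[1] > rr[2])
        return("channel row spans must lie inside the image")
    }
    TRUE
  }
)

#' Position-to-size calibration from a reference ladder
#'
#' Pairs fitted ladder band positions with their declared sizes and
#' interpolates between them, either linearly in (position, size) or
#' linearly in log-log space (a local power law). Both modes pass exactly
#' through the knots.
#'
#' @slot knots data.frame with columns \code{position_um}, \code{size_bp},
#'   strictly increasing in both.
#' @slot mode "linear" or "loglog".
#' @slot offsetUm registration shift (um) added to sample-channel band
#'   positions before interpolation.
#' @export
setClass("Calibration",
  representation(knots = "data.frame", mode = "character", offsetUm = "numeric"),
  prototype(mode = "linear", offsetUm = 0),
  validity = function(object) {
    k <- object@knots
    if (!all(c("position_um", "size_bp") %in% names(k)))
      return("knots must have columns position_um, size_bp")
    if (nrow(k) < 2L) return("at least 2 knots required")
    if (any(diff(k$position_um) <= 0) || any(diff(k$size_bp) <= 0))
      return("knots must be strictly increasing in both position and size")
    if (!object@mode %in% c("linear", "loglog"))
      return("mode must be 'linear' or 'loglog'")
    TRUE
  }
)

#' Linear locus model for trinucleotide-repeat amplicons
#'
#' An amplicon at a repeat locus is a fixed flank plus 3 bp per repeat:
#' length(N) = flank + 3 N. The flank is derived from a printed anchor pair
#' (anchor repeat count, anchor amplicon length) rather than asserted
#' independently.
#'
#' @slot name locus identifier (e.g. "HTT").
#' @slot anchorRepeats repeat count of the anchor allele.
#' @slot anchorLength amplicon length (bp) of the anchor allele.
#' @slot unit repeat unit length (bp); 3 for CAG/CTG.
#' @export
setClass("LocusModel",
  representation(name = "character", anchorRepeats = "numeric",
                 anchorLength = "numeric", unit = "numeric"),
  prototype(unit = 3),
  validity = function(object) {
    fl <- object@anchorLength - object@unit * object@anchorRepeats
    if (fl <= 0) return("derived flank must be positive")
    if (object@anchorRepeats < 0) return("anchorRepeats must be >= 0")
    TRUE
  }
)

setMethod("show", "PositionModel", function(object) {
  seg <- object@segments
  cat(sprintf("PositionModel: %d power-law segment(s), %g-%g bp\n",
              nrow(seg), min(seg$size_min), max(seg$size_max)))
  for (i in seq_len(nrow(seg)))
    cat(sprintf("  [%g, %g] bp: x = %.4g * L^%.3g um\n",
                seg$size_min[i], seg$size_max[i], seg$prefactor[i], seg$exponent[i]))
  invisible(NULL)
})

setMethod("show", "Profile", function(object) {
  n <- length(object@positions)
  cat(sprintf("Profile (%s): %d points, %.1f-%.1f um, max %.1f counts\n",
              object@channel, n,
              if (n) min(object@positions) else NA, if (n) max(object@positions) else NA,
              if (n) max(object@intensities) else NA))
  invisible(NULL)
})

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration (%s): %d knots, %g-%g bp, offset %.2f um\n",
              object@mode, nrow(object@knots),
              min(object@knots$size_bp), max(object@knots$size_bp), object@offsetUm))
  invisible(NULL)
})

setMethod("show", "LocusModel", function(object) {
  cat(sprintf("LocusModel %s: flank %g bp + %g bp x repeats (anchor %g -> %g bp)\n",
              object@name, locusFlank(object), object@unit,
              object@anchorRepeats, object@anchorLength))
  invisible(NULL)
})

setMethod("show", "AcquisitionSpec", function(object) {
  cat(sprintf(paste0("AcquisitionSpec: %dx%d px @ %.2f um/px, noise sd %g, ",
                     "flow %g uL/min, gain %g counts*um/fg\n"),
              object@imageShape[1], object@imageShape[2], object@pixelSizeUm,
              object@noiseSd, object@flowRate, object@dyeGain))
  invisible(NULL)
})

#' @describeIn Profile-class positions accessor (um from constriction).
#' @param x a Profile
#' @export
positions <- function(x) x@positions

#' @describeIn Profile-class intensities accessor (counts).
#' @export
intensities <- function(x) x@intensities

#' @describeIn Profile-class channel accessor.
#' @export
profileChannel <- function(x) x@channel

#' @describeIn Calibration-class knot table accessor.
#' @param cal a Calibration
#' @export
calibrationKnots <- function(cal) cal@knots

#' @describeIn LocusModel-class derived flank length (bp).
#' @param locus a LocusModel
#' @export
locusFlank <- function(locus) locus@anchorLength - locus@unit * locus@anchorRepeats
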
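# Evaluate a piecewise power-law segment table at lengths L (bp).
# Sizes at a knot belong to the left segment; both sides agree to < 0.5 um
# by the class validity, so the choice is cosmetic.
.evalSegments <- function(seg, L) {
  x <- rep(NA_real_, length(L))
  for (i in seq_len(nrow(seg))) {
    inseg <- if (i == 1L) L >= seg$size_min[i] & L <= seg$size_max[i]
             else         L >  seg$size_min[i] & L <= seg$size_max[i]
    x[inseg] <- seg$prefactor[i] * L[inseg]^seg$exponent[i]
  }
  x
}

#' Default band-position model for a ladder kind
#'
#' Returns the piecewise power-law position model used by the simulator and
#' by closed-loop tests. The model is anchored to the chip's one printed
#' geometric fact — the 400 and 500 bp ladder bands sit 80 um apart — and
#' covers 100 to 4000 bp with two power-law segments joined continuously at
#' 800 bp (exponent 1.2 below, 0.7 above), reproducing the qualitative
#' inhomogeneous power-law scaling of band position with molecular weight:
#' resolution is highest for mid-size fragments and degrades toward high
#' molecular weight. Coefficients are synthetic defaults, not measured chip
#' constants; both ladder kinds share the law because the position-size
#' response is a property of the chip and actuation, not of the ladder run
#' in it. The declared band sizes of each ladder kind are available via
#' [ladderSizes()].
#'
#' @param ladderKind "100bp" or "1kb".
#' @return a [PositionModel-class].
#' @examples
#' m <- defaultPositionModel("100bp")
#' predictPosition(m, 500) - predictPosition(m, 400)  # 80 um anchor
#' @export
defaultPositionModel <- function(ladderKind = c("100bp", "1kb")) {
  ladderKind <- match.arg(ladderKind)
  b1 <- 1.2; b2 <- 0.7; knot <- 800
  a1 <- 80 / (500^b1 - 400^b1)        # x(500) - x(400) = 80 um exactly
  a2 <- a1 * knot^(b1 - b2)           # continuity at the knot
  seg <- data.frame(size_min  = c(100, knot),
                    size_max  = c(knot, 4000),
                    prefactor = c(a1, a2),
                    exponent  = c(b1, b2))
  new("PositionModel", segments = seg, constrictionUm = 0)
}

#' Predict band position from fragment length
#'
#' @param model a [PositionModel-class].
#' @param sizeBp fragment length(s) in bp; must lie within the model range.
#' @return positions in um from the constriction, same length as `sizeBp`.
#' @export
predictPosition <- function(model, sizeBp) {
  rng <- positionRange(model)
  bad <- sizeBp < rng[1] | sizeBp > rng[2] | !is.finite(sizeBp)
  if (any(bad))
    stop(sprintf("fragment size(s) outside model range [%g, %g] bp: %s",
                 rng[1], rng[2], paste(sizeBp[bad], collapse = ", ")))
  .evalSegments(model@segments, sizeBp)
}

#' Size range covered by a position model
#'
#' @param model a [PositionModel-class].
#' @return c(min_bp, max_bp).
#' @export
positionRange <- function(model) {
  c(min(model@segments$size_min), max(model@segments$size_max))
}

#' Declared band sizes of the stock ladders
#'
#' The 100 bp ladder carries 11 bands (100-1000 bp in 100 bp steps plus
#' 1500 bp); the 1 kb ladder carries six bands from 0.5 to 4 kb.
#'
#' @param ladderKind "100bp" or "1kb".
#' @return integer vector of band sizes (bp), ascending.
#' @export
ladderSizes <- function(ladderKind = c("100bp", "1kb")) {
  ladderKind <- match.arg(ladderKind)
  switch(ladderKind,
         "100bp" = c(seq(100L, 1000L, by = 100L), 1500L),
         "1kb"   = c(500L, 1000L, 1500L, 2000L, 3000L, 4000L))
}
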
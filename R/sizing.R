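#' Build a position-to-size calibration from fitted ladder bands
#'
#' Pairs the fitted ladder band positions (ascending) with the declared
#' ladder sizes (ascending) by rank and verifies joint monotonicity. The
#' default interpolation is piecewise linear in (position, size); a log-log
#' mode (piecewise power law) is offered because band position scales as an
#' inhomogeneous power law of molecular weight, though interpolation choice
#' has little effect on accuracy at ladder density.
#'
#' @param ladderBands data.frame of fitted bands ([fitBands()]), one row
#'   per ladder band, sorted by mu.
#' @param ladderSizes declared ladder sizes (bp), ascending, same count.
#' @param mode "linear" or "loglog".
#' @param offsetUm registration shift (um) applied to sample-channel
#'   positions before interpolation.
#' @return a [Calibration-class].
#' @export
buildCalibration <- function(ladderBands, ladderSizes, mode = c("linear", "loglog"),
                             offsetUm = 0) {
  mode <- match.arg(mode)
  if (nrow(ladderBands) != length(ladderSizes))
    stop(sprintf("ladder band count (%d) does not match declared sizes (%d); mis-detected ladder",
                 nrow(ladderBands), length(ladderSizes)))
  mu <- ladderBands$mu
  if (is.unsorted(mu, strictly = TRUE))
    stop("ladder band positions must be strictly increasing")
  if (is.unsorted(ladderSizes, strictly = TRUE))
    stop("declared ladder sizes must be strictly increasing")
  new("Calibration",
      knots = data.frame(position_um = mu, size_bp = as.numeric(ladderSizes)),
      mode = mode, offsetUm = offsetUm)
}

# Interpolate size at positions (um), with linear extrapolation from the
# terminal segments. Returns list(size, slope, extrapolated).
.interpSize <- function(cal, posUm) {
  k <- cal@knots
  p <- k$position_um; s <- k$size_bp
  n <- length(p)
  if (cal@mode == "loglog") {
    # power-law segments through knots; positions must be positive in this
    # mode, fall back to linear when not
    if (all(p > 0) && all(posUm > 0)) {
      seg <- pmin(pmax(findInterval(posUm, p, all.inside = TRUE), 1L), n - 1L)
      b <- (log(s[seg + 1]) - log(s[seg])) / (log(p[seg + 1]) - log(p[seg]))
      size <- s[seg] * (posUm / p[seg])^b
      slope <- b * size / posUm
      return(list(size = size, slope = slope,
                  extrapolated = posUm < p[1] | posUm > p[n]))
    }
  }
  seg <- pmin(pmax(findInterval(posUm, p, all.inside = TRUE), 1L), n - 1L)
  slope <- (s[seg + 1] - s[seg]) / (p[seg + 1] - p[seg])
  size <- s[seg] + slope * (posUm - p[seg])
  list(size = size, slope = slope, extrapolated = posUm < p[1] | posUm > p[n])
}

#' Size fitted bands against a calibration
#'
#' Interpolates each band position (plus the channel registration offset)
#' through the calibration knots. Uncertainty is first-order propagation of
#' the fitted position standard error and a fixed channel-registration
#' term through the local slope:
#' se_bp = slope x sqrt(se_mu^2 + registration_sd^2). Bands outside the
#' knot range are linearly extrapolated from the terminal segment and
#' flagged (with a warning): extrapolated calls for very long heterogeneous
#' alleles are known to under-read.
#'
#' @param cal a [Calibration-class].
#' @param bands data.frame of fitted bands ([fitBands()]).
#' @param registrationSd inter-channel registration uncertainty (um);
#'   default 2 um, the typical inter-channel position accuracy.
#' @return `bands` with added columns size_bp, se_bp, local_slope,
#'   extrapolated.
#' @export
sizeBands <- function(cal, bands, registrationSd = 2) {
  if (!nrow(bands)) {
    bands$size_bp <- numeric(0); bands$se_bp <- numeric(0)
    bands$local_slope <- numeric(0); bands$extrapolated <- logical(0)
    return(bands)
  }
  r <- .interpSize(cal, bands$mu + cal@offsetUm)
  se_mu <- ifelse(is.finite(bands$se_mu), bands$se_mu, 0)
  bands$size_bp <- r$size
  bands$se_bp <- abs(r$slope) * sqrt(se_mu^2 + registrationSd^2)
  bands$local_slope <- r$slope
  bands$extrapolated <- r$extrapolated
  if (any(r$extrapolated))
    warning(sprintf("%d band(s) outside the ladder range; sizes extrapolated",
                    sum(r$extrapolated)))
  bands
}

#' Resolution length of a band pair
#'
#' The separation resolution Rs of two bands is their center distance over
#' the sum of their baseline widths, with baseline width taken as 4 sigma
#' per band: Rs = (mu2 - mu1) / (2 (sigma1 + sigma2)). The resolution
#' length is the size difference divided by Rs — the smallest size
#' difference that would still give baseline-resolved peaks (Rs = 1) at
#' this position.
#'
#' @param b1,b2 single-row band data.frames (b1 at the smaller position).
#' @param s1,s2 their sizes (bp), s1 < s2.
#' @return resolution length (bp).
#' @export
resolutionLength <- function(b1, b2, s1, s2) {
  stopifnot(s1 < s2)
  dmu <- b2$mu - b1$mu
  if (dmu <= 0) stop("bands coincide or are mis-ordered; resolution undefined")
  rs <- dmu / (2 * (b1$sigma + b2$sigma))
  (s2 - s1) / rs
}

#' Inter-channel band-position concordance
#'
#' QC for a frame with the same ladder run in both channels: pairs bands by
#' rank and reports the per-band position differences. The mean difference
#' estimates the channel registration offset.
#'
#' @param refBands,sampleBands fitted band tables of the two channels.
#' @return list(delta_um, max_abs_um, mean_um, n, pass); `pass` is FALSE
#'   (with NA deltas) when the band counts differ.
#' @export
channelConcordance <- function(refBands, sampleBands) {
  if (nrow(refBands) != nrow(sampleBands)) {
    return(list(delta_um = rep(NA_real_, max(nrow(refBands), nrow(sampleBands))),
                max_abs_um = NA_real_, mean_um = NA_real_,
                n = c(nrow(refBands), nrow(sampleBands)), pass = FALSE))
  }
  d <- sampleBands$mu - refBands$mu
  list(delta_um = d, max_abs_um = max(abs(d)), mean_um = mean(d),
       n = nrow(refBands), pass = TRUE)
}

#' Percent sizing error
#'
#' @param measured measured size(s), bp.
#' @param nominal nominal size(s), bp.
#' @return 100 x |measured - nominal| / nominal.
#' @export
sizingErrorPercent <- function(measured, nominal) {
  100 * abs(measured - nominal) / nominal
}
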
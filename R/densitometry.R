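#' Extract the 1-D intensity profile along a channel's symmetry line
#'
#' Reduces a transverse strip of the image to one intensity per axial pixel
#' and converts the pixel column to um from the constriction. Orientation
#' follows the chip convention: position increases away from the
#' constriction, i.e. with fragment length.
#'
#' @param image numeric matrix of counts (rows x cols).
#' @param roi list(rows = c(first, last), cols = c(first, last)) in 1-based
#'   pixel indices; rows is the transverse strip, cols the axial span.
#' @param pixelSizeUm pixel pitch (um).
#' @param constrictionCol 0-based pixel column of the constriction.
#' @param reduce transverse reduction, "mean" or "max".
#' @param channel channel label stored in the profile.
#' @param meta extra provenance stored in the profile.
#' @return a [Profile-class].
#' @export
extractProfile <- function(image, roi, pixelSizeUm, constrictionCol = 0,
                           reduce = c("mean", "max"), channel = NA_character_,
                           meta = list()) {
  reduce <- match.arg(reduce)
  r <- roi$rows; cl <- roi$cols
  if (r[1] < 1 || r[2] > nrow(image) || cl[1] < 1 || cl[2] > ncol(image) ||
      r[1] > r[2] || cl[1] > cl[2])
    stop("ROI out of image bounds")
  strip <- image[r[1]:r[2], cl[1]:cl[2], drop = FALSE]
  vals <- if (reduce == "mean") colMeans(strip) else apply(strip, 2, max)
  pos <- (seq.int(cl[1], cl[2]) - 1 - constrictionCol) * pixelSizeUm
  new("Profile", positions = pos, intensities = unname(vals),
      channel = channel, meta = c(meta, list(roi = roi, reduce = reduce)))
}

#' Robust noise estimate of a profile
#'
#' sd = 1.4826 x MAD of the first difference / sqrt(2); insensitive to
#' peaks, which occupy few grid points.
#'
#' @param profile a [Profile-class].
#' @return noise sd in counts.
#' @export
estimateNoise <- function(profile) {
  d <- diff(profile@intensities)
  1.4826 * stats::median(abs(d - stats::median(d))) / sqrt(2)
}

#' Subtract the background from a profile
#'
#' Two modes. Reference mode subtracts a same-grid reference profile
#' point-wise (e.g. the t = 0 s frame of a time series, before any band has
#' accumulated). Model mode fits a low-order polynomial to the non-peak
#' grid points — found by iterative sigma-clipping — and subtracts it.
#' Output values are not clipped: small negatives are expected in noise.
#'
#' @param profile a [Profile-class].
#' @param reference optional same-grid [Profile-class] to subtract.
#' @param polyOrder polynomial order (0, 1 or 2) for model mode.
#' @param clipSigma clipping threshold in noise sds for the peak mask.
#' @return a background-corrected [Profile-class].
#' @export
subtractBackground <- function(profile, reference = NULL, polyOrder = 1,
                               clipSigma = 3) {
  y <- profile@intensities
  if (!is.null(reference)) {
    if (length(reference@positions) != length(profile@positions) ||
        any(abs(reference@positions - profile@positions) > 1e-9))
      stop("reference profile grid does not match")
    corrected <- y - reference@intensities
  } else {
    if (!polyOrder %in% 0:2) stop("polyOrder must be 0, 1 or 2")
    x <- profile@positions
    keep <- rep(TRUE, length(y))
    for (it in 1:6) {
      X <- outer(x[keep], 0:polyOrder, `^`)
      cf <- qr.coef(qr(X), y[keep])
      bg <- drop(outer(x, 0:polyOrder, `^`) %*% cf)
      res <- y - bg
      s <- 1.4826 * stats::median(abs(res[keep] - stats::median(res[keep])))
      newKeep <- res < clipSigma * s   # clip high outliers (peaks) only
      if (identical(newKeep, keep)) break
      keep <- newKeep
      if (sum(keep) < 2 * (polyOrder + 1)) break
    }
    corrected <- y - bg
  }
  new("Profile", positions = profile@positions, intensities = corrected,
      channel = profile@channel,
      meta = c(profile@meta, list(background_subtracted = TRUE)))
}

# Gaussian smoothing of a vector with kernel sd in grid points.
.smooth1d <- function(y, sdPts = 2) {
  half <- max(1L, ceiling(4 * sdPts))
  k <- stats::dnorm(-half:half, 0, sdPts)
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  stats::filter(ypad, k, sides = 2)[(half + 1):(half + n)]
}

#' Detect candidate peak positions in a profile
#'
#' Local maxima of a lightly smoothed profile (Gaussian kernel, 2 grid
#' points sd) whose prominence exceeds `minSnr` times the robust noise sd
#' from [estimateNoise()]. Maxima closer than `minSeparationUm` are merged,
#' keeping the more prominent one (ties: the smaller position). Fitting
#' later uses the raw profile; smoothing only stabilizes detection.
#'
#' @param profile a [Profile-class], background-corrected.
#' @param minSnr prominence threshold in units of noise sd (> 0).
#' @param minSeparationUm merge radius (um).
#' @return numeric vector of seed positions (um), possibly empty.
#' @export
detectPeaks <- function(profile, minSnr = 5, minSeparationUm = 20) {
  stopifnot(minSnr > 0)
  x <- profile@positions
  ys <- as.numeric(.smooth1d(profile@intensities, 2))
  n <- length(ys)
  if (n < 3) return(numeric(0))
  noise <- estimateNoise(profile)
  if (!is.finite(noise) || noise <= 0) noise <- stats::sd(profile@intensities) * 1e-6 + 1e-12
  isMax <- which(ys[2:(n - 1)] > ys[1:(n - 2)] & ys[2:(n - 1)] >= ys[3:n]) + 1L
  if (!length(isMax)) return(numeric(0))
  # topographic prominence: in each direction, descend until a point higher
  # than the maximum is met; the key saddle is the higher of the two
  # stretch minima. Noise bumps riding a band flank meet a higher point
  # immediately and score near zero.
  prom <- vapply(isMax, function(i) {
    h <- ys[i]
    lmin <- h
    j <- i - 1L
    while (j >= 1L && ys[j] <= h) { if (ys[j] < lmin) lmin <- ys[j]; j <- j - 1L }
    rmin <- h
    j <- i + 1L
    while (j <= n && ys[j] <= h) { if (ys[j] < rmin) rmin <- ys[j]; j <- j + 1L }
    h - max(lmin, rmin)
  }, numeric(1))
  # absolute floor of 2 counts: integer-count images cannot carry sub-count
  # structure, and quantization of a smooth gradient leaves <= 1-count
  # staircase ripple even in noise-free frames
  ok <- prom >= max(minSnr * noise, 2)
  idx <- isMax[ok]; prom <- prom[ok]
  if (!length(idx)) return(numeric(0))
  # merge neighbors closer than the separation radius, keep higher prominence
  ord <- order(x[idx])
  idx <- idx[ord]; prom <- prom[ord]
  keep <- logical(length(idx))
  i <- 1L
  while (i <= length(idx)) {
    j <- i
    while (j < length(idx) && x[idx[j + 1]] - x[idx[j]] < minSeparationUm) j <- j + 1L
    grp <- i:j
    best <- grp[which.max(prom[grp])]
    # exact prominence tie: keep the smaller position
    tied <- grp[prom[grp] == prom[best]]
    keep[min(tied)] <- TRUE
    i <- j + 1L
  }
  sort(x[idx[keep]])
}

# Sum-of-Gaussians + constant model over one window.
.gaussSum <- function(x, pars, k) {
  y <- rep(pars[["b"]], length(x))
  for (j in seq_len(k))
    y <- y + pars[[paste0("A", j)]] *
      exp(-(x - pars[[paste0("mu", j)]])^2 / (2 * pars[[paste0("s", j)]]^2))
  y
}

#' Fit Gaussian bands at seeded positions
#'
#' Nonlinear least-squares fit of a sum of Gaussians plus a shared constant
#' baseline, over windows of +/- 4 initial sd around each seed; overlapping
#' windows are merged and their peaks fitted jointly. Bands are dropped
#' (with a warning) when the fitted amplitude falls below twice the noise
#' sd or the fitted sd exceeds the window half-width; non-convergence
#' yields a flagged band carrying the seed values rather than an error.
#'
#' @param profile a [Profile-class], background-corrected (raw, unsmoothed
#'   intensities are fitted).
#' @param seeds seed positions (um) from [detectPeaks()].
#' @param initSigmaUm initial Gaussian sd (um).
#' @param broadFactor bands whose fitted sd exceeds `broadFactor` x the
#'   median fitted sd are tagged broad (heterogeneous allele signature).
#' @return data.frame with one row per retained band: mu, sigma, amplitude,
#'   area, se_mu, baseline, converged, broad; sorted by mu. `area` is the
#'   analytic Gaussian integral amplitude x sigma x sqrt(2*pi).
#' @export
fitBands <- function(profile, seeds, initSigmaUm = 8, broadFactor = 1.8) {
  if (!length(seeds)) stop("at least one seed required")
  x <- profile@positions
  y <- profile@intensities
  noise <- estimateNoise(profile)
  seeds <- sort(seeds)
  dx <- if (length(x) > 1) x[2] - x[1] else 1
  halfPx <- max(3L, as.integer(ceiling(4 * initSigmaUm / dx)))
  # windows are pixel-snapped (seed's nearest grid point +/- a fixed pixel
  # count) so that sub-pixel seed shifts cannot change window membership;
  # overlapping windows merge and their peaks are fitted jointly
  ctr <- vapply(seeds, function(s) which.min(abs(x - s)), integer(1))
  lo <- pmax(ctr - halfPx, 1L); hi <- pmin(ctr + halfPx, length(x))
  groups <- list(); g <- 1L
  cur <- c(1L, 1L)
  for (i in seq_along(seeds)[-1]) {
    if (lo[i] <= hi[cur[2]]) cur[2] <- i
    else { groups[[g]] <- cur; g <- g + 1L; cur <- c(i, i) }
  }
  groups[[g]] <- cur
  out <- list()
  for (grp in groups) {
    ii <- grp[1]:grp[2]
    k <- length(ii)
    sel <- seq.int(lo[ii[1]], hi[ii[k]])
    xs <- x[sel]; ysub <- y[sel]
    b0 <- stats::quantile(ysub, 0.1, names = FALSE)
    start <- list(b = b0)
    form <- "b"
    for (j in seq_len(k)) {
      A0 <- max(y[which.min(abs(x - seeds[ii[j]]))] - b0, 3 * noise, 1e-6)
      start[[paste0("A", j)]] <- A0
      start[[paste0("mu", j)]] <- seeds[ii[j]]
      start[[paste0("s", j)]] <- initSigmaUm
      form <- paste0(form, sprintf(" + A%d*exp(-(xs-mu%d)^2/(2*s%d^2))", j, j, j))
    }
    fml <- stats::as.formula(paste("ysub ~", form))
    fit <- tryCatch(
      minpack.lm::nlsLM(fml, start = start,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    winHalf <- (max(xs) - min(xs)) / 2
    if (is.null(fit)) {
      for (j in seq_len(k))
        out[[length(out) + 1L]] <- data.frame(
          mu = seeds[ii[j]], sigma = initSigmaUm, amplitude = NA_real_,
          area = NA_real_, se_mu = NA_real_, baseline = b0,
          converged = FALSE, broad = FALSE)
      warning("band fit did not converge; seed values returned flagged")
      next
    }
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) stats::setNames(rep(NA_real_, length(cf)), names(cf)))
    for (j in seq_len(k)) {
      A <- cf[[paste0("A", j)]]; mu <- cf[[paste0("mu", j)]]
      s <- abs(cf[[paste0("s", j)]])
      if (A < 2 * noise || s > winHalf) {
        warning(sprintf("band near %.1f um rejected (amplitude %.2g, sigma %.2g)",
                        mu, A, s))
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        mu = mu, sigma = s, amplitude = A, area = A * s * sqrt(2 * pi),
        se_mu = unname(se[paste0("mu", j)]), baseline = unname(cf[["b"]]),
        converged = TRUE, broad = FALSE)
    }
  }
  bands <- do.call(rbind, out)
  if (is.null(bands) || !nrow(bands)) return(.emptyBands())
  bands <- bands[order(bands$mu), , drop = FALSE]
  med <- stats::median(bands$sigma[bands$converged], na.rm = TRUE)
  bands$broad <- is.finite(bands$sigma) & bands$sigma > broadFactor * med
  rownames(bands) <- NULL
  bands
}

.emptyBands <- function() {
  data.frame(mu = numeric(0), sigma = numeric(0), amplitude = numeric(0),
             area = numeric(0), se_mu = numeric(0), baseline = numeric(0),
             converged = logical(0), broad = logical(0))
}
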
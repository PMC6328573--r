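# Pipeline orchestration: extract -> subtract -> detect -> fit ->
# calibrate -> size -> quantify -> repeat-call, plus the CLI-facing
# cmdSimulate / cmdAnalyze / cmdConvert / cmdQuant entry points.

#' Default per-channel ROIs of an acquisition spec
#'
#' @param acq an [AcquisitionSpec-class].
#' @return list(reference, sample), each list(rows, cols).
#' @export
defaultRois <- function(acq) {
  list(reference = list(rows = as.integer(acq@referenceRows),
                        cols = c(1L, acq@imageShape[2])),
       sample    = list(rows = as.integer(acq@sampleRows),
                        cols = c(1L, acq@imageShape[2])))
}

#' Analyze one dual-channel micrograph
#'
#' Runs the full analysis on a counts matrix: per-channel profile
#' extraction, background subtraction (robust linear model fit unless a
#' reference frame is supplied), peak detection, Gaussian band fitting,
#' ladder calibration, sample-band sizing, concentration estimation and —
#' when a locus is named — repeat calling with heterogeneity scoring
#' against the nearest ladder band.
#'
#' @param image counts matrix (dual-channel frame).
#' @param opts list of analysis options:
#'   \describe{
#'     \item{pixel_size_um, constriction_col}{geometry (as in the
#'       acquisition spec).}
#'     \item{rois}{list(reference, sample) ROIs; see [defaultRois()].}
#'     \item{ladder_sizes, ladder_conc}{declared ladder (bp, pg/uL).}
#'     \item{locus}{locus name or NA.}
#'     \item{dilution}{dilution factor for undiluted concentrations.}
#'     \item{min_snr, min_separation_um}{detection thresholds.}
#'     \item{mode}{calibration interpolation mode.}
#'     \item{registration_sd}{inter-channel term of the size uncertainty
#'       (um).}
#'   }
#' @param referenceImage optional t=0 frame for reference-mode background
#'   subtraction.
#' @return list(report = per-band data.frame, ladder = fitted ladder table
#'   with sizes, calibration, qc = list(ladder_n, extrapolated_n, broad_n,
#'   calibration_ok), profiles).
#' @export
analyzeFrame <- function(image, opts, referenceImage = NULL) {
  o <- opts
  prof <- list()
  for (ch in c("reference", "sample")) {
    p <- extractProfile(image, o$rois[[ch]], o$pixel_size_um,
                        o$constriction_col, channel = ch)
    ref <- NULL
    if (!is.null(referenceImage))
      ref <- extractProfile(referenceImage, o$rois[[ch]], o$pixel_size_um,
                            o$constriction_col, channel = ch)
    prof[[ch]] <- subtractBackground(p, reference = ref, polyOrder = 1)
  }
  minSnr <- if (is.null(o$min_snr)) 5 else o$min_snr
  minSep <- if (is.null(o$min_separation_um)) 20 else o$min_separation_um
  regSd <- if (is.null(o$registration_sd)) 2 else o$registration_sd
  mode <- if (is.null(o$mode)) "linear" else o$mode

  ladderBands <- fitBands(prof$reference, detectPeaks(prof$reference, minSnr, minSep))
  sampleSeeds <- detectPeaks(prof$sample, minSnr, minSep)
  sampleBands <- if (length(sampleSeeds)) fitBands(prof$sample, sampleSeeds)
                 else .emptyBands()

  cal <- NULL; calOk <- FALSE
  res <- tryCatch({
    cal <- buildCalibration(ladderBands, o$ladder_sizes, mode = mode)
    calOk <- TRUE
    NULL
  }, error = function(e) conditionMessage(e))
  if (!calOk)
    return(list(report = NULL, ladder = ladderBands, calibration = NULL,
                qc = list(ladder_n = nrow(ladderBands),
                          calibration_ok = FALSE, error = res),
                profiles = prof))

  ladderSized <- sizeBands(cal, ladderBands, registrationSd = regSd)
  report <- sizeBands(cal, sampleBands, registrationSd = regSd)
  if (nrow(report)) {
    # broadness is judged against the sharp ladder, not the sample's own
    # width distribution (a two-allele sample may have no sharp majority)
    report$broad <- report$sigma > 1.8 * stats::median(ladderBands$sigma)
    conc <- conc_und <- refIdx <- hetRatio <- rep(NA_real_, nrow(report))
    for (i in seq_len(nrow(report))) {
      cc <- estimateConcentration(report[i, ], ladderBands, o$ladder_conc,
                                  dilution = if (is.null(o$dilution)) 1 else o$dilution)
      conc[i] <- cc$concentration
      conc_und[i] <- cc$undiluted_ng_per_uL
      refIdx[i] <- cc$reference_index
      hetRatio[i] <- heterogeneityScore(report[i, ], ladderBands[cc$reference_index, ],
                                        report$local_slope[i])$width_ratio
    }
    report$concentration_pg_per_uL <- conc
    report$undiluted_ng_per_uL <- conc_und
    report$reference_band <- refIdx
    report$width_ratio <- hetRatio
    if (!is.null(o$locus) && !is.na(o$locus)) {
      loc <- getLocus(o$locus)
      rc <- repeatCount(loc, report$size_bp, report$se_bp)
      report$repeats <- rc$repeats
      report$repeat_se <- rc$repeat_se
      report$locus <- loc@name
    }
  }
  list(report = report, ladder = ladderSized, calibration = cal,
       qc = list(ladder_n = nrow(ladderBands),
                 sample_n = nrow(report),
                 extrapolated_n = sum(report$extrapolated),
                 broad_n = sum(report$broad),
                 calibration_ok = TRUE),
       profiles = prof)
}

# Resolve a scenario name into analysis options matching its simulator
# geometry and declared ladder.
.scenarioOpts <- function(sc) {
  list(pixel_size_um = sc$acq@pixelSizeUm,
       constriction_col = sc$acq@constrictionCol,
       rois = defaultRois(sc$acq),
       ladder_sizes = ladderSizes(sc$ladder_kind),
       ladder_conc = sc$ladder_conc,
       locus = sc$locus,
       dilution = sc$dilution)
}

#' Simulate a scenario and write its artifacts
#'
#' Writes a 16-bit TIFF (multi-page when the scenario defines several frame
#' times), the ground-truth CSV, and an echo of the resolved configuration
#' (YAML, stamped with the tool version and a config hash). Deterministic
#' for a fixed seed.
#'
#' @param scenario scenario name ([listScenarios()]).
#' @param seed integer seed.
#' @param out output directory (created if missing).
#' @return list of written paths, invisibly.
#' @export
cmdSimulate <- function(scenario, seed = 1L, out = ".") {
  sc <- simScenario(scenario)
  if (!dir.exists(out)) {
    dir.create(out, recursive = TRUE)
    message("created output directory ", out)
  }
  ser <- renderSeries(sc$truths, sc$model, sc$acq, seed = seed)
  tifPath <- file.path(out, paste0(scenario, ".tif"))
  writeMicrograph(ser$images, tifPath)
  truth <- ser$truths[[length(ser$truths)]]
  truthPath <- file.path(out, paste0(scenario, "_truth.csv"))
  utils::write.csv(truth, truthPath, row.names = FALSE)
  cfg <- c(.scenarioOpts(sc),
           list(scenario = scenario, seed = as.integer(seed),
                frame_times_s = sc$acq@frameTimes, tool_version = .toolVersion()))
  cfg$config_hash <- .configHash(cfg)
  cfgPath <- file.path(out, paste0(scenario, "_config.yaml"))
  yaml::write_yaml(cfg, cfgPath)
  invisible(list(tiff = tifPath, truth = truthPath, config = cfgPath))
}

#' Analyze a simulated scenario or an image file
#'
#' Config may name a registered scenario (simulated in memory) or a TIFF
#' path plus explicit analysis options. Writes report.csv and summary.json
#' into `out`. The exit contract for the CLI wrapper: calibration failure
#' is the only fatal condition.
#'
#' @param config list (or YAML path) with either `scenario` (+ `seed`) or
#'   `image` plus the [analyzeFrame()] options.
#' @param out output directory.
#' @return the [analyzeFrame()] result, invisibly.
#' @export
cmdAnalyze <- function(config, out = ".") {
  if (is.character(config)) config <- readRunConfig(config)
  if (!is.null(config$scenario) && !is.null(config$image))
    stop("config must name exactly one of scenario or image")
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  if (!is.null(config$scenario)) {
    sc <- simScenario(config$scenario)
    seed <- if (is.null(config$seed)) 1L else config$seed
    lastT <- sc$acq@frameTimes[length(sc$acq@frameTimes)]
    fr <- renderFrame(sc$truths, sc$model, sc$acq, lastT, seed = seed)
    image <- fr$image
    opts <- .scenarioOpts(sc)
  } else {
    image <- readMicrograph(config$image)
    if (is.list(image)) image <- image[[length(image)]]
    opts <- config
    if (!is.null(config$ladder_csv)) {
      lad <- readLadderCsv(config$ladder_csv)
      opts$ladder_sizes <- lad$size_bp
      opts$ladder_conc <- lad$concentration_pg_per_uL
    }
  }
  res <- analyzeFrame(image, opts)
  if (!is.null(res$report)) {
    utils::write.csv(res$report, file.path(out, "report.csv"), row.names = FALSE)
  }
  summ <- list(tool_version = .toolVersion(),
               config_hash = .configHash(config),
               seed = config$seed,
               qc = res$qc,
               sample_bands = if (is.null(res$report)) list() else res$report)
  jsonlite::write_json(summ, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!isTRUE(res$qc$calibration_ok))
    stop("calibration failed: ", res$qc$error)
  invisible(res)
}

#' Convert amplicon sizes to repeat counts (calculator)
#'
#' @param locus locus name.
#' @param sizes amplicon sizes (bp).
#' @return data.frame(size_bp, repeats).
#' @export
cmdConvert <- function(locus, sizes) {
  loc <- getLocus(locus)
  rc <- repeatCount(loc, sizes)
  data.frame(size_bp = sizes, repeats = rc$repeats)
}

#' Per-cycle amplification factors from a concentration series (calculator)
#'
#' @param conc concentrations, one per cycle number.
#' @param cycles cycle numbers, ascending.
#' @return data.frame of consecutive-pair per-cycle factors.
#' @export
cmdQuant <- function(conc, cycles) {
  stopifnot(length(conc) == length(cycles), length(conc) >= 2)
  n <- length(conc)
  data.frame(from_cycle = cycles[-n], to_cycle = cycles[-1],
             per_cycle_factor = vapply(seq_len(n - 1), function(i)
               amplificationFactor(conc[i], cycles[i], conc[i + 1], cycles[i + 1]),
               numeric(1)))
}
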
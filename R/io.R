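# Readers/writers: 16-bit TIFF micrographs, ladder CSVs, YAML run configs.

#' Write a micrograph (or time series) as 16-bit grayscale TIFF
#'
#' @param images a counts matrix, or a list of matrices for a multi-page
#'   time series.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMicrograph <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  imgs <- lapply(images, function(m) {
    m <- pmin(pmax(round(m), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Read a 16-bit grayscale TIFF micrograph
#'
#' @param path TIFF file.
#' @return a counts matrix, or a list of matrices for multi-page files.
#' @export
readMicrograph <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  imgs <- lapply(imgs, function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1]   # tolerate gray stored with channels
    round(m * 65535)
  })
  if (length(imgs) == 1L) imgs[[1]] else imgs
}

#' Read a ladder definition CSV
#'
#' Expected columns: size_bp, concentration_pg_per_uL.
#'
#' @param path CSV file.
#' @return data.frame sorted by size.
#' @export
readLadderCsv <- function(path) {
  lad <- utils::read.csv(path)
  if (!all(c("size_bp", "concentration_pg_per_uL") %in% names(lad)))
    stop("ladder CSV must have columns size_bp, concentration_pg_per_uL")
  lad[order(lad$size_bp), , drop = FALSE]
}

#' Export a profile as a 2-column CSV
#'
#' @param profile a [Profile-class].
#' @param path CSV file.
#' @return `path`, invisibly.
#' @export
writeProfileCsv <- function(profile, path) {
  utils::write.csv(data.frame(position_um = profile@positions,
                              intensity = profile@intensities),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return named list.
#' @export
readRunConfig <- function(path) yaml::read_yaml(path)

# Short stable hash of a resolved config (FNV-1a over its YAML text),
# stamped into every output for provenance.
.configHash <- function(cfg) {
  txt <- yaml::as.yaml(cfg)
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.toolVersion <- function() as.character(utils::packageVersion("repeatsizer"))
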
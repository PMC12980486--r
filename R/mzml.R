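#' Read a centroided mzML file into an LC-HRMS sample
#'
#' Reads all MS1 spectra of an mzML file and assembles the union of their
#' (scan RT, m/z, intensity) centroids into a single point cloud. MS2+
#' spectra (e.g. from autoMSMS acquisitions) are skipped: the classifier
#' consumes one MS1 intensity map per run. Zero-intensity entries are
#' dropped. Retention times are stored in seconds (the backend converts
#' minute-based files).
#'
#' @param path path to a readable mzML file.
#' @param sample_id identifier for the returned sample; defaults to the
#'   file name without extension.
#' @param label,batch_id optional metadata attached to the sample.
#' @return An [lcms_sample()] with `acquisition_span` equal to the range of
#'   MS1 scan retention times.
#' @export
read_mzml <- function(path, sample_id = NULL, label = NA_character_,
                      batch_id = NA_character_) {
  if (!file.exists(path)) {
    abort_lcms(sprintf("mzML file not found: %s", path), "lcmsnet_io_error")
  }
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  ms1 <- which(hdr$msLevel == 1L)
  if (!length(ms1)) {
    abort_lcms(sprintf("no MS1 spectra in %s", path), "lcmsnet_empty_sample_error")
  }
  pk <- mzR::peaks(ms, ms1)
  if (is.matrix(pk)) pk <- list(pk)
  rts <- hdr$retentionTime[ms1]
  n <- vapply(pk, nrow, integer(1))
  points <- data.frame(
    rt = rep(rts, n),
    mz = unlist(lapply(pk, function(m) m[, 1]), use.names = FALSE),
    intensity = unlist(lapply(pk, function(m) m[, 2]), use.names = FALSE)
  )
  points <- points[points$intensity > 0, , drop = FALSE]
  lcms_sample(points, sample_id = sample_id, label = label, batch_id = batch_id,
              acquisition_span = range(rts))
}

#' Write an LC-HRMS sample to a centroided mzML file
#'
#' Points sharing the same retention time are grouped into one MS1 scan
#' with m/z values ascending, and the scans are written as a valid
#' centroided mzML file.
#'
#' @param sample an [lcms_sample()] with at least one point.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(sample, path) {
  validate_sample(sample)
  p <- sample$points
  if (!nrow(p)) {
    abort_lcms("cannot write an empty sample to mzML", "lcmsnet_parameter_error")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort_lcms(sprintf("output directory does not exist: %s", dir), "lcmsnet_io_error")
  }
  scan_rt <- sort(unique(p$rt))
  grp <- match(p$rt, scan_rt)
  pk <- lapply(seq_along(scan_rt), function(i) {
    sub <- p[grp == i, , drop = FALSE]
    cbind(mz = sub$mz, intensity = sub$intensity)
  })
  ns <- length(scan_rt)
  npk <- vapply(pk, nrow, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(ns), acquisitionNum = seq_len(ns),
    msLevel = rep(1L, ns), polarity = rep(1L, ns), peaksCount = npk,
    totIonCurrent = vapply(pk, function(m) sum(m[, 2]), numeric(1)),
    retentionTime = scan_rt,
    basePeakMZ = vapply(pk, function(m) m[which.max(m[, 2]), 1], numeric(1)),
    basePeakIntensity = vapply(pk, function(m) max(m[, 2]), numeric(1)),
    collisionEnergy = rep(NA_real_, ns), ionisationEnergy = rep(0, ns),
    lowMZ = vapply(pk, function(m) min(m[, 1]), numeric(1)),
    highMZ = vapply(pk, function(m) max(m[, 1]), numeric(1)),
    precursorScanNum = rep(0L, ns), precursorMZ = rep(0, ns),
    precursorCharge = rep(0L, ns), precursorIntensity = rep(0, ns),
    mergedScan = rep(0L, ns), mergedResultScanNum = rep(0L, ns),
    mergedResultStartScanNum = rep(0L, ns), mergedResultEndScanNum = rep(0L, ns),
    injectionTime = rep(0, ns), filterString = rep(NA_character_, ns),
    spectrumId = sprintf("scan=%d", seq_len(ns)),
    centroided = rep(TRUE, ns),
    ionMobilityDriftTime = rep(NA_real_, ns),
    isolationWindowTargetMZ = rep(NA_real_, ns),
    isolationWindowLowerOffset = rep(NA_real_, ns),
    isolationWindowUpperOffset = rep(NA_real_, ns),
    scanWindowLowerLimit = rep(NA_real_, ns),
    scanWindowUpperLimit = rep(NA_real_, ns),
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(object = pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}
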
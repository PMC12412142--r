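# Centroided LC-MS runs: mzML I/O, extracted ion chromatograms, apex picking.

.polarity_code <- c(NEG = 0L, POS = 1L)

new_sst_run <- function(spectra, polarity, source_id) {
  structure(list(spectra = spectra, polarity = polarity,
                 source_id = source_id),
            class = "sst_run")
}

#' @export
print.sst_run <- function(x, ...) {
  rts <- vapply(x$spectra, `[[`, numeric(1), "rt")
  cat(sprintf("<sst_run> %s: %d %s MS1 scans, rt %.2f-%.2f min\n",
              x$source_id, length(x$spectra), x$polarity,
              if (length(rts)) min(rts) else NA, if (length(rts)) max(rts) else NA))
  invisible(x)
}

#' Read a centroided LC-MS run from mzML
#'
#' Loads all MS1 centroid spectra of the requested polarity, ordered by
#' retention time. Profile-mode spectra are rejected: apex m/z reading
#' assumes centroided data. Retention times are converted to minutes.
#'
#' @param path Path to an mzML file.
#' @param polarity `"POS"` or `"NEG"`; only scans of this polarity are kept.
#' @return An object of class `sst_run`: a list with `spectra` (each a
#'   list with `rt` in minutes, `mz` ascending, `intensity`), `polarity`
#'   and `source_id`.
#' @export
read_run <- function(path, polarity = c("POS", "NEG")) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) stop("mzML file not found: ", path)
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) stop("malformed mzML file '", path,
                                          "': ", conditionMessage(e)))
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  keep <- which(hdr$msLevel == 1L & hdr$polarity == .polarity_code[[polarity]])
  if (!length(keep))
    stop("no MS1 spectra of polarity ", polarity, " in '", path, "'")
  if ("centroided" %in% names(hdr)) {
    cent <- hdr$centroided[keep]
    if (any(!is.na(cent) & !cent))
      stop("profile-mode spectra found in '", path,
           "'; only centroided MS1 data are supported")
    if (anyNA(cent))
      warning("centroiding status missing for some spectra in '", path,
              "'; assuming centroided")
  }
  keep <- keep[order(hdr$retentionTime[keep])]
  spectra <- lapply(keep, function(i) {
    pk <- mzR::peaks(ms, i)
    o <- order(pk[, 1])
    list(rt = hdr$retentionTime[i] / 60,
         mz = pk[o, 1], intensity = pk[o, 2])
  })
  new_sst_run(spectra, polarity, basename(path))
}

#' Write a run to mzML
#'
#' Serialises an `sst_run` as a centroided MS1 mzML file (PSI standard),
#' the inverse of [read_run()].
#'
#' @param run An `sst_run`.
#' @param path Output mzML path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  stopifnot(inherits(run, "sst_run"))
  n <- length(run$spectra)
  pks <- lapply(run$spectra, function(s)
    cbind(mz = s$mz, intensity = s$intensity))
  npk <- vapply(pks, nrow, integer(1))
  bp <- function(s, what) {
    if (!length(s$intensity)) return(0)
    i <- which.max(s$intensity)
    if (what == "mz") s$mz[i] else s$intensity[i]
  }
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = .polarity_code[[run$polarity]],
    peaksCount = npk,
    totIonCurrent = vapply(run$spectra, function(s) sum(s$intensity), numeric(1)),
    retentionTime = vapply(run$spectra, `[[`, numeric(1), "rt") * 60,
    basePeakMZ = vapply(run$spectra, bp, numeric(1), what = "mz"),
    basePeakIntensity = vapply(run$spectra, bp, numeric(1), what = "int"),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$spectra, function(s) if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(run$spectra, function(s) if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0,
    mergedScan = -1L, mergedResultScanNum = -1L,
    mergedResultStartScanNum = -1L, mergedResultEndScanNum = -1L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = 100, scanWindowUpperLimit = 1000,
    stringsAsFactors = FALSE)
  mzR::writeMSData(pks, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Extracted ion chromatogram
#'
#' For every MS1 scan (optionally restricted to an rt range), sums the
#' intensities of all centroids within `target_mz * (1 +/- tol_ppm * 1e-6)`
#' and records the m/z of the most intense centroid in the window.
#'
#' @param run An `sst_run`.
#' @param target_mz Target m/z in u.
#' @param tol_ppm Half-width of the extraction window in ppm (> 0).
#' @param rt_range Optional `c(min, max)` retention-time window in minutes.
#' @return A data frame of class `sst_eic` with columns `rt`, `intensity`,
#'   `best_mz` (NA when no centroid falls in the window), plus attributes
#'   `target_mz` and `tol_ppm`.
#' @export
extract_eic <- function(run, target_mz, tol_ppm = 10, rt_range = NULL) {
  stopifnot(inherits(run, "sst_run"), tol_ppm > 0, target_mz > 0)
  lo <- shift_mz(target_mz, -tol_ppm)
  hi <- shift_mz(target_mz, tol_ppm)
  spectra <- run$spectra
  if (!is.null(rt_range)) {
    rts <- vapply(spectra, `[[`, numeric(1), "rt")
    spectra <- spectra[rts >= rt_range[1] & rts <= rt_range[2]]
  }
  pts <- lapply(spectra, function(s) {
    in_win <- s$mz >= lo & s$mz <= hi
    if (any(in_win)) {
      ints <- s$intensity[in_win]
      best <- s$mz[in_win][which.max(ints)]
      c(s$rt, sum(ints), best)
    } else {
      c(s$rt, 0, NA_real_)
    }
  })
  out <- as.data.frame(do.call(rbind, pts))
  if (!nrow(out)) out <- data.frame(V1 = numeric(), V2 = numeric(), V3 = numeric())
  names(out) <- c("rt", "intensity", "best_mz")
  structure(out, target_mz = target_mz, tol_ppm = tol_ppm,
            class = c("sst_eic", "data.frame"))
}

#' Apex of an extracted ion chromatogram
#'
#' The apex scan is the scan with maximal summed window intensity (ties
#' broken toward the earliest retention time); the apex m/z is the most
#' intense centroid of that scan. The peak is reported as not detected
#' when the maximal intensity falls below `min_intensity`.
#'
#' @param eic An `sst_eic`.
#' @param min_intensity Detection floor in counts.
#' @return A list with `detected`, `apex_rt`, `apex_mz`, `apex_intensity`.
#' @export
find_apex <- function(eic, min_intensity = 1e4) {
  stopifnot(inherits(eic, "sst_eic"))
  if (!nrow(eic))
    return(list(detected = FALSE, apex_rt = NA_real_, apex_mz = NA_real_,
                apex_intensity = NA_real_))
  i <- which.max(eic$intensity)  # which.max takes the first maximum: earliest rt
  if (eic$intensity[i] < min_intensity || is.na(eic$best_mz[i]))
    return(list(detected = FALSE, apex_rt = NA_real_, apex_mz = NA_real_,
                apex_intensity = NA_real_))
  list(detected = TRUE, apex_rt = eic$rt[i], apex_mz = eic$best_mz[i],
       apex_intensity = eic$intensity[i])
}

# Intensity-weighted apex m/z: weighted mean of per-scan best_mz over the
# scans within half-max of the apex. Offered as an alternative to the
# plain apex read-off; less sensitive to single-scan jitter.
weighted_apex_mz <- function(eic, apex_index) {
  half <- eic$intensity[apex_index] / 2
  sel <- which(eic$intensity >= half & !is.na(eic$best_mz))
  sum(eic$best_mz[sel] * eic$intensity[sel]) / sum(eic$intensity[sel])
}

#' Measure all panel compounds in a run
#'
#' For each panel compound whose polarity matches the run, extracts its
#' EIC at the expected m/z, locates the apex, and scores the signed ppm
#' mass error of the apex m/z against the expected m/z. Compounds of the
#' other polarity are omitted from the output; compounds with no peak
#' above `min_intensity` are returned with `detected = FALSE` and no
#' error value.
#'
#' @param run An `sst_run`.
#' @param panel An `sst_panel`; defaults to the bundled 13-compound panel.
#' @param tol_ppm EIC extraction half-width in ppm. Deliberately wider
#'   (default 10) than the 3 ppm acceptance threshold so a drifted-but-
#'   failing peak is still measured rather than silently missed.
#' @param min_intensity Apex detection floor in counts.
#' @param apex_mode `"centroid"` reads the most intense centroid of the
#'   apex scan; `"weighted"` uses an intensity-weighted mean across the
#'   upper half of the peak.
#' @param rt_ranges Optional named list of `c(min, max)` rt windows (in
#'   minutes) per compound; by default each compound is searched across
#'   the whole run, since SST chromatography is deliberately generic.
#' @return A data frame of class `sst_measurements` with one row per
#'   matching-polarity compound: `compound`, `expected_mz`, `apex_rt`,
#'   `apex_mz`, `apex_intensity`, `ppm_error`, `detected`.
#' @export
measure_panel <- function(run, panel = default_panel(), tol_ppm = 10,
                          min_intensity = 1e4,
                          apex_mode = c("centroid", "weighted"),
                          rt_ranges = NULL) {
  stopifnot(inherits(run, "sst_run"))
  apex_mode <- match.arg(apex_mode)
  sub <- panel[panel$polarity == run$polarity, , drop = FALSE]
  rows <- lapply(seq_len(nrow(sub)), function(i) {
    target <- sub$expected_mz[i]
    eic <- extract_eic(run, target, tol_ppm,
                       rt_range = rt_ranges[[sub$name[i]]])
    apex <- find_apex(eic, min_intensity)
    mz <- apex$apex_mz
    if (apex$detected && apex_mode == "weighted")
      mz <- weighted_apex_mz(eic, which.max(eic$intensity))
    data.frame(
      compound = sub$name[i], expected_mz = target,
      apex_rt = apex$apex_rt, apex_mz = mz,
      apex_intensity = apex$apex_intensity,
      ppm_error = if (apex$detected) ppm_error(mz, target) else NA_real_,
      detected = apex$detected, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  structure(out, polarity = run$polarity, source_id = run$source_id,
            class = c("sst_measurements", "data.frame"))
}

#' Bundle measurements into an SST injection result
#'
#' Converts the per-compound measurements of one SST injection into the
#' replicate-level record consumed by [evaluate_sst()]: a named vector of
#' signed ppm errors for the detected compounds, plus injection metadata.
#'
#' @param measurements An `sst_measurements` data frame.
#' @param injection_id Identifier for the injection (defaults to the
#'   source file name).
#' @param phase `"PRE"` (before the sample batch) or `"POST"` (after).
#' @param timestamp Optional acquisition time (`POSIXct` or string).
#' @return An object of class `sst_injection`.
#' @export
as_injection_result <- function(measurements, injection_id = NULL,
                                phase = c("PRE", "POST"), timestamp = NULL) {
  stopifnot(inherits(measurements, "sst_measurements"))
  phase <- match.arg(phase)
  det <- measurements[measurements$detected, , drop = FALSE]
  errors <- stats::setNames(det$ppm_error, det$compound)
  injection_result(errors,
                   injection_id = injection_id %||% attr(measurements, "source_id"),
                   polarity = attr(measurements, "polarity"),
                   phase = phase, timestamp = timestamp)
}

#' Construct an SST injection result
#'
#' @param errors Named numeric vector of signed ppm errors, one element
#'   per detected compound.
#' @param injection_id Identifier string.
#' @param polarity `"POS"` or `"NEG"`.
#' @param phase `"PRE"` or `"POST"`.
#' @param timestamp Optional acquisition time.
#' @return An object of class `sst_injection`.
#' @export
injection_result <- function(errors, injection_id, polarity = c("POS", "NEG"),
                             phase = c("PRE", "POST"), timestamp = NULL) {
  polarity <- match.arg(polarity)
  phase <- match.arg(phase)
  if (length(errors) && is.null(names(errors)))
    stop("errors must be a named vector (compound -> ppm error)")
  structure(list(injection_id = as.character(injection_id),
                 timestamp = timestamp, polarity = polarity, phase = phase,
                 errors = errors),
            class = "sst_injection")
}

#' @export
print.sst_injection <- function(x, ...) {
  cat(sprintf("<sst_injection> %s [%s/%s]: %d compounds\n",
              x$injection_id, x$polarity, x$phase, length(x$errors)))
  if (length(x$errors)) print(round(x$errors, 3))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
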
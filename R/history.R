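# Longitudinal SST histories: CSV persistence and per-mass summaries.

.history_cols <- c("batch_id", "date", "polarity", "phase", "replicate",
                   "n_batch_injections", "cal_type", "cal_rms_ppm",
                   "days_since_cal", "compound", "error_ppm")

.history_key <- c("batch_id", "phase", "polarity", "replicate", "compound")

validate_history <- function(df) {
  missing <- setdiff(.history_cols, names(df))
  if (length(missing))
    stop("history lacks required column(s): ", paste(missing, collapse = ", "))
  df <- df[, .history_cols, drop = FALSE]
  df$batch_id <- as.character(df$batch_id)
  df$date <- as.character(df$date)
  df$compound <- as.character(df$compound)
  df$cal_type <- as.character(df$cal_type)
  df$replicate <- as.integer(df$replicate)
  df$n_batch_injections <- as.integer(df$n_batch_injections)
  df$cal_rms_ppm <- as.numeric(df$cal_rms_ppm)
  df$days_since_cal <- as.numeric(df$days_since_cal)
  df$error_ppm <- as.numeric(df$error_ppm)
  if (nrow(df)) {
    if (!all(df$polarity %in% c("POS", "NEG")))
      stop("polarity must be POS or NEG")
    if (!all(df$phase %in% c("PRE", "POST")))
      stop("phase must be PRE or POST")
    if (!all(df$cal_type %in% c("CALMIX", "CALMIX_FLEXMIX")))
      stop("cal_type must be CALMIX or CALMIX_FLEXMIX")
    if (any(df$n_batch_injections < 0, na.rm = TRUE))
      stop("n_batch_injections must be >= 0")
    if (any(df$days_since_cal < 0, na.rm = TRUE))
      stop("days_since_cal must be >= 0")
    key <- do.call(paste, c(df[.history_key], sep = "\r"))
    if (anyDuplicated(key))
      stop("duplicate (batch_id, phase, polarity, replicate, compound) record(s), e.g. ",
           gsub("\r", "/", key[duplicated(key)][1]))
  }
  rownames(df) <- NULL
  structure(df, class = c("sst_history", "data.frame"))
}

#' Load or save a longitudinal SST history
#'
#' The on-disk format is long-form CSV with one row per compound per
#' replicate injection: `batch_id, date (ISO-8601), polarity, phase,
#' replicate, n_batch_injections, cal_type (CALMIX | CALMIX_FLEXMIX),
#' cal_rms_ppm, days_since_cal, compound, error_ppm`. Save and load
#' round-trip exactly.
#'
#' @param path CSV file path.
#' @return `load_history()` returns an `sst_history` data frame;
#'   `save_history()` returns `path` invisibly.
#' @export
load_history <- function(path) {
  if (!file.exists(path)) stop("history file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(batch_id = "character",
                                       date = "character"))
  validate_history(df)
}

#' @rdname load_history
#' @param history An `sst_history`.
#' @export
save_history <- function(history, path) {
  stopifnot(inherits(history, "sst_history"))
  utils::write.csv(history, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Append records to a history
#'
#' @param history An `sst_history` (may be empty, see [empty_history()]).
#' @param record A data frame of new rows in the history schema (e.g. one
#'   injection's compound errors).
#' @return The extended `sst_history`; duplicate keys are an error.
#' @export
append_record <- function(history, record) {
  stopifnot(inherits(history, "sst_history"))
  record <- as.data.frame(record)
  missing <- setdiff(.history_cols, names(record))
  if (length(missing))
    stop("record lacks required column(s): ", paste(missing, collapse = ", "))
  validate_history(rbind(as.data.frame(history),
                         record[, .history_cols, drop = FALSE]))
}

#' An empty SST history
#' @return An `sst_history` with zero records.
#' @export
empty_history <- function() {
  df <- as.data.frame(stats::setNames(
    list(character(), character(), character(), character(), integer(),
         integer(), character(), numeric(), numeric(), character(), numeric()),
    .history_cols), stringsAsFactors = FALSE)
  validate_history(df)
}

#' Rows of injection results in history-schema form
#'
#' Helper to turn one injection's errors into history rows ready for
#' [append_record()].
#'
#' @param injection An `sst_injection`.
#' @param batch_id,date Batch identifier and ISO date.
#' @param replicate Replicate index within the phase (1-based).
#' @param n_batch_injections Number of real-sample injections in the batch.
#' @param cal_type `"CALMIX"` or `"CALMIX_FLEXMIX"`.
#' @param cal_rms_ppm Calibration quality (rms ppm over calibrant masses).
#' @param days_since_cal Days since the last calibration.
#' @return A data frame in the history schema.
#' @export
history_rows <- function(injection, batch_id, date, replicate,
                         n_batch_injections, cal_type, cal_rms_ppm,
                         days_since_cal) {
  stopifnot(inherits(injection, "sst_injection"))
  data.frame(batch_id = as.character(batch_id), date = as.character(date),
             polarity = injection$polarity, phase = injection$phase,
             replicate = as.integer(replicate),
             n_batch_injections = as.integer(n_batch_injections),
             cal_type = cal_type, cal_rms_ppm = cal_rms_ppm,
             days_since_cal = days_since_cal,
             compound = names(injection$errors),
             error_ppm = unname(injection$errors),
             stringsAsFactors = FALSE)
}

#' Batch length in hours
#'
#' Converts real-sample injection counts to batch duration using the
#' fixed nominal injection length (20 min by default).
#'
#' @param n_batch_injections Injection count(s).
#' @param minutes_per_injection Nominal minutes per injection.
#' @return Hours.
#' @export
batch_hours <- function(n_batch_injections, minutes_per_injection = 20) {
  n_batch_injections * minutes_per_injection / 60
}

#' Calibration-quality flag
#'
#' `"GOOD"` when the calibration rms error is at or below the threshold
#' (0.3 ppm by default), else `"POOR"`.
#'
#' @param cal_rms_ppm Calibration rms error(s), ppm.
#' @param threshold Quality threshold, rms ppm.
#' @return Character vector of `"GOOD"`/`"POOR"`.
#' @export
cal_quality_flag <- function(cal_rms_ppm, threshold = 0.3) {
  ifelse(cal_rms_ppm <= threshold, "GOOD", "POOR")
}

#' Per-mass history summary
#'
#' Summarises mass errors over a history for one polarity, retaining the
#' first `k_injections` replicates (the lowest replicate indices) of each
#' batch and phase -- the device used to compare full five-injection SSTs
#' with a reduced two-injection protocol. Reports the per-compound mean
#' and sample standard deviation over all retained replicate errors, and
#' a polarity-level aggregate: the mean and standard deviation across the
#' per-compound means.
#'
#' @param history An `sst_history`.
#' @param k_injections Number of leading replicates to keep (2-5).
#' @param polarity `"POS"` or `"NEG"`.
#' @return A list of class `sst_history_summary`: `per_mass` (data frame
#'   `compound`, `n`, `mean_error`, `sd_error`), `aggregate`
#'   (`mean_of_means`, `sd_of_means`), `k_injections`, `polarity`,
#'   `n_records`.
#' @export
summarize_history <- function(history, k_injections = 5,
                              polarity = c("POS", "NEG")) {
  stopifnot(inherits(history, "sst_history"))
  polarity <- match.arg(polarity)
  if (!(k_injections %in% 2:5))
    stop("k_injections must be between 2 and 5")
  d <- history[history$polarity == polarity, , drop = FALSE]
  if (!nrow(d)) stop("history has no ", polarity, " records")
  grp <- paste(d$batch_id, d$phase, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(d)), grp), function(idx) {
    reps <- sort(unique(d$replicate[idx]))
    idx[d$replicate[idx] %in% reps[seq_len(min(k_injections, length(reps)))]]
  }), use.names = FALSE)
  d <- d[keep, , drop = FALSE]
  per <- do.call(rbind, lapply(split(d$error_ppm, d$compound), function(v)
    data.frame(n = length(v), mean_error = mean(v),
               sd_error = if (length(v) >= 2) stats::sd(v) else NA_real_)))
  per <- data.frame(compound = rownames(per), per, row.names = NULL,
                    stringsAsFactors = FALSE)
  per <- per[order(per$compound), , drop = FALSE]
  structure(list(per_mass = per,
                 aggregate = c(mean_of_means = mean(per$mean_error),
                               sd_of_means = stats::sd(per$mean_error)),
                 k_injections = k_injections, polarity = polarity,
                 n_records = nrow(d)),
            class = "sst_history_summary")
}

#' @export
print.sst_history_summary <- function(x, ...) {
  cat(sprintf("<sst_history_summary> %s, first %d injections, %d records\n",
              x$polarity, x$k_injections, x$n_records))
  print.data.frame(transform(x$per_mass,
                             mean_error = round(mean_error, 3),
                             sd_error = round(sd_error, 3)),
                   row.names = FALSE)
  cat(sprintf("aggregate: mean of means %.3f ppm, sd of means %.3f ppm\n",
              x$aggregate[["mean_of_means"]], x$aggregate[["sd_of_means"]]))
  invisible(x)
}
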
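# Longitudinal report: per-mass summaries, model fits, drift table and
# batch-length advisories, written as CSV/JSON/Markdown artifacts.

#' Longitudinal SST report
#'
#' Compiles the standard history report into `out_dir`: per-mass
#' mean/sd summaries for the full (k = 5) and reduced (k = 2) replicate
#' protocols, per-compound error-model fits, the pooled calibration-effect
#' model, the pre/post drift table with per-stratum trends, and
#' batch-length advisories. Files written: `summary_k5_<pol>.csv`,
#' `summary_k2_<pol>.csv`, `error_models_<pol>.json`,
#' `calibration_model_<pol>.json`, `drift.csv`, `drift_trends.csv`,
#' `advisories.md`, `report.json`.
#'
#' @param history An `sst_history` with at least one record.
#' @param out_dir Output directory (created if needed).
#' @param polarity Polarities to report; default both present in the data.
#' @param config An [sst_config()].
#' @return Invisibly, a named list of the report components.
#' @export
sst_report <- function(history, out_dir, polarity = NULL,
                       config = sst_config()) {
  stopifnot(inherits(history, "sst_history"))
  if (!nrow(history)) stop("empty history: nothing to report")
  if (is.null(polarity)) polarity <- intersect(c("POS", "NEG"),
                                               unique(history$polarity))
  if (!length(polarity) || !all(polarity %in% unique(history$polarity)))
    stop("history has no data for polarity ",
         paste(setdiff(polarity, unique(history$polarity)), collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  components <- list()
  for (pol in polarity) {
    for (k in c(5, 2)) {
      s <- summarize_history(history, k_injections = k, polarity = pol)
      utils::write.csv(s$per_mass,
                       file.path(out_dir, sprintf("summary_k%d_%s.csv", k, pol)),
                       row.names = FALSE)
      components[[sprintf("summary_k%d_%s", k, pol)]] <- s
    }
    compounds <- unique(history$compound[history$polarity == pol])
    fits <- list()
    for (cmp in compounds) {
      fits[[cmp]] <- tryCatch(
        fit_error_model(history, cmp, polarity = pol),
        error = function(e) conditionMessage(e))
    }
    fit_objs <- Filter(function(f) inherits(f, "sst_fit"), fits)
    writeLines(jsonlite::toJSON(
      lapply(fits, function(f) if (inherits(f, "sst_fit"))
        jsonlite::fromJSON(fit_json(f)) else list(error = f)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE),
      file.path(out_dir, sprintf("error_models_%s.json", pol)))
    components[[paste0("error_models_", pol)]] <- fit_objs
    cal <- tryCatch(
      fit_calibration_model(history, polarity = pol,
                            cal_rms_threshold = config$cal_rms_threshold),
      error = function(e) conditionMessage(e))
    if (inherits(cal, "sst_fit"))
      fit_json(cal, file.path(out_dir, sprintf("calibration_model_%s.json", pol)))
    components[[paste0("calibration_model_", pol)]] <- cal
  }

  drift <- tryCatch(drift_analysis(history,
                                   cal_rms_threshold = config$cal_rms_threshold,
                                   minutes_per_injection =
                                     config$minutes_per_injection),
                    error = function(e) NULL)
  if (!is.null(drift)) {
    utils::write.csv(drift$deltas, file.path(out_dir, "drift.csv"),
                     row.names = FALSE)
    utils::write.csv(drift$trends, file.path(out_dir, "drift_trends.csv"),
                     row.names = FALSE)
    components$drift <- drift
  }

  adv_lines <- c("# Batch-length advisories", "")
  per_batch <- unique(history[, c("batch_id", "n_batch_injections",
                                  "cal_rms_ppm")])
  for (i in seq_len(nrow(per_batch))) {
    adv <- batch_length_advisor(
      per_batch$n_batch_injections[i],
      minutes_per_injection = config$minutes_per_injection,
      cal_quality = cal_quality_flag(per_batch$cal_rms_ppm[i],
                                     config$cal_rms_threshold),
      max_batch_injections = config$max_batch_injections)
    if (length(adv))
      adv_lines <- c(adv_lines,
                     sprintf("* %s: %s", per_batch$batch_id[i],
                             paste(adv, collapse = "; ")))
  }
  if (length(adv_lines) == 2L) adv_lines <- c(adv_lines, "None.")
  writeLines(adv_lines, file.path(out_dir, "advisories.md"))

  summary_json <- list(
    n_records = nrow(history),
    polarities = polarity,
    n_batches = length(unique(history$batch_id)),
    aggregates = lapply(stats::setNames(polarity, polarity), function(pol)
      lapply(c(k5 = 5, k2 = 2), function(k) {
        s <- summarize_history(history, k, pol)
        as.list(s$aggregate)
      })))
  writeLines(jsonlite::toJSON(summary_json, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "report.json"))
  invisible(components)
}
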
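# Linear models for mass-accuracy drift and calibration effects, plus the
# pre/post drift analysis and batch-length advisories.

new_sst_fit <- function(lmfit, response, data) {
  s <- summary(lmfit)
  ct <- s$coefficients
  structure(list(terms = rownames(ct),
                 estimates = unname(ct[, "Estimate"]),
                 standard_errors = unname(ct[, "Std. Error"]),
                 t_values = unname(ct[, "t value"]),
                 p_values = unname(ct[, "Pr(>|t|)"]),
                 r_squared = s$r.squared,
                 n_obs = stats::nobs(lmfit),
                 response = response,
                 fit = lmfit),
            class = "sst_fit")
}

#' @export
print.sst_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<sst_fit> %s, n = %d, R^2 = %.4f\n", x$response, x$n_obs,
              x$r_squared))
  print(as.data.frame(x), digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.sst_fit <- function(x, ...) {
  data.frame(term = x$terms, estimate = x$estimates,
             std_error = x$standard_errors, t_value = x$t_values,
             p_value = x$p_values, stringsAsFactors = FALSE)
}

#' @export
coef.sst_fit <- function(object, ...) {
  stats::setNames(object$estimates, object$terms)
}

#' @export
summary.sst_fit <- function(object, ...) object

# Fail with the offending term names instead of silently dropping
# rank-deficient columns the way lm() does.
check_full_rank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("model matrix is rank deficient; collinear term(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(TRUE)
}

#' Mass-error drift model for one compound
#'
#' Ordinary least squares of the signed mass error of one compound on the
#' SST phase (POST = 1 for injections acquired after the sample batch),
#' the number of real-sample injections in the batch, and their
#' interaction:
#' `error ~ phase_post * n_batch_injections`.
#' The interaction term measures how much additional error each batch
#' injection contributes between the pre- and post-batch SSTs, i.e. the
#' within-batch drift rate. Replicate-level rows are the modelling unit.
#' P-values are unadjusted two-sided t tests.
#'
#' @param history An `sst_history`.
#' @param compound Compound name to model.
#' @param polarity Optional polarity filter (a compound normally ionises
#'   in one mode only, so this is rarely needed).
#' @param max_hours Optional batch-length cap in hours; implements the
#'   short-batch stratification (e.g. `max_hours = 33`, about 100
#'   injections at 20 min each).
#' @param minutes_per_injection Injection-to-hours conversion for
#'   `max_hours`.
#' @param min_obs Minimum observations required after filtering.
#' @return An object of class `sst_fit`.
#' @export
fit_error_model <- function(history, compound, polarity = NULL,
                            max_hours = NULL, minutes_per_injection = 20,
                            min_obs = 10L) {
  stopifnot(inherits(history, "sst_history"))
  d <- history[history$compound == compound, , drop = FALSE]
  if (!is.null(polarity)) d <- d[d$polarity == polarity, , drop = FALSE]
  if (!is.null(max_hours))
    d <- d[batch_hours(d$n_batch_injections, minutes_per_injection) < max_hours,
           , drop = FALSE]
  if (nrow(d) < min_obs)
    stop("only ", nrow(d), " observations for '", compound,
         "' after filtering (need >= ", min_obs, ")")
  dd <- data.frame(error_ppm = d$error_ppm,
                   phase_post = as.integer(d$phase == "POST"),
                   n_batch_injections = d$n_batch_injections)
  X <- stats::model.matrix(~ phase_post * n_batch_injections, dd)
  check_full_rank(X)
  fit <- stats::lm(error_ppm ~ phase_post * n_batch_injections, data = dd)
  new_sst_fit(fit, response = paste0("error_ppm[", compound, "]"), data = dd)
}

#' Calibration-effect model for absolute mass error
#'
#' Ordinary least squares of the absolute mass error on calibration
#' covariates:
#' `|error| ~ cal_type + cal_quality + days_since_cal +
#' days_since_cal:cal_quality`.
#' Calibration quality enters as the binary GOOD/POOR flag at the 0.3 ppm
#' rms threshold by default (`quality = "flag"`), or as the continuous rms
#' value (`quality = "continuous"`). The reference levels are a
#' CALMIX + FLEXMIX calibration of GOOD quality, so the `cal_type`
#' coefficient is the penalty of calibrating with CalMix alone, and the
#' interaction measures how much faster accuracy decays per day under a
#' poor calibration.
#'
#' Sparse strata can destabilise the fit; `exclusions` drops such rows
#' first. The default predicate excludes CalMix-only records with more
#' than `exclude_days` days since calibration (these long-interval
#' CalMix-only cases are typically too rare to support the interaction).
#'
#' @param history An `sst_history`.
#' @param compound Optional compound filter (default: all compounds pooled).
#' @param polarity Optional polarity filter.
#' @param phase Optional phase filter; fitting on `"PRE"` rows isolates
#'   the calibration state from within-batch drift, which accrues only in
#'   post-batch SSTs.
#' @param quality `"flag"` or `"continuous"`.
#' @param cal_rms_threshold GOOD/POOR threshold, rms ppm.
#' @param exclusions Predicate `function(d)` returning rows to drop, or
#'   NULL to keep everything.
#' @param exclude_days Day cutoff used by the default exclusion predicate.
#' @param min_obs Minimum observations required after filtering.
#' @return An object of class `sst_fit`.
#' @export
fit_calibration_model <- function(history, compound = NULL, polarity = NULL,
                                  phase = NULL,
                                  quality = c("flag", "continuous"),
                                  cal_rms_threshold = 0.3,
                                  exclusions = NULL, exclude_days = 7,
                                  min_obs = 10L) {
  stopifnot(inherits(history, "sst_history"))
  quality <- match.arg(quality)
  d <- history
  if (!is.null(compound)) d <- d[d$compound %in% compound, , drop = FALSE]
  if (!is.null(polarity)) d <- d[d$polarity == polarity, , drop = FALSE]
  if (!is.null(phase)) d <- d[d$phase %in% phase, , drop = FALSE]
  if (is.null(exclusions))
    exclusions <- function(d) d$cal_type == "CALMIX" &
      d$days_since_cal > exclude_days
  drop <- exclusions(d)
  if (any(drop))
    message("excluding ", sum(drop),
            " sparse-stratum record(s) (default: CALMIX with > ",
            exclude_days, " days since calibration)")
  d <- d[!drop, , drop = FALSE]
  if (nrow(d) < min_obs)
    stop("only ", nrow(d), " observations after filtering (need >= ",
         min_obs, ")")
  dd <- data.frame(
    abs_error = abs(d$error_ppm),
    cal_type = factor(d$cal_type, levels = c("CALMIX_FLEXMIX", "CALMIX")),
    days_since_cal = d$days_since_cal)
  dd$cal_quality <- if (quality == "flag")
    factor(cal_quality_flag(d$cal_rms_ppm, cal_rms_threshold),
           levels = c("GOOD", "POOR"))
  else d$cal_rms_ppm
  if (is.factor(dd$cal_type) && length(unique(dd$cal_type)) < 2L)
    stop("model matrix is rank deficient; collinear term(s): cal_type (single calibration type)")
  if (is.factor(dd$cal_quality) && length(unique(dd$cal_quality)) < 2L)
    stop("model matrix is rank deficient; collinear term(s): cal_quality (single quality stratum)")
  X <- stats::model.matrix(
    ~ cal_type + cal_quality + days_since_cal + days_since_cal:cal_quality, dd)
  check_full_rank(X)
  fit <- stats::lm(
    abs_error ~ cal_type + cal_quality + days_since_cal +
      days_since_cal:cal_quality, data = dd)
  new_sst_fit(fit, response = "abs(error_ppm)", data = dd)
}

#' Pre/post drift analysis
#'
#' For every batch and polarity with both PRE and POST SST records,
#' computes the drift `delta = mean(POST errors) - mean(PRE errors)`
#' together with the batch length in hours and the calibration-quality
#' stratum, then summarises the trend of delta against batch length in
#' each quality stratum with a straight-line fit. Batches missing a
#' phase are skipped with a warning.
#'
#' @param history An `sst_history`.
#' @param cal_rms_threshold GOOD/POOR threshold, rms ppm.
#' @param minutes_per_injection Injection-to-hours conversion.
#' @return A list of class `sst_drift` with `deltas` (per batch/polarity:
#'   `batch_id`, `polarity`, `n_batch_injections`, `batch_hours`,
#'   `cal_quality_flag`, `delta_ppm`) and `trends` (per polarity/stratum:
#'   slope of delta per hour, its p-value, n).
#' @export
drift_analysis <- function(history, cal_rms_threshold = 0.3,
                           minutes_per_injection = 20) {
  stopifnot(inherits(history, "sst_history"))
  if (!nrow(history)) stop("empty history")
  grp <- split(seq_len(nrow(history)),
               paste(history$batch_id, history$polarity, sep = "\r"))
  skipped <- character()
  rows <- list()
  for (g in names(grp)) {
    idx <- grp[[g]]
    d <- history[idx, , drop = FALSE]
    if (!all(c("PRE", "POST") %in% d$phase)) {
      skipped <- c(skipped, gsub("\r", "/", g))
      next
    }
    rows[[g]] <- data.frame(
      batch_id = d$batch_id[1], polarity = d$polarity[1],
      n_batch_injections = d$n_batch_injections[1],
      batch_hours = batch_hours(d$n_batch_injections[1], minutes_per_injection),
      cal_quality_flag = cal_quality_flag(d$cal_rms_ppm[1], cal_rms_threshold),
      delta_ppm = mean(d$error_ppm[d$phase == "POST"]) -
        mean(d$error_ppm[d$phase == "PRE"]),
      stringsAsFactors = FALSE)
  }
  if (length(skipped))
    warning("skipped ", length(skipped),
            " batch/polarity group(s) missing a phase: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ..." else "")
  if (!length(rows)) stop("no batch has both PRE and POST records")
  deltas <- do.call(rbind, rows)
  rownames(deltas) <- NULL
  trends <- do.call(rbind, lapply(
    split(deltas, paste(deltas$polarity, deltas$cal_quality_flag, sep = "\r")),
    function(d) {
      if (nrow(d) >= 3 && stats::var(d$batch_hours) > 0) {
        f <- stats::lm(delta_ppm ~ batch_hours, data = d)
        ct <- summary(f)$coefficients
        data.frame(polarity = d$polarity[1],
                   cal_quality_flag = d$cal_quality_flag[1],
                   slope_ppm_per_hour = ct["batch_hours", "Estimate"],
                   p_value = ct["batch_hours", "Pr(>|t|)"],
                   mean_delta_ppm = mean(d$delta_ppm), n = nrow(d),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(polarity = d$polarity[1],
                   cal_quality_flag = d$cal_quality_flag[1],
                   slope_ppm_per_hour = NA_real_, p_value = NA_real_,
                   mean_delta_ppm = mean(d$delta_ppm), n = nrow(d),
                   stringsAsFactors = FALSE)
      }
    }))
  rownames(trends) <- NULL
  structure(list(deltas = deltas, trends = trends), class = "sst_drift")
}

#' @export
print.sst_drift <- function(x, ...) {
  cat(sprintf("<sst_drift> %d batch/polarity deltas\n", nrow(x$deltas)))
  print.data.frame(transform(x$trends,
                             slope_ppm_per_hour = round(slope_ppm_per_hour, 4),
                             mean_delta_ppm = round(mean_delta_ppm, 3)),
                   row.names = FALSE)
  invisible(x)
}

#' Batch-length advisory
#'
#' Advises on planned batch length before acquisition. Warns when the
#' batch exceeds `max_batch_injections` real-sample injections (about
#' 33 h at 20 min per injection), past which mass-accuracy drift becomes
#' appreciable even under a good calibration, and adds a stronger caution
#' when the calibration quality is POOR and the batch exceeds about 20 h
#' (roughly 60 injections), where drift can set in earlier.
#'
#' @param n_batch_injections Planned number of real-sample injections.
#' @param minutes_per_injection Nominal minutes per injection.
#' @param cal_quality `"GOOD"` or `"POOR"`.
#' @param max_batch_injections Advisory injection limit.
#' @return Character vector of advisory messages (empty when none),
#'   class `sst_advice`.
#' @export
batch_length_advisor <- function(n_batch_injections,
                                 minutes_per_injection = 20,
                                 cal_quality = c("GOOD", "POOR"),
                                 max_batch_injections = 100) {
  stopifnot(n_batch_injections >= 0)
  cal_quality <- match.arg(cal_quality)
  hours <- batch_hours(n_batch_injections, minutes_per_injection)
  max_hours <- batch_hours(max_batch_injections, minutes_per_injection)
  msgs <- character()
  if (n_batch_injections > max_batch_injections || hours > max_hours)
    msgs <- c(msgs, sprintf(
      "batch of %d injections (%.1f h) exceeds the %d-injection (~%.0f h) limit; run an SST before continuing",
      n_batch_injections, hours, max_batch_injections, max_hours))
  if (cal_quality == "POOR" && hours >= 20)
    msgs <- c(msgs, sprintf(
      "calibration quality is POOR and the batch spans %.1f h; drift can begin to increase after ~20 h (~60 injections) under suboptimal calibration",
      hours))
  structure(msgs, class = "sst_advice")
}

#' @export
print.sst_advice <- function(x, ...) {
  if (!length(x)) cat("No batch-length advisories.\n")
  else for (m in x) cat(" !", m, "\n")
  invisible(x)
}

#' Serialise a model fit to JSON
#'
#' @param fit An `sst_fit`.
#' @param path Optional output file.
#' @return JSON text (invisibly when written to `path`).
#' @export
fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "sst_fit"))
  obj <- list(response = fit$response, terms = fit$terms,
              estimates = fit$estimates,
              standard_errors = fit$standard_errors,
              t_values = fit$t_values, p_values = fit$p_values,
              r_squared = fit$r_squared, n_obs = fit$n_obs)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
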
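# SST verdict logic: replicate summaries, threshold and bias criteria,
# and the 2/3/5-injection protocol.

check_same_batch <- function(results) {
  if (!length(results)) stop("no injection results supplied")
  if (!all(vapply(results, inherits, logical(1), "sst_injection")))
    stop("results must be a list of sst_injection objects")
  pol <- unique(vapply(results, `[[`, character(1), "polarity"))
  ph <- unique(vapply(results, `[[`, character(1), "phase"))
  if (length(pol) != 1L) stop("mixed polarities in one SST evaluation")
  if (length(ph) != 1L) stop("mixed phases in one SST evaluation")
  list(polarity = pol, phase = ph)
}

#' Per-compound replicate summary
#'
#' Arithmetic mean and sample standard deviation (n-1 denominator) of the
#' signed ppm error of each compound across replicate injections.
#'
#' @param results A list of `sst_injection` objects from the same
#'   polarity and phase.
#' @param compounds Optional character vector fixing which compounds to
#'   summarise (e.g. the panel of the run's polarity); defaults to every
#'   compound seen in any replicate.
#' @return A data frame of class `sst_summary`: `compound`, `n`,
#'   `mean_error`, `sd_error` (NA when n < 2), `n_missing`.
#' @export
summarize_replicates <- function(results, compounds = NULL) {
  check_same_batch(results)
  k <- length(results)
  if (is.null(compounds))
    compounds <- unique(unlist(lapply(results, function(r) names(r$errors))))
  rows <- lapply(compounds, function(cmp) {
    vals <- unlist(lapply(results, function(r) unname(r$errors[cmp])))
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    data.frame(compound = cmp, n = n,
               mean_error = if (n) mean(vals) else NA_real_,
               sd_error = if (n >= 2) stats::sd(vals) else NA_real_,
               n_missing = k - n, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("sst_summary", "data.frame"))
}

#' Mass-deviation threshold criterion
#'
#' Flags compounds whose mass error exceeds the acceptance threshold.
#' Mode `"each"` (the default, a strict reading of a maximum-deviation
#' criterion) fails a compound if any single replicate has
#' `|error| > threshold_ppm`; mode `"mean"` fails on the replicate mean.
#'
#' @param results A list of `sst_injection` objects.
#' @param threshold_ppm Acceptance threshold in ppm (default 3).
#' @param mode `"each"` or `"mean"`.
#' @return Character vector of failing compound names (possibly empty).
#' @export
check_threshold <- function(results, threshold_ppm = 3,
                            mode = c("each", "mean")) {
  mode <- match.arg(mode)
  stopifnot(threshold_ppm > 0)
  check_same_batch(results)
  smry <- summarize_replicates(results)
  if (mode == "mean") {
    failed <- smry$compound[!is.na(smry$mean_error) &
                              abs(smry$mean_error) > threshold_ppm]
  } else {
    failed <- smry$compound[vapply(smry$compound, function(cmp) {
      vals <- unlist(lapply(results, function(r) unname(r$errors[cmp])))
      any(abs(vals) > threshold_ppm, na.rm = TRUE)
    }, logical(1))]
  }
  sort(unname(failed))
}

#' Bias-randomness criterion
#'
#' Tests whether the per-compound mean errors are randomly distributed
#' about zero, i.e. free of a systematic positive or negative bias. The
#' default is an exact two-sided sign test on the signs of the compound
#' means (zeros dropped): with k the larger sign count out of n,
#' `p = min(1, 2 * P(Binomial(n, 1/2) >= k))`. A one-sample t test on the
#' means is available as an alternative. With fewer than `min_compounds`
#' defined means the check is inconclusive and never flags.
#'
#' @param summaries An `sst_summary` data frame (or list of
#'   `sst_injection`s, which is summarised first).
#' @param alpha Significance level (default 0.05).
#' @param method `"sign"` (exact sign test) or `"t"` (one-sample t test).
#' @param min_compounds Minimum number of compound means required for a
#'   conclusive check.
#' @return A list of class `sst_bias`: `flag`, `sign` (`"+"`, `"-"` or
#'   `"0"`), `p_value`, `n`, `method`, `inconclusive`.
#' @export
check_bias <- function(summaries, alpha = 0.05, method = c("sign", "t"),
                       min_compounds = 5L) {
  method <- match.arg(method)
  if (!inherits(summaries, "sst_summary")) {
    if (is.list(summaries) && all(vapply(summaries, inherits, logical(1),
                                         "sst_injection")))
      summaries <- summarize_replicates(summaries)
    else stop("summaries must be an sst_summary or list of sst_injection")
  }
  means <- summaries$mean_error[!is.na(summaries$mean_error)]
  if (length(means) < min_compounds) {
    warning("bias check inconclusive: only ", length(means),
            " compound means available (need ", min_compounds, ")")
    return(structure(list(flag = FALSE, sign = "0", p_value = NA_real_,
                          n = length(means), method = method,
                          inconclusive = TRUE), class = "sst_bias"))
  }
  n_pos <- sum(means > 0)
  n_neg <- sum(means < 0)
  if (method == "sign") {
    n <- n_pos + n_neg  # zeros carry no sign information
    if (n == 0L) {
      p <- 1
    } else {
      k <- max(n_pos, n_neg)
      p <- min(1, 2 * stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE))
    }
  } else {
    p <- stats::t.test(means, mu = 0)$p.value
  }
  sgn <- if (n_pos > n_neg) "+" else if (n_neg > n_pos) "-" else "0"
  structure(list(flag = is.finite(p) && p < alpha, sign = sgn, p_value = p,
                 n = length(means), method = method, inconclusive = FALSE),
            class = "sst_bias")
}

#' @export
print.sst_bias <- function(x, ...) {
  cat(sprintf("bias check (%s test): %s (sign %s, p = %.4g, n = %d)\n",
              x$method,
              if (x$inconclusive) "inconclusive" else if (x$flag) "BIAS FLAGGED" else "no bias",
              x$sign, x$p_value, x$n))
  invisible(x)
}

#' Two-injection outlier rule
#'
#' Decides whether a reduced two-injection SST is trustworthy on its own
#' or a third injection is required. A third injection is demanded when,
#' for any compound, (i) either replicate exceeds the acceptance threshold,
#' (ii) the within-pair disagreement exceeds `delta_ppm`, or (iii) the
#' compound is detected in only one of the two replicates.
#'
#' @param first_two A list of exactly two `sst_injection` objects.
#' @param delta_ppm Largest acceptable within-pair disagreement in ppm.
#'   Default 1.5, roughly twice the replicate standard deviation of a
#'   well-behaved Orbitrap SST.
#' @param threshold_ppm Acceptance threshold in ppm.
#' @return `"ACCEPT_TWO"` or `"THIRD_INJECTION"`, with a `reasons`
#'   attribute (character vector) explaining any trigger.
#' @export
adaptive_protocol <- function(first_two, delta_ppm = 1.5, threshold_ppm = 3) {
  if (length(first_two) != 2L)
    stop("adaptive_protocol needs exactly two injection results")
  check_same_batch(first_two)
  e1 <- first_two[[1]]$errors
  e2 <- first_two[[2]]$errors
  compounds <- union(names(e1), names(e2))
  reasons <- character()
  for (cmp in compounds) {
    a <- unname(e1[cmp])
    b <- unname(e2[cmp])
    if (xor(is.na(a), is.na(b))) {
      reasons <- c(reasons, sprintf("%s detected in only one replicate", cmp))
      next
    }
    if (any(abs(c(a, b)) > threshold_ppm, na.rm = TRUE))
      reasons <- c(reasons,
                   sprintf("%s exceeds %g ppm in a replicate", cmp, threshold_ppm))
    if (!is.na(a) && !is.na(b) && abs(a - b) > delta_ppm)
      reasons <- c(reasons,
                   sprintf("%s replicate gap %.2f ppm > %g", cmp, abs(a - b),
                           delta_ppm))
  }
  structure(if (length(reasons)) "THIRD_INJECTION" else "ACCEPT_TWO",
            reasons = reasons)
}

#' Evaluate an SST injection set
#'
#' Composes the full suitability verdict for 2-5 replicate injections of
#' one polarity and phase: the per-replicate threshold criterion, the
#' bias-randomness criterion on compound means, and detection of every
#' matching-polarity panel compound. The verdict passes only when no
#' compound fails the threshold, no bias is flagged, and no panel
#' compound is missing. The recommendation is `RECALIBRATE` on any
#' failure, `THIRD_INJECTION` when exactly two replicates were run and
#' the two-injection outlier rule is triggered, and `PROCEED` otherwise.
#'
#' @param results A list of 2-5 `sst_injection` objects (same polarity
#'   and phase).
#' @param panel The reference panel (`sst_panel`).
#' @param config An [sst_config()] list of thresholds and options.
#' @return An object of class `sst_verdict`.
#' @export
evaluate_sst <- function(results, panel = default_panel(),
                         config = sst_config()) {
  meta <- check_same_batch(results)
  n <- length(results)
  if (n < 2L || n > 5L)
    stop("an SST evaluation needs 2-5 replicate injections, got ", n)
  panel_compounds <- panel$name[panel$polarity == meta$polarity]
  smry <- summarize_replicates(results, compounds = panel_compounds)
  failed <- check_threshold(results, config$threshold_ppm,
                            config$threshold_mode)
  bias <- check_bias(smry, alpha = config$bias_alpha,
                     method = config$bias_method)
  missing <- setdiff(smry$compound[smry$n == 0L], config$allow_missing)
  pass <- length(failed) == 0L && !bias$flag && length(missing) == 0L
  recommendation <- if (!pass) {
    "RECALIBRATE"
  } else if (n == 2L &&
             adaptive_protocol(results, config$adaptive_delta_ppm,
                               config$threshold_ppm) == "THIRD_INJECTION") {
    "THIRD_INJECTION"
  } else {
    "PROCEED"
  }
  structure(list(polarity = meta$polarity, phase = meta$phase,
                 n_replicates = n, pass = pass,
                 failed_compounds = failed, bias = bias,
                 missing_compounds = sort(missing),
                 summaries = smry, recommendation = recommendation,
                 config = config),
            class = "sst_verdict")
}

#' @export
print.sst_verdict <- function(x, ...) {
  cat(sprintf("<sst_verdict> %s/%s, %d replicates: %s -> %s\n",
              x$polarity, x$phase, x$n_replicates,
              if (x$pass) "PASS" else "FAIL", x$recommendation))
  if (length(x$failed_compounds))
    cat("  threshold failures:", paste(x$failed_compounds, collapse = ", "), "\n")
  if (x$bias$flag)
    cat(sprintf("  systematic %s bias (sign test p = %.3g)\n",
                x$bias$sign, x$bias$p_value))
  if (length(x$missing_compounds))
    cat("  undetected compounds:", paste(x$missing_compounds, collapse = ", "), "\n")
  print.data.frame(transform(x$summaries,
                             mean_error = round(mean_error, 3),
                             sd_error = round(sd_error, 3)),
                   row.names = FALSE)
  invisible(x)
}

#' Serialise a verdict
#'
#' `verdict_json()` renders the verdict as machine-readable JSON;
#' `verdict_markdown()` renders a human-readable Markdown report with the
#' per-compound summary table.
#'
#' @param verdict An `sst_verdict`.
#' @param path Optional output file; when NULL the text is returned.
#' @return The JSON/Markdown text, invisibly when written to `path`.
#' @export
verdict_json <- function(verdict, path = NULL) {
  stopifnot(inherits(verdict, "sst_verdict"))
  obj <- list(
    polarity = verdict$polarity, phase = verdict$phase,
    n_replicates = verdict$n_replicates, pass = verdict$pass,
    recommendation = verdict$recommendation,
    failed_compounds = as.list(verdict$failed_compounds),
    missing_compounds = as.list(verdict$missing_compounds),
    bias = list(flag = verdict$bias$flag, sign = verdict$bias$sign,
                p_value = verdict$bias$p_value, method = verdict$bias$method,
                inconclusive = verdict$bias$inconclusive),
    summaries = verdict$summaries)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null",
                          pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname verdict_json
#' @export
verdict_markdown <- function(verdict, path = NULL) {
  stopifnot(inherits(verdict, "sst_verdict"))
  s <- verdict$summaries
  lines <- c(
    sprintf("# SST verdict: %s / %s", verdict$polarity, verdict$phase),
    "",
    sprintf("* Result: **%s** (%s)", if (verdict$pass) "PASS" else "FAIL",
            verdict$recommendation),
    sprintf("* Replicates: %d", verdict$n_replicates),
    sprintf("* Bias check (%s): %s, p = %.4g", verdict$bias$method,
            if (verdict$bias$flag) paste0("flagged (", verdict$bias$sign, ")")
            else "not flagged", verdict$bias$p_value),
    if (length(verdict$failed_compounds))
      sprintf("* Threshold failures: %s",
              paste(verdict$failed_compounds, collapse = ", ")),
    if (length(verdict$missing_compounds))
      sprintf("* Undetected: %s",
              paste(verdict$missing_compounds, collapse = ", ")),
    "",
    "| Compound | n | Mean error (ppm) | SD (ppm) | Missing |",
    "|---|---|---|---|---|",
    sprintf("| %s | %d | %.3f | %s | %d |", s$compound, s$n, s$mean_error,
            ifelse(is.na(s$sd_error), "-", sprintf("%.3f", s$sd_error)),
            s$n_missing))
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' SST configuration
#'
#' Central collection of tunable thresholds. Defaults: a 3 ppm
#' per-replicate acceptance threshold, a 0.05 significance level for the
#' bias sign test, +/-10 ppm EIC extraction windows, a 1e4-count apex
#' detection floor, a 1.5 ppm two-injection disagreement limit, a 20
#' min/injection time convention, a 100-injection (~33 h) batch-length
#' advisory limit, and a 0.3 ppm rms calibration-quality threshold.
#'
#' @param threshold_ppm Acceptance threshold for |mass error|, ppm.
#' @param threshold_mode `"each"` (any replicate) or `"mean"`.
#' @param bias_alpha Significance level of the bias criterion.
#' @param bias_method `"sign"` or `"t"`.
#' @param tol_ppm EIC extraction half-width, ppm.
#' @param min_intensity Apex detection floor, counts.
#' @param adaptive_delta_ppm Two-injection disagreement limit, ppm.
#' @param minutes_per_injection Nominal duration of one injection, min.
#' @param max_batch_injections Advisory batch-length limit, injections.
#' @param cal_rms_threshold Calibration-quality threshold, rms ppm.
#' @param allow_missing Compounds allowed to be absent without failing.
#' @param ... Further named entries kept verbatim (e.g. paths, seed).
#' @return A list of class `sst_config`.
#' @export
sst_config <- function(threshold_ppm = 3, threshold_mode = c("each", "mean"),
                       bias_alpha = 0.05, bias_method = c("sign", "t"),
                       tol_ppm = 10, min_intensity = 1e4,
                       adaptive_delta_ppm = 1.5, minutes_per_injection = 20,
                       max_batch_injections = 100, cal_rms_threshold = 0.3,
                       allow_missing = character(), ...) {
  threshold_mode <- match.arg(threshold_mode)
  bias_method <- match.arg(bias_method)
  stopifnot(threshold_ppm > 0, bias_alpha > 0, tol_ppm > 0,
            adaptive_delta_ppm > 0, minutes_per_injection > 0,
            cal_rms_threshold > 0)
  structure(list(threshold_ppm = threshold_ppm, threshold_mode = threshold_mode,
                 bias_alpha = bias_alpha, bias_method = bias_method,
                 tol_ppm = tol_ppm, min_intensity = min_intensity,
                 adaptive_delta_ppm = adaptive_delta_ppm,
                 minutes_per_injection = minutes_per_injection,
                 max_batch_injections = max_batch_injections,
                 cal_rms_threshold = cal_rms_threshold,
                 allow_missing = allow_missing, ...),
            class = "sst_config")
}

#' Load an SST configuration from YAML
#'
#' Reads a YAML mapping of [sst_config()] fields; unknown keys are kept.
#'
#' @param path YAML file path.
#' @return An `sst_config` list.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configuration files")
  vals <- yaml::read_yaml(path)
  do.call(sst_config, vals)
}
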
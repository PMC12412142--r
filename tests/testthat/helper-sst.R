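# Shared fixtures for the hramsst test suite. All data are built in code.

inj <- function(errors, id = "inj", polarity = "POS", phase = "PRE") {
  injection_result(errors, injection_id = id, polarity = polarity,
                   phase = phase)
}

pos_compounds <- function() {
  p <- default_panel()
  p$name[p$polarity == "POS"]
}

# A clean replicate set: all POS panel compounds present with the given
# per-compound error vectors (list of named vectors or a constant).
clean_replicates <- function(errs_list) {
  lapply(seq_along(errs_list), function(i)
    inj(errs_list[[i]], id = paste0("r", i)))
}

# Per-compound errors with alternating signs, |error| small: passes both
# SST criteria.
balanced_errors <- function(offset = 0.5) {
  cmp <- pos_compounds()
  setNames(offset * rep_len(c(1, -1), length(cmp)), cmp)
}

# Exact two-sided sign test by enumeration of all 2^n equiprobable sign
# vectors: P(max(K, n - K) >= max(k_obs, n - k_obs)) under K ~ Bin(n, 1/2).
enum_sign_p <- function(n, k_obs) {
  stat_obs <- max(k_obs, n - k_obs)
  hits <- 0L
  for (i in 0:(2^n - 1L)) {
    k <- sum(as.integer(intToBits(i))[seq_len(n)])
    if (max(k, n - k) >= stat_obs) hits <- hits + 1L
  }
  hits / 2^n
}

# Minimal valid history rows built record by record.
history_df <- function(batch_id, phase, replicate, compound, error_ppm,
                       polarity = "POS", n_batch_injections = 50L,
                       cal_type = "CALMIX_FLEXMIX", cal_rms_ppm = 0.1,
                       days_since_cal = 1, date = "2024-01-01") {
  data.frame(batch_id = batch_id, date = date, polarity = polarity,
             phase = phase, replicate = replicate,
             n_batch_injections = n_batch_injections, cal_type = cal_type,
             cal_rms_ppm = cal_rms_ppm, days_since_cal = days_since_cal,
             compound = compound, error_ppm = error_ppm,
             stringsAsFactors = FALSE)
}

make_history <- function(...) {
  append_record(empty_history(), rbind(...))
}

# Hand-built EIC for apex-picking tests.
make_eic <- function(rt, intensity, best_mz, target_mz = 200, tol_ppm = 10) {
  structure(data.frame(rt = rt, intensity = intensity, best_mz = best_mz),
            target_mz = target_mz, tol_ppm = tol_ppm,
            class = c("sst_eic", "data.frame"))
}

# Small, fast synthetic-run config (coarser scans than the default).
quick_run_config <- function(...) {
  synthetic_run_config(scan_interval_seconds = 2, n_decoys = 5, ...)
}
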
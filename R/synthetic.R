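# Synthetic-data generators with known ground truth: centroided LC-MS runs
# and longitudinal SST histories.
#
# All randomness uses R's default Mersenne-Twister RNG under a local seed;
# the caller's RNG state is left untouched and a fixed seed yields
# identical output.

with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

#' Configuration for a synthetic LC-MS run
#'
#' Describes a centroided MS1 run containing Gaussian chromatographic
#' peaks for every matching-polarity panel compound, with a controllable
#' true mass bias (ppm), scan-to-scan mass noise, and decoy centroids.
#' Each compound's centroid m/z in a scan is
#' `expected_mz * (1 + (bias + N(0, mass_noise_sd_ppm)) * 1e-6)`.
#' Decoy centroids are kept at least `decoy_min_ppm` (default 50 ppm)
#' away from every target so default 10 ppm extraction windows see only
#' the intended peaks; lower it towards 15 ppm for interference
#' robustness tests.
#'
#' @param panel An `sst_panel`.
#' @param polarity `"POS"` or `"NEG"`.
#' @param true_bias_ppm Global true mass bias in ppm.
#' @param per_compound_bias Optional named vector of per-compound bias
#'   overrides (ppm).
#' @param mass_noise_sd_ppm Scan-to-scan mass noise SD in ppm.
#' @param rt_assignments Optional named vector of peak-centre retention
#'   times (minutes); by default compounds are spread evenly across the
#'   run, mimicking a short generic gradient.
#' @param peak_sigma_minutes Chromatographic peak SD in minutes.
#' @param peak_height Apex intensity in counts.
#' @param baseline_height Typical decoy/baseline centroid intensity.
#' @param scan_interval_seconds MS1 scan interval.
#' @param run_minutes Run length in minutes (default 7, a short
#'   generic SST gradient).
#' @param n_decoys Number of decoy centroid tracks.
#' @param decoy_min_ppm Minimum distance of decoys from targets, ppm.
#' @param seed RNG seed; a fixed seed gives an identical run.
#' @return A list of class `sst_run_config`.
#' @export
synthetic_run_config <- function(panel = default_panel(),
                                 polarity = c("POS", "NEG"),
                                 true_bias_ppm = 0,
                                 per_compound_bias = NULL,
                                 mass_noise_sd_ppm = 0,
                                 rt_assignments = NULL,
                                 peak_sigma_minutes = 0.05,
                                 peak_height = 1e6,
                                 baseline_height = 1e3,
                                 scan_interval_seconds = 1,
                                 run_minutes = 7,
                                 n_decoys = 20,
                                 decoy_min_ppm = 50,
                                 seed = 1L) {
  polarity <- match.arg(polarity)
  stopifnot(mass_noise_sd_ppm >= 0, peak_sigma_minutes > 0, peak_height > 0,
            scan_interval_seconds > 0, run_minutes > 0, n_decoys >= 0)
  compounds <- panel$name[panel$polarity == polarity]
  if (!length(compounds)) stop("panel has no ", polarity, " compounds")
  if (is.null(rt_assignments)) {
    rt_assignments <- stats::setNames(
      seq(0.08 * run_minutes, 0.92 * run_minutes,
          length.out = length(compounds)),
      compounds)
  }
  if (!all(compounds %in% names(rt_assignments)))
    stop("rt_assignments must cover every matching-polarity compound")
  structure(list(panel = panel, polarity = polarity,
                 true_bias_ppm = true_bias_ppm,
                 per_compound_bias = per_compound_bias,
                 mass_noise_sd_ppm = mass_noise_sd_ppm,
                 rt_assignments = rt_assignments,
                 peak_sigma_minutes = peak_sigma_minutes,
                 peak_height = peak_height,
                 baseline_height = baseline_height,
                 scan_interval_seconds = scan_interval_seconds,
                 run_minutes = run_minutes, n_decoys = n_decoys,
                 decoy_min_ppm = decoy_min_ppm, seed = as.integer(seed)),
            class = "sst_run_config")
}

#' Generate a synthetic centroided run
#'
#' Builds the `sst_run` described by an [synthetic_run_config()]; when
#' `path` is given, additionally writes it as mzML (round-trippable
#' through [read_run()]) together with a ground-truth JSON sidecar
#' (`<path>.ground_truth.json`) recording the generating parameters.
#'
#' @param config An `sst_run_config`.
#' @param path Optional mzML output path.
#' @return An `sst_run` (with attribute `ground_truth`); when `path` is
#'   given the run is also written to disk.
#' @export
generate_run <- function(config, path = NULL) {
  stopifnot(inherits(config, "sst_run_config"))
  sub <- config$panel[config$panel$polarity == config$polarity, , drop = FALSE]
  bias <- stats::setNames(rep(config$true_bias_ppm, nrow(sub)), sub$name)
  if (!is.null(config$per_compound_bias)) {
    ov <- intersect(names(config$per_compound_bias), names(bias))
    bias[ov] <- config$per_compound_bias[ov]
  }
  rts <- seq(0, config$run_minutes, by = config$scan_interval_seconds / 60)
  run <- with_seed(config$seed, {
    # Decoy m/z tracks, rejected within decoy_min_ppm of any target.
    decoys <- numeric(0)
    while (length(decoys) < config$n_decoys) {
      cand <- stats::runif(config$n_decoys, 100, 1000)
      ok <- vapply(cand, function(mz)
        all(abs(ppm_error(mz, sub$expected_mz)) > config$decoy_min_ppm),
        logical(1))
      decoys <- c(decoys, cand[ok])[seq_len(min(config$n_decoys,
                                                length(decoys) + sum(ok)))]
    }
    spectra <- lapply(rts, function(rt) {
      mz <- numeric(0); int <- numeric(0)
      for (i in seq_len(nrow(sub))) {
        h <- config$peak_height *
          exp(-(rt - config$rt_assignments[[sub$name[i]]])^2 /
                (2 * config$peak_sigma_minutes^2))
        if (h < 1) next
        ppm_off <- bias[[sub$name[i]]] +
          if (config$mass_noise_sd_ppm > 0)
            stats::rnorm(1, 0, config$mass_noise_sd_ppm) else 0
        mz <- c(mz, shift_mz(sub$expected_mz[i], ppm_off))
        int <- c(int, h)
      }
      if (length(decoys)) {
        mz <- c(mz, decoys)
        int <- c(int, config$baseline_height *
                   stats::runif(length(decoys), 0.5, 1.5))
      }
      o <- order(mz)
      list(rt = rt, mz = mz[o], intensity = int[o])
    })
    new_sst_run(spectra, config$polarity,
                source_id = sprintf("synthetic-%s-seed%d", config$polarity,
                                    config$seed))
  })
  truth <- list(polarity = config$polarity,
                true_bias_ppm = config$true_bias_ppm,
                per_compound_bias = as.list(bias),
                mass_noise_sd_ppm = config$mass_noise_sd_ppm,
                rt_assignments = as.list(config$rt_assignments),
                peak_height = config$peak_height, seed = config$seed)
  attr(run, "ground_truth") <- truth
  if (!is.null(path)) {
    write_mzml(run, path)
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               paste0(path, ".ground_truth.json"))
  }
  run
}

# Stylized per-compound true mean errors (ppm) used as generator defaults:
# small sub-ppm offsets of the magnitude a routinely calibrated Orbitrap
# shows, positive-mode compounds tightly centred, negative-mode compounds
# more dispersed.
.default_true_means <- c(
  "Acetaminophen" = 0.31, "Caffeine" = 0.07, "Carbamazepine" = 0.40,
  "Oxazepam" = 0.00, "Clindamycin sulfoxide" = -0.19, "Verapamil" = 0.13,
  "Fexofenadine" = -0.13, "Anhydro erythromycin" = -0.02,
  "Perfluoropentanoic acid" = 0.94, "Perfluorohexanoic acid" = -0.88,
  "Perfluorooctanoic acid" = -0.01,
  "6:2 Fluorotelomer sulfonic acid" = 0.76,
  "Perfluorooctane sulfonamide" = -0.05)

#' Configuration for a synthetic SST history
#'
#' Describes a longitudinal history of SST batches with known ground
#' truth. Each batch draws its covariates (injection count, calibration
#' type, calibration rms, days since calibration); each replicate error is
#'
#' `error = mu_c + calmix_penalty * 1(CALMIX) + poor_cal_penalty * 1(POOR)
#'          + drift_slope * n_batch_injections * 1(POST) + N(0, sd_pol)`
#'
#' so drift accrues only in post-batch SSTs while calibration penalties,
#' being properties of the batch's calibration state, apply to both
#' phases. Replicate noise defaults to 0.7 ppm in positive and 0.5 ppm in
#' negative mode, the magnitudes routinely observed in long-term Orbitrap
#' SST records.
#'
#' @param panel An `sst_panel`.
#' @param n_batches Number of batches.
#' @param injections_per_batch Either a fixed count, a vector sampled
#'   from uniformly, or a `function(n)` sampler. Default: uniform over
#'   10-130 injections per batch.
#' @param replicates_per_phase Replicate SST injections per phase
#'   (default 5).
#' @param compound_true_means Named vector of per-compound true mean
#'   errors mu_c in ppm; defaults to stylized sub-ppm offsets.
#' @param replicate_sd_pos,replicate_sd_neg Replicate noise SD, ppm.
#' @param drift_slope_ppm_per_injection Drift accrued per batch injection
#'   in POST-phase errors (default 0.01 ppm/injection, about 1 ppm after
#'   a 100-injection batch).
#' @param poor_cal_penalty_ppm Error shift under a POOR calibration
#'   (default 0.5 ppm).
#' @param calmix_penalty_ppm Error shift when calibrated with CalMix only
#'   (default 0.4 ppm, the scale of the low-mass penalty seen when
#'   low-m/z calibrants are omitted).
#' @param cal_quality_mix Fraction of batches with a POOR calibration.
#' @param cal_type_mix Fraction of batches calibrated with CalMix only.
#' @param days_since_cal_sampler `function(n)` drawing days since the
#'   last calibration (default: uniform integers 0-14).
#' @param polarities Polarities to generate.
#' @param start_date First batch date (batches are spread over ~5 months).
#' @param seed RNG seed.
#' @return A list of class `sst_history_config`.
#' @export
synthetic_history_config <- function(panel = default_panel(),
                                     n_batches = 50,
                                     injections_per_batch = 10:130,
                                     replicates_per_phase = 5,
                                     compound_true_means = .default_true_means,
                                     replicate_sd_pos = 0.7,
                                     replicate_sd_neg = 0.5,
                                     drift_slope_ppm_per_injection = 0.01,
                                     poor_cal_penalty_ppm = 0.5,
                                     calmix_penalty_ppm = 0.4,
                                     cal_quality_mix = 0.2,
                                     cal_type_mix = 0.3,
                                     days_since_cal_sampler = NULL,
                                     polarities = c("POS", "NEG"),
                                     start_date = "2024-01-10",
                                     seed = 1L) {
  stopifnot(n_batches >= 1, replicates_per_phase >= 1,
            replicate_sd_pos >= 0, replicate_sd_neg >= 0,
            cal_quality_mix >= 0, cal_quality_mix <= 1,
            cal_type_mix >= 0, cal_type_mix <= 1)
  if (is.null(days_since_cal_sampler))
    days_since_cal_sampler <- function(n) sample(0:14, n, replace = TRUE)
  structure(list(panel = panel, n_batches = as.integer(n_batches),
                 injections_per_batch = injections_per_batch,
                 replicates_per_phase = as.integer(replicates_per_phase),
                 compound_true_means = compound_true_means,
                 replicate_sd_pos = replicate_sd_pos,
                 replicate_sd_neg = replicate_sd_neg,
                 drift_slope_ppm_per_injection = drift_slope_ppm_per_injection,
                 poor_cal_penalty_ppm = poor_cal_penalty_ppm,
                 calmix_penalty_ppm = calmix_penalty_ppm,
                 cal_quality_mix = cal_quality_mix,
                 cal_type_mix = cal_type_mix,
                 days_since_cal_sampler = days_since_cal_sampler,
                 polarities = match.arg(polarities, c("POS", "NEG"),
                                        several.ok = TRUE),
                 start_date = start_date, seed = as.integer(seed)),
            class = "sst_history_config")
}

#' Generate a synthetic SST history
#'
#' Draws the longitudinal history described by an
#' [synthetic_history_config()]. The returned history carries a
#' `ground_truth` attribute with every generating parameter and the
#' per-batch covariate draws, for parameter-recovery tests.
#'
#' @param config An `sst_history_config`.
#' @return An `sst_history` with attribute `ground_truth`.
#' @export
generate_history <- function(config) {
  stopifnot(inherits(config, "sst_history_config"))
  panel <- config$panel
  mu <- stats::setNames(rep(0, nrow(panel)), panel$name)
  ov <- intersect(names(config$compound_true_means), names(mu))
  mu[ov] <- config$compound_true_means[ov]

  with_seed(config$seed, {
    nb <- config$n_batches
    n_inj <- if (is.function(config$injections_per_batch))
      config$injections_per_batch(nb)
    else if (length(config$injections_per_batch) == 1L)
      rep(config$injections_per_batch, nb)
    else sample(config$injections_per_batch, nb, replace = TRUE)
    poor <- stats::runif(nb) < config$cal_quality_mix
    cal_rms <- ifelse(poor, stats::runif(nb, 0.31, 0.8),
                      stats::runif(nb, 0.05, 0.3))
    cal_type <- ifelse(stats::runif(nb) < config$cal_type_mix,
                       "CALMIX", "CALMIX_FLEXMIX")
    days <- config$days_since_cal_sampler(nb)
    dates <- as.character(as.Date(config$start_date) +
                            round(seq(0, 150, length.out = nb)))
    batches <- data.frame(
      batch_id = sprintf("B%03d", seq_len(nb)), date = dates,
      n_batch_injections = as.integer(n_inj), cal_type = cal_type,
      cal_rms_ppm = round(cal_rms, 3), days_since_cal = days,
      stringsAsFactors = FALSE)

    pieces <- list()
    for (pol in config$polarities) {
      compounds <- panel$name[panel$polarity == pol]
      sd_pol <- if (pol == "POS") config$replicate_sd_pos
                else config$replicate_sd_neg
      grid <- expand.grid(compound = compounds,
                          replicate = seq_len(config$replicates_per_phase),
                          phase = c("PRE", "POST"),
                          batch = seq_len(nb),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      b <- batches[grid$batch, ]
      mean_err <- mu[grid$compound] +
        config$calmix_penalty_ppm * (b$cal_type == "CALMIX") +
        config$poor_cal_penalty_ppm * (b$cal_rms_ppm > 0.3) +
        config$drift_slope_ppm_per_injection * b$n_batch_injections *
          (grid$phase == "POST")
      pieces[[pol]] <- data.frame(
        batch_id = b$batch_id, date = b$date, polarity = pol,
        phase = grid$phase, replicate = grid$replicate,
        n_batch_injections = b$n_batch_injections, cal_type = b$cal_type,
        cal_rms_ppm = b$cal_rms_ppm, days_since_cal = b$days_since_cal,
        compound = grid$compound,
        error_ppm = stats::rnorm(nrow(grid), mean_err, sd_pol),
        stringsAsFactors = FALSE)
    }
    hist <- validate_history(do.call(rbind, pieces))
    attr(hist, "ground_truth") <- list(
      compound_true_means = as.list(mu),
      replicate_sd_pos = config$replicate_sd_pos,
      replicate_sd_neg = config$replicate_sd_neg,
      drift_slope_ppm_per_injection = config$drift_slope_ppm_per_injection,
      poor_cal_penalty_ppm = config$poor_cal_penalty_ppm,
      calmix_penalty_ppm = config$calmix_penalty_ppm,
      batches = batches, seed = config$seed)
    hist
  })
}
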
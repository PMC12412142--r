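# Drift and calibration linear models, drift analysis, advisories.

test_that("the drift model equals the normal-equation solution", {
  h <- generate_history(synthetic_history_config(n_batches = 6, seed = 41))
  fit <- fit_error_model(h, "Caffeine")
  d <- h[h$compound == "Caffeine", ]
  X <- cbind(1, post = as.integer(d$phase == "POST"),
             n = d$n_batch_injections,
             px = as.integer(d$phase == "POST") * d$n_batch_injections)
  beta <- solve(t(X) %*% X, t(X) %*% d$error_ppm)
  expect_equal(fit$estimates, as.numeric(beta), tolerance = 1e-10)
  # standard errors from the same brute-force route
  res <- d$error_ppm - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  expect_equal(fit$standard_errors,
               unname(sqrt(diag(s2 * solve(t(X) %*% X)))), tolerance = 1e-8)
  expect_equal(fit$n_obs, nrow(d))
})

test_that("a pure-intercept truth yields a flat fitted drift model", {
  cfg <- synthetic_history_config(
    n_batches = 20, replicates_per_phase = 5, replicate_sd_pos = 0.1,
    compound_true_means = setNames(rep(0.5, 13), default_panel()$name),
    drift_slope_ppm_per_injection = 0, poor_cal_penalty_ppm = 0,
    calmix_penalty_ppm = 0, seed = 43)
  fit <- fit_error_model(generate_history(cfg), "Caffeine")
  i <- match("(Intercept)", fit$terms)
  expect_lt(abs(fit$estimates[i] - 0.5), 2 * fit$standard_errors[i])
  # slope terms carry no signal
  others <- setdiff(seq_along(fit$terms), i)
  expect_true(all(abs(fit$estimates[others]) <
                    3 * fit$standard_errors[others]))
})

test_that("a post-phase drift slope is recovered by the interaction term", {
  cfg <- synthetic_history_config(
    n_batches = 50, drift_slope_ppm_per_injection = 0.02,
    poor_cal_penalty_ppm = 0, calmix_penalty_ppm = 0, seed = 47)
  fit <- fit_error_model(generate_history(cfg), "Caffeine")
  i <- match("phase_post:n_batch_injections", fit$terms)
  # 3 SE: a fixed-seed draw sits inside this band with ~99.7% probability;
  # calibrated 2-SE coverage is checked over many seeds elsewhere
  expect_lt(abs(fit$estimates[i] - 0.02), 3 * fit$standard_errors[i])
  expect_lt(fit$p_values[i], 0.01)
})

test_that("row order does not change the fit", {
  h <- generate_history(synthetic_history_config(n_batches = 8, seed = 53))
  f1 <- fit_error_model(h, "Verapamil")
  set.seed(1)
  hp <- h[sample(nrow(h)), ]
  class(hp) <- class(h)
  f2 <- fit_error_model(hp, "Verapamil")
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-12)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-12)
})

test_that("rank-deficient designs fail naming the collinear term", {
  # PRE-only history: the phase indicator is constant
  pre <- make_history(history_df("B1", "PRE", 1:5, "Caffeine",
                                 rnorm(5), n_batch_injections = 50L),
                      history_df("B2", "PRE", 1:5, "Caffeine",
                                 rnorm(5), n_batch_injections = 80L))
  expect_error(fit_error_model(pre, "Caffeine", min_obs = 5),
               "phase_post")
  # single calibration type
  h <- generate_history(synthetic_history_config(n_batches = 10,
                                                 cal_type_mix = 0, seed = 59))
  expect_error(suppressMessages(fit_calibration_model(h)), "cal_type")
  # single quality stratum
  h2 <- generate_history(synthetic_history_config(n_batches = 10,
                                                  cal_quality_mix = 0,
                                                  seed = 61))
  expect_error(suppressMessages(fit_calibration_model(h2)), "cal_quality")
})

test_that("calibration penalties are recovered from noisy histories", {
  cfg <- synthetic_history_config(
    n_batches = 60, poor_cal_penalty_ppm = 0.5, calmix_penalty_ppm = 0.4,
    drift_slope_ppm_per_injection = 0,
    compound_true_means = setNames(rep(1.5, 13), default_panel()$name),
    cal_quality_mix = 0.3, cal_type_mix = 0.4, seed = 67)
  fit <- suppressMessages(
    fit_calibration_model(generate_history(cfg), polarity = "POS"))
  i <- match("cal_typeCALMIX", fit$terms)
  j <- match("cal_qualityPOOR", fit$terms)
  expect_lt(abs(fit$estimates[i] - 0.4), 2 * fit$standard_errors[i])
  expect_lt(abs(fit$estimates[j] - 0.5), 2 * fit$standard_errors[j])
})

test_that("a noiseless linear truth is fit exactly", {
  cfg <- synthetic_history_config(
    n_batches = 20, replicate_sd_pos = 0, replicate_sd_neg = 0,
    compound_true_means = setNames(rep(1.5, 13), default_panel()$name),
    poor_cal_penalty_ppm = 0.5, calmix_penalty_ppm = 0.4,
    drift_slope_ppm_per_injection = 0, cal_quality_mix = 0.4,
    cal_type_mix = 0.5, seed = 71)
  fit <- suppressWarnings(suppressMessages(
    fit_calibration_model(generate_history(cfg), exclusions = function(d)
      rep(FALSE, nrow(d)))))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(max(abs(residuals(fit$fit))), 0, tolerance = 1e-10)
})

test_that("the sparse-stratum exclusion drops long-interval CalMix records", {
  cfg <- synthetic_history_config(
    n_batches = 30, cal_type_mix = 0.5,
    days_since_cal_sampler = function(n) sample(0:20, n, replace = TRUE),
    seed = 73)
  h <- generate_history(cfg)
  n_excl <- sum(h$cal_type == "CALMIX" & h$days_since_cal > 7)
  expect_gt(n_excl, 0)
  expect_message(fit <- fit_calibration_model(h), "excluding")
  expect_equal(fit$n_obs, nrow(h) - n_excl)
})

test_that("pre/post drift deltas and strata are computed per batch", {
  h <- make_history(
    history_df("B1", "PRE", 1:2, "Caffeine", c(0.0, 0.2)),
    history_df("B1", "POST", 1:2, "Caffeine", c(0.5, 0.7)),
    history_df("B2", "PRE", 1L, "Caffeine", 0.1, cal_rms_ppm = 0.5))
  expect_warning(d <- drift_analysis(h), "missing a phase")
  expect_equal(nrow(d$deltas), 1L)
  expect_equal(d$deltas$delta_ppm, 0.5)
  expect_equal(d$deltas$cal_quality_flag, "GOOD")
  expect_equal(d$deltas$batch_hours, 50 * 20 / 60)
})

test_that("drift deltas track the generator's drift arithmetic", {
  # slope 0.025 ppm/injection on 60-injection batches: mean delta ~ 1.5 ppm
  cfg <- synthetic_history_config(
    n_batches = 30, injections_per_batch = 60,
    drift_slope_ppm_per_injection = 0.025,
    poor_cal_penalty_ppm = 0, calmix_penalty_ppm = 0, seed = 79)
  d <- drift_analysis(generate_history(cfg))
  expect_equal(mean(d$deltas$delta_ppm), 1.5, tolerance = 0.1)

  cfg0 <- synthetic_history_config(
    n_batches = 40, drift_slope_ppm_per_injection = 0,
    poor_cal_penalty_ppm = 0, calmix_penalty_ppm = 0, seed = 83)
  d0 <- drift_analysis(generate_history(cfg0))
  se <- sd(d0$deltas$delta_ppm) / sqrt(nrow(d0$deltas))
  expect_lt(abs(mean(d0$deltas$delta_ppm)), 3.5 * se)
})

test_that("batch-length advisories fire at the documented limits", {
  expect_length(batch_length_advisor(99), 0L)
  adv <- batch_length_advisor(101)
  expect_length(adv, 1L)
  expect_match(adv, "exceeds the 100-injection")
  adv2 <- batch_length_advisor(60, cal_quality = "POOR")
  expect_length(adv2, 1L)
  expect_match(adv2, "~20 h")
  expect_length(batch_length_advisor(60, cal_quality = "GOOD"), 0L)
})

test_that("fits serialise to JSON", {
  h <- generate_history(synthetic_history_config(n_batches = 6, seed = 89))
  fit <- fit_error_model(h, "Caffeine")
  j <- jsonlite::fromJSON(fit_json(fit))
  expect_equal(j$terms, fit$terms)
  expect_equal(j$estimates, fit$estimates)
  expect_equal(j$r_squared, fit$r_squared)
})
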
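# mzML I/O, extracted ion chromatograms and apex picking.

test_that("a generated run round-trips through mzML", {
  cfg <- quick_run_config(true_bias_ppm = 1.2, mass_noise_sd_ppm = 0.05,
                          seed = 3)
  run <- generate_run(cfg)
  f <- tempfile(fileext = ".mzML")
  write_mzml(run, f)
  back <- read_run(f, "POS")
  expect_equal(length(back$spectra), length(run$spectra))
  i <- c(1, 50, length(run$spectra))
  for (k in i) {
    expect_equal(back$spectra[[k]]$rt, run$spectra[[k]]$rt, tolerance = 1e-9)
    expect_equal(back$spectra[[k]]$mz, run$spectra[[k]]$mz, tolerance = 1e-9)
    expect_equal(back$spectra[[k]]$intensity, run$spectra[[k]]$intensity,
                 tolerance = 1e-6)
  }
  unlink(f)
})

test_that("polarity filtering and missing files give distinct errors", {
  expect_error(read_run(tempfile(fileext = ".mzML"), "POS"), "not found")
  f <- tempfile(fileext = ".mzML")
  generate_run(quick_run_config(polarity = "NEG", seed = 4), path = f)
  expect_error(read_run(f, "POS"), "no MS1 spectra of polarity POS")
  neg <- read_run(f, "NEG")
  expect_equal(neg$polarity, "NEG")
  unlink(f)
})

test_that("profile-mode spectra are rejected", {
  f <- tempfile(fileext = ".mzML")
  pks <- list(cbind(mz = c(100, 200), intensity = c(1, 2)))
  hdr <- data.frame(
    seqNum = 1L, acquisitionNum = 1L, msLevel = 1L, polarity = 1L,
    peaksCount = 2L, totIonCurrent = 3, retentionTime = 10,
    basePeakMZ = 200, basePeakIntensity = 2, collisionEnergy = 0,
    ionisationEnergy = 0, lowMZ = 100, highMZ = 200,
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = -1L, mergedResultScanNum = -1L,
    mergedResultStartScanNum = -1L, mergedResultEndScanNum = -1L,
    injectionTime = 0, filterString = NA_character_, spectrumId = "scan=1",
    centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = 100,
    scanWindowUpperLimit = 1000, stringsAsFactors = FALSE)
  mzR::writeMSData(pks, f, header = hdr, outformat = "mzml")
  expect_error(read_run(f, "POS"), "profile")
  unlink(f)
})

test_that("EIC windows select only centroids within the ppm tolerance", {
  # a compound displaced by +20 ppm is invisible to a 10 ppm window
  cfg <- quick_run_config(
    per_compound_bias = c(Caffeine = 20), seed = 5)
  run <- generate_run(cfg)
  target <- default_panel()$expected_mz[default_panel()$name == "Caffeine"]
  eic <- extract_eic(run, target, tol_ppm = 10)
  expect_true(all(eic$intensity == 0))
  expect_true(all(is.na(eic$best_mz)))
  # but a 30 ppm window sees it
  eic30 <- extract_eic(run, target, tol_ppm = 30)
  expect_gt(max(eic30$intensity), 1e5)
})

test_that("EIC total intensity is invariant under rt-range splitting", {
  run <- generate_run(quick_run_config(seed = 6))
  target <- 195.0877
  full <- extract_eic(run, target, 10)
  left <- extract_eic(run, target, 10, rt_range = c(0, 3.0001))
  right <- extract_eic(run, target, 10, rt_range = c(3.0002, 8))
  expect_equal(nrow(left) + nrow(right), nrow(full))
  expect_equal(sum(left$intensity) + sum(right$intensity),
               sum(full$intensity))
})

test_that("apex picking takes the maximal scan with earliest-rt ties", {
  tri <- make_eic(rt = 1:13 / 10, intensity = c(1:7, 6:1) * 1e4,
                  best_mz = 200 + (1:13) * 1e-5)
  apex <- find_apex(tri, min_intensity = 1e4)
  expect_true(apex$detected)
  expect_equal(apex$apex_rt, 0.7)
  expect_equal(apex$apex_mz, tri$best_mz[7])

  tie <- make_eic(rt = 1:10, intensity = c(1, 2, 3, 9, 5, 6, 7, 8, 9, 1) * 1e4,
                  best_mz = 200 + 1:10)
  expect_equal(find_apex(tie, 1e4)$apex_rt, 4)  # first of the two maxima

  low <- make_eic(rt = 1:5, intensity = rep(100, 5), best_mz = rep(200, 5))
  expect_false(find_apex(low, 1e4)$detected)

  # scaling all intensities (above threshold) does not move the apex
  scaled <- tri
  scaled$intensity <- scaled$intensity * 37
  expect_equal(find_apex(scaled, 1e4)$apex_rt, apex$apex_rt)
})

test_that("measure_panel scores matching-polarity compounds only", {
  run <- generate_run(quick_run_config(seed = 8))
  m <- measure_panel(run)
  p <- default_panel()
  expect_setequal(m$compound, p$name[p$polarity == "POS"])
  expect_true(all(m$detected))
  # low-signal run: compounds present but below the detection floor
  faint <- generate_run(quick_run_config(peak_height = 500, seed = 9))
  mf <- measure_panel(faint, min_intensity = 1e4)
  expect_true(all(!mf$detected))
  expect_true(all(is.na(mf$ppm_error)))
})

test_that("injected mass bias is recovered end to end across the pipeline", {
  for (b in c(-3, -1, 0, 1, 3)) {
    run <- generate_run(quick_run_config(true_bias_ppm = b,
                                         mass_noise_sd_ppm = 0, seed = 10))
    m <- measure_panel(run)
    expect_true(all(abs(m$ppm_error - b) < 0.01),
                label = sprintf("bias %+.0f ppm recovered", b))
  }
})

test_that("measurements convert to injection results", {
  run <- generate_run(quick_run_config(true_bias_ppm = 1, seed = 12))
  m <- measure_panel(run)
  r <- as_injection_result(m, phase = "PRE")
  expect_s3_class(r, "sst_injection")
  expect_equal(r$polarity, "POS")
  expect_setequal(names(r$errors), m$compound)
  expect_equal(unname(r$errors[m$compound]), m$ppm_error)
})
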
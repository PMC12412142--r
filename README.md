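# hramsst

High-resolution accurate mass system suitability testing (HRAM-SST) for
LC-HRMS instruments.

## The problem

High-resolution mass spectrometers (Orbitraps in particular) are only as
useful as their mass accuracy: suspect and nontarget screening of small
molecules needs observed *m/z* values within a few ppm of theory, and a
successful vendor calibration does not guarantee that accuracy will hold
through a long acquisition batch. An HRAM-SST brackets every sample batch
with replicate injections of a known reference-standard mixture and asks two
questions of the observed apex *m/z* values:

1. **Threshold criterion** — is every mass error within the acceptance
   threshold?

   `ppm error = (m/z_observed − m/z_theoretical) / m/z_theoretical × 10⁶`,
   with |error| ≤ 3 ppm required for every compound;

2. **Randomness criterion** — are the signed errors randomly distributed
   about zero? A consistent positive or negative offset signals a
   calibration problem even when every individual error is inside the
   threshold. This package operationalises the criterion as an exact
   two-sided sign test on the per-compound mean errors.

If either criterion fails, the instrument should be recalibrated before
samples are run. The package implements this workflow end to end for
centroided mzML data, plus the longitudinal layer: persisting SST records
over months and fitting the two linear models that quantify (a) mass-error
drift with batch length (`error ~ phase × n_injections`, where the
interaction is the within-batch drift rate in ppm per injection) and (b) the
effect of calibration state on accuracy
(`|error| ~ cal_type + cal_quality + days_since_cal +
days_since_cal:cal_quality`).

It ships a 13-compound reference panel (8 positive-mode, 5 negative-mode
species from 152 to 716 *m/z*) whose expected adduct *m/z* values are
recomputed from elemental formulas, a 2/3/5-injection protocol (two
injections suffice unless they disagree, in which case a third is demanded),
and synthetic-data generators with known ground truth so every stage is
testable without instrument data.

## Worked example

Theoretical masses and ppm errors:

```r
library(hramsst)
mz <- adduct_mz("C8H10N4O2", "+H")   # caffeine [M+H]+
sprintf("%.4f", mz)                  # "195.0877"
ppm_error(195.0883, mz)              # +3.321 ppm -> outside the 3 ppm limit
```

A full SST evaluation on three (here synthetic) pre-batch injections from an
instrument with a uniform +1.8 ppm miscalibration:

```r
files <- sapply(1:3, function(i) {
  f <- file.path(tempdir(), sprintf("sst_pre_%d.mzML", i))
  generate_run(synthetic_run_config(true_bias_ppm = 1.8,
                                    mass_noise_sd_ppm = 0.15,
                                    seed = 100 + i), path = f)
  f
})
results <- lapply(files, function(f)
  as_injection_result(measure_panel(read_run(f, "POS")), phase = "PRE"))
evaluate_sst(results)
#> <sst_verdict> POS/PRE, 3 replicates: FAIL -> RECALIBRATE
#>   systematic + bias (sign test p = 0.00781)
#>               compound n mean_error sd_error n_missing
#>          Acetaminophen 3      1.891    0.181         0
#>   Anhydro erythromycin 3      1.772    0.009         0
#>               Caffeine 3      1.736    0.071         0
#>          Carbamazepine 3      1.733    0.105         0
#>  Clindamycin sulfoxide 3      1.804    0.055         0
#>           Fexofenadine 3      1.856    0.037         0
#>               Oxazepam 3      1.792    0.062         0
#>              Verapamil 3      1.814    0.185         0
```

Every compound is inside 3 ppm, yet the verdict is FAIL: all eight mean
errors share the same sign (exact sign test p = 2 × (1/2)⁸ ≈ 0.0078), so the
errors are not randomly distributed and a recalibration is recommended —
exactly the situation the second criterion exists to catch.

Longitudinal analysis of a history of SST records:

```r
h <- generate_history(synthetic_history_config(n_batches = 50, seed = 42))
fit_error_model(h, "Caffeine")            # drift per batch injection
fit_calibration_model(h, polarity = "POS") # CalMix / quality / staleness effects
drift_analysis(h)                          # per-batch POST - PRE deltas
sst_report(h, "report/")                   # CSV/JSON/Markdown artifacts
```

A command-line front end (panel inspection, batch evaluation with exit codes
0 = proceed / 2 = third injection / 3 = recalibrate, reporting, simulation)
is installed at `system.file("cli", "hram-sst.R", package = "hramsst")`.

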
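---
title: "Methods: mass-accuracy system suitability testing with hramsst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass-accuracy system suitability testing with hramsst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hramsst)
```

## The procedure

An HRAM-SST (high-resolution accurate mass system suitability test) answers
one operational question: *is this LC-HRMS instrument currently delivering
the mass accuracy that screening work requires?* It is deliberately not a
calibration, not a quantitative QC, and not a retention-time or
sensitivity check — chromatography is generic and unoptimised by design,
because only the mass axis is under test.

The workflow bracketing every sample batch is:

1. Inject a mixture of reference standards 2–5 times per ionization mode,
   before (PRE) and after (POST) the batch.
2. For each compound, extract an ion chromatogram at its theoretical adduct
   *m/z* and read the observed *m/z* at the apex of the peak.
3. Score the signed error in ppm against two criteria:
   * **threshold** — every replicate |error| ≤ 3 ppm;
   * **randomness** — per-compound mean errors show no systematic sign.
4. On failure, recalibrate and repeat; on success, proceed. With exactly two
   replicates, a within-pair disagreement triggers a third injection.

Longitudinally, the per-injection records accumulate into a history from
which two ordinary least squares models quantify what erodes accuracy:
drift over the course of a batch, and the calibration state (calibrant
coverage, calibration quality, time since calibration).

## Theoretical masses

Monoisotopic masses are summed from a static table of
most-abundant-isotope masses (NIST / AME evaluation values, ≥ 9
significant decimals, covering C, H, N, O, F, S, Cl, P, Br, I, Na, K, Si,
B). Protonation and deprotonation are modelled as gain/loss of a proton
(±1.00727646 u) at unit charge; no separate electron-mass bookkeeping is
applied, which reproduces the reference panel's published 4-decimal values
exactly. Multiply charged species, isotopologues and in-source fragments
are out of scope: an SST mixture is chosen so its compounds appear as
clean singly charged (de)protonated molecules.

The bundled 13-compound panel is data, not code (`inst/extdata/`), so
laboratories can substitute their own mixture; `read_panel()` recomputes
every expected *m/z* from the formula and refuses silent disagreements.
One bundled entry, perfluoropentanoic acid, carries an `erratum` flag: its
published expected *m/z* (262.9760) corresponds to C5HF9O2 rather than the
listed formula C6HF9O2. The published value is kept verbatim — the SST
compares instrument readings against the value analysts actually use — and
`validate_panel()` surfaces the inconsistency as an advisory. Acetaminophen
ionises in both modes; only its protonated form is carried in the panel, so
each ionization mode scores exactly the compounds observable in it (8
positive, 5 negative).

`validate_panel()` also screens the panel design: the guidance it encodes
is one compound per 100–200 *m/z* per polarity across the scan range
(default 100–1000). Gaps over 200 u between neighbours and uncovered
stretches over 100 u at either end are reported, advisory only.

## Apex measurement

EICs are extracted in a ±10 ppm window by default — deliberately wider
than the 3 ppm acceptance threshold, so a drifted-but-failing compound is
still *measured* (and fails loudly) rather than falling out of its window
and disappearing. The apex is the scan of maximal summed window intensity,
ties broken toward the earliest retention time; the apex *m/z* is the most
intense centroid of that scan, mirroring how an analyst reads the apex
value in vendor software. An intensity-weighted alternative
(`apex_mode = "weighted"`, weighted mean of per-scan window maxima over the
upper half of the peak) is offered for noisy data.

There is no retention-time library: SST chromatography varies with
whatever column and mobile phases the analyst will use for their samples,
so by default each compound is searched across the whole run and its
global EIC maximum is taken as the peak. An optional per-compound
`rt_ranges` narrows the search when a method is stable enough to warrant
it. Peaks below `min_intensity` (default 1e4 counts, a typical Orbitrap
noise floor; no intensity criterion is part of the SST itself) are
reported as not detected — and an undetected panel compound *fails* the
verdict, because silent non-detection is itself a suitability problem. A
configurable allowlist covers intentionally skipped compounds.

Only centroided MS1 mzML is supported; profile data are rejected with a
clear error rather than centroided internally, because an in-house
centroider would add an uncontrolled error source to a test whose whole
point is metrology.

## The two criteria

**Threshold.** The default mode `"each"` fails a compound if *any*
replicate exceeds 3 ppm — the strict reading of a maximum-deviation
criterion. A `"mean"` mode (failing on the replicate mean) is available
for laboratories that prefer to tolerate single outlying replicates.

**Randomness.** The requirement that deviations be "randomly distributed"
needs a statistical operationalisation; this package uses an exact
two-sided sign test on the signs of the per-compound mean errors (zeros
dropped): with $k$ the larger sign count among $n$ compounds,
$p = \min\!\big(1,\; 2\,P(\mathrm{Bin}(n, 1/2) \ge k)\big)$, flagged when
$p < \alpha = 0.05$. The sign test is distribution-free, matches the
plain-language criterion (no positive or negative bias), and is exact at
panel sizes of 5–13; a one-sample t test on the means is available behind
`bias_method = "t"`. With fewer than 5 compound means the check is
inconclusive and never flags. Because the test is discrete it is
conservative: with 8 compounds it can only reject on a unanimous 8–0 split
(p ≈ 0.008), so its false-alarm rate is well below the nominal 5%.

**Two-injection protocol.** A reduced two-injection SST is accepted unless
(i) a replicate exceeds the threshold, (ii) the within-pair disagreement
for any compound exceeds `adaptive_delta_ppm`, or (iii) a compound is seen
in only one replicate. The default delta of 1.5 ppm is roughly twice the
replicate standard deviation of a well-behaved instrument (~0.7 ppm), so a
pair that disagrees by more is an outlier candidate and a third injection
is demanded. The recommendation on any criterion failure is RECALIBRATE.

## Longitudinal models

Replicate-level rows (not batch means) are the modelling unit — the
natural unit given that each injection is a separate measurement — and
p-values are unadjusted two-sided t tests.

* **Drift model**, per compound:
  `error ~ phase_post * n_batch_injections`. The interaction is the
  within-batch drift rate (ppm per injection): how much extra error a
  post-batch SST carries per injection run since the pre-batch SST.
  Batch length in time is a fixed 20 min/injection convention used for
  display and for the `max_hours` stratification (33 h ≈ 100 injections);
  the regression itself uses the injection count, the quantity actually
  recorded.
* **Calibration model**, pooled or per compound:
  `|error| ~ cal_type + cal_quality + days_since_cal +
  days_since_cal:cal_quality`, reference levels CalMix + FlexMix and GOOD.
  Calibration quality enters as the binary GOOD/POOR flag at 0.3 ppm rms
  (the vendor-recommended acceptance value) by default; a continuous mode
  uses the rms value itself. Long-interval CalMix-only records are
  typically too sparse to support the interaction, so a configurable
  exclusion predicate drops them first (default: CalMix with more than 7
  days since calibration; the cutoff is a package choice, announced via a
  message whenever it removes rows).

Both fits go through `stats::lm`, with the model matrix rank-checked first
so that collinear designs fail naming the offending term instead of
silently dropping it. The test suite verifies the coefficients and
standard errors against an explicit normal-equation solve.

`drift_analysis()` gives the model-free counterpart: per batch and
polarity, Δ = mean(POST) − mean(PRE), stratified by calibration quality,
with a straight-line trend of Δ against batch hours per stratum.
`batch_length_advisor()` encodes the operational rules of thumb: warn past
100 injections (~33 h), and warn from ~20 h (~60 injections) when the
calibration is POOR, where drift can set in earlier.

## Synthetic data: what it does and does not emulate

The generators exist so the entire pipeline is testable with known ground
truth and no instrument data.

`generate_run()` emulates a centroided MS1 run: one Gaussian
chromatographic peak per matching-polarity compound spread over a 7 min
generic gradient, centroid *m/z* displaced by
`(bias + N(0, noise_sd)) ppm` from theory, plus decoy centroid tracks and
a low baseline. Decoys are kept ≥ 50 ppm from every target by default so
standard extraction windows are unaffected; placing them at 15 ppm makes
an interference stress test. Mass noise is Gaussian *in ppm*, matching how
Orbitrap errors are reported and thresholded. Not emulated: isotope
patterns, adduct clusters, ion suppression, profile peak shapes, intensity
drift — so passing tests demonstrate correct *measurement arithmetic*, not
robustness to every real-world pathology.

`generate_history()` draws batches with covariates (injection count
uniform over 10–130 per batch; POOR-calibration fraction 0.2;
CalMix-only fraction 0.3; 0–14 days since calibration) and replicate
errors

`error = mu_c + 0.4·1(CalMix) + 0.5·1(POOR) + 0.01·n_injections·1(POST) + N(0, sd)`

with per-compound true means `mu_c` defaulting to stylized sub-ppm
offsets, and replicate noise 0.7 ppm (positive) / 0.5 ppm (negative) — the
spread magnitudes seen in long-term Orbitrap SST records. The drift slope
applies to POST errors only; the calibration penalties apply to *both*
phases, because the calibration state is constant across a batch — a
pre-batch SST already feels a poor or narrow calibration, while drift by
definition accrues during the batch. (This also means the calibration
model can be estimated cleanly from PRE rows when drift is present.) The
default effect sizes are stylized magnitudes, not claims of fidelity to
any particular instrument. All randomness runs under a locally scoped
Mersenne-Twister seed: a fixed seed reproduces the run or history
byte-identically and the caller's RNG state is untouched.

## Numerical and degenerate-input choices

* EIC windows are closed intervals; at ppm widths the boundary measure is
  zero and half-open handling is irrelevant.
* Apex ties break to the earliest retention time (deterministic verdicts).
* Sample standard deviations use the n−1 denominator and are undefined
  (NA) for a single replicate.
* Sign-test zeros are dropped; an all-zero panel gives p = 1.
* Empty formulas, zero/unknown element counts, zero adduct charge,
  non-positive theoretical masses, mixed polarity or phase in one
  evaluation, duplicate history keys, and absent polarities in summaries
  are all hard errors with named messages.
* Verdicts are invariant under replicate and compound reordering, and
  shrinking all errors toward zero can never turn a PROCEED into a
  RECALIBRATE (the criteria are monotone in |error|; sign patterns are
  scale-invariant).

## Test problem sizes

The simulation-backed tests use sizes chosen to make their statistical
assertions sharp while keeping the suite quick: parameter-recovery
coverage uses 200 histories of 50 batches × 5 replicates/phase;
false-alarm rates use 100 histories (20 batches × 2 replicates) for the
drift interaction and 1000 simulated verdicts for the bias flag, with the
acceptance bound on the interaction rate set at the ~99.5% binomial
envelope of a true 5% rate. End-to-end bias recovery runs full
mzML-write/read round trips at ±3, ±1 and 0 ppm injected bias.

## Known limitations

* Only singly charged (de)protonated species; no isotopologue scoring.
* No retention-time or intensity suitability criteria — out of scope for a
  mass-accuracy test by design.
* The calibration model treats |error| as its response; when true errors
  straddle zero tightly, penalties expressed as mean shifts partially fold
  and the model attenuates them. Baseline offsets of the magnitude real
  instruments show (a few tenths of a ppm to ~1.5 ppm) keep this effect
  small.
* OLS standard errors assume independent replicate errors; batch-level
  shared disturbances beyond the modelled covariates (e.g. unmodelled
  ambient-temperature excursions) would call for mixed models, which are
  deliberately not included.
* Vendor raw files are not read; convert to centroided mzML first.
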
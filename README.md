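# rmrflow

Resting-metabolic-rate extraction and mixed-model inference for open-flow
respirometry of nest-box-housed small mammals.

Urban heat islands expose city wildlife to warmer, more stable temperatures
than nearby natural habitat, and one route by which a synurban endotherm can
profit is a flattened thermal response of its resting metabolism. Testing
that requires a long chain of processing between an oxygen analyser's raw
signal and a habitat × temperature inference, and every link has rules that
affect the answer: baseline drift correction, activity and absence
filtering, diel classification, low-quantile resting extraction,
temperature binning, and information-theoretic model selection. `rmrflow`
implements that chain as a tested R package plus a numbered analysis
workflow, with a forward simulator in place of the unreleased field data so
that every stage can be checked against ground truth.

## What the package computes

**Respirometry.** Oxygen consumption from an open-flow system with the
excurrent-fraction equation

    V'O2 = FR_e (FiO2 − F'eO2) / [1 − FiO2 (1 − RQ)]

with FR_e the excurrent flow (80 l/h at STP), FiO2 = 0.2095, RQ = 0.85, and
energy conversion at 20.37 J/ml O2. Analyser drift is estimated from hourly
5-min ambient zero checks (piecewise-linear interpolation between window
midpoints) and subtracted; out-of-box absence bouts are masked by a
rolling-median detector or an external occupancy record.

**Extraction.** One record per individual × measurement day × clock hour:
the mean of the lowest 30% of occupied VO2 samples (⌈0.3 n⌉ of them), with
civil-twilight day/night classification, the hour before and after official
sunrise/sunset excluded, nest temperature averaged per hour and rounded to
the integer degree (records outside 8–29 °C dropped), nest-temperature
readings more than 3 °C above the enclosure replaced by the median of the
other boxes, and division by linearly interpolated body mass.

**Inference.** Gaussian linear mixed models of mass-specific RMR
(ml O2 h⁻¹ g⁻¹) with fixed terms from {T_nest, habitat, diel phase,
sampling run, housing half, habitat:T_nest, habitat:run} and random
individual intercepts and T_nest slopes (intercepts nested in housing
half). All marginality-respecting subsets are fitted with ML and ranked by
AICc = −2 logL + 2k + 2k(k+1)/(n−k−1); the package reports ΔAICc, Akaike
weights, evidence ratios ER = exp(Δ/2), the 95% confidence set,
per-predictor variable weights, and — for the REML-refitted top model —
coefficients with CIs, signed Cohen's f², ICC and marginal/conditional R².
Univariate cohort comparisons (pooled and paired t, body condition index)
round out the report.

**Simulation.** `simulate_cohort()` inverts the whole chain: it draws
individual random effects, diurnally cycling nest temperatures, activity
bursts, daytime foraging absences and analyser drift, converts true VO2 to
an excurrent O2 fraction by the exact algebraic inverse of the equation
above, and keeps a truth ledger for recovery tests.
`simulate_rmr_records()` draws the hourly analysis table directly from the
mixed model for fast parameter-recovery studies.

## Worked example

```r
library(rmrflow)

# one drift-corrected sample: FiO2 0.2095, F'eO2 0.2085, 80 l/h, RQ 0.85
calib <- calibration_info()
trace <- data.frame(timestamp = as.POSIXct("2018-05-01 15:00:00",
                                           tz = "Europe/Berlin"),
                    o2_fraction = 0.2085, is_zero_check = FALSE)
v <- compute_vo2(trace, calib)
round(v$vo2_ml_h, 2)          # 82.6  (ml O2 per hour)
round(v$energy_j_h / 1000, 2) # 1.68  (kJ per hour)

# simulate an hourly RMR table at the generating coefficients and select
# among candidate mixed models
p <- true_model_params()
records <- simulate_rmr_records(p, seed = 1)
cand <- enumerate_candidates(c("t_nest_int", "habitat", "diel"),
                             "habitat:t_nest_int")
fits <- lapply(cand, fit_lmm, records = records, method = "ML")
sel <- build_selection_table(fits)
sel$table[1:3, c("terms", "delta_aicc", "weight", "evidence_ratio")]
#                                              terms delta_aicc weight evidence_ratio
# 1 diel + habitat + t_nest_int + habitat:t_nest_int      0.000 0.8569           1.00
# 2                                diel + t_nest_int      4.630 0.0846          10.12
# 3                      diel + habitat + t_nest_int      5.369 0.0585          14.65

eff <- effect_sizes(records, sel$fits[[1]]$terms)
round(eff$fit$coefficients["habitaturban:t_nest_int",
                           c("estimate", "se", "ci_low", "ci_high")], 4)
#                         estimate     se ci_low ci_high
# habitaturban:t_nest_int   0.0046 0.0016 0.0015  0.0077
```

The interaction-bearing model wins the AICc ranking and the fitted urban
slope offset (+0.0046 ml O2 h⁻¹ g⁻¹ per °C, CI excluding zero) recovers
the generating value 0.005: the urban group's metabolic response to nest
temperature is flatter than the forest group's.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on a simulated
cohort (7 forest + 13 urban individuals, 3 measurement days each) and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # raw traces, logger series, metadata, truth
Rscript analysis/02_process.R    # drift-corrected VO2 + occupancy masks
Rscript analysis/03_extract.R    # hourly RMR records + filter audit
Rscript analysis/04_fit.R        # AICc selection table + top-model panel
Rscript analysis/05_report.R     # group comparisons + truth recovery
```

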
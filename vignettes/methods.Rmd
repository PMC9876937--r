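---
title: "From raw oxygen traces to habitat x temperature inference: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw oxygen traces to habitat x temperature inference: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmrflow)
```

`rmrflow` turns raw open-flow respirometry traces of nest-box-housed small
mammals into an inference about how habitat of origin modulates the thermal
response of resting metabolism. This vignette documents the model at each
stage, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where the procedure left room.

## The respirometry model

Air is drawn through the nest box at a fixed excurrent flow rate and the
analyser reports the fractional O2 concentration of the outflow every 10 s.
With CO2 neither scrubbed nor measured, oxygen consumption follows

$$V'O_2 = FR_e \frac{FiO_2 - F'eO_2}{1 - FiO_2(1 - RQ)},$$

where $FR_e$ is the excurrent flow (default 80 l/h = 80,000 ml/h, treated
as a volume rate at STP), $FiO_2 = 0.2095$ the incurrent fraction, and
$RQ = 0.85$ the respiratory quotient of a half-fat, half-carbohydrate
substrate mix. Energy conversion uses 20.37 J per ml O2. `stp_correct()`
implements the ideal-gas volume correction
$\dot V_{STP} = \dot V \cdot \frac{273.15}{273.15+T} \cdot \frac{P}{101.325}$
for set-ups whose flow meter reads ambient volumes; the calibration object
carries a `flow_at_stp` switch and a barometric-pressure constant (default
101.325 kPa) because pressure is not logged in the emulated set-up. The
STPD convention (dry air at 0 °C, one standard atmosphere) is assumed.

**Baseline drift.** Each hour the analyser samples ambient air for five
minutes (a "zero check"). The first 60 s of each window are discarded as
analyser washout and the median of the remainder is the window's reference
reading — the median, rather than the mean, shrugs off switching
transients. Drift at the window midpoint is the reference minus $FiO_2$;
between midpoints it is interpolated linearly, beyond the first/last
midpoint held constant. This makes the correction *exact* whenever true
drift is linear between zero-check windows, which is also exactly the drift
family the generator produces — so the round trip is a machine-precision
test, not an approximate one. A window median deviating more than 0.005
from the reference raises a calibration warning (flag, not failure).

**Negative VO2.** Analyser noise can push computed VO2 below zero during
absences. Values within twice the expected VO2 noise SD are clipped to
zero; larger negatives are retained but flagged and excluded from
extraction. The underlying procedure is silent here; clipping at a noise
tolerance keeps the occupancy detector's statistics honest without hiding
genuinely broken samples.

**Absence detection.** An animal out of its box shows near-zero VO2.
`detect_absence()` marks maximal runs of at least 30 min in which VO2 falls
below 0.25 times a 3-h rolling median. The rolling median is floored at
half the day's overall median so that bouts longer than the window (inside
which the rolling median itself collapses to zero) are still recognised; a
day whose overall median is zero is flagged empty and excluded. An external
occupancy record (camera traps, or the simulator's truth ledger) overrides
detection entirely — which is also how the filter-audit tests obtain exact
expected counts.

## Extraction of hourly resting records

Resting metabolism is estimated per individual × measurement day × clock
hour as the mean of the lowest 30% of occupied samples. The retained count
is $\lceil 0.3 n \rceil$ — the ceiling is a choice (the rule's rounding is
otherwise unspecified) and guarantees a non-empty subset for any $n \ge 1$;
ties at the cutoff break by earlier timestamp. Hours with fewer than 6
usable samples (one minute of data) are dropped.

Day/night classification uses civil twilight (sun 6° below the horizon) at
the site coordinates (defaults: Hamburg, 53.5511° N, 9.9937° E), while the
hour before and after *official* sunrise/sunset (zenith 90.833°) is
excluded as a metabolic transition period. Both definitions are honoured
literally, as stated, even though at this latitude the ±1 h exclusion
swallows the civil-twilight band itself. Solar times come from the NOAA
solar-position equations implemented in `R/solar.R` (no installed package
provides them); tests cross-check the event times against an independently
coded low-precision ephemeris by verifying the sun's altitude at each
event. Polar day/night raises an error rather than guessing.

Nest temperature is averaged over the clock hour and rounded *half-up* to
the nearest integer degree ("nearest integer" alone does not fix the
half-way rule; half-up avoids R's banker's rounding producing
non-monotone bins). Records outside 8–29 °C are dropped. A nest reading
more than 3 °C above the concurrent enclosure reading indicates an animal
sitting on the logger; it is replaced by the median of the other boxes'
concurrent non-outlying readings (nearest-neighbour alignment within
5 min), or dropped with a warning when no other box reports. Body mass is
interpolated linearly between the housing start and end weighings.

One record per day × hour is kept (no pooling of equal-temperature hours
across days): the phrasing "per individual and hour of measurement day"
reads most naturally as one record per day-hour, and pooling across days
would blur the housing-half covariate. The audit log counts exclusions per
filter (absence, transition, too-few-samples, temperature range,
replacements) so that synthetic-cohort tests can reconcile them against the
generator's ledger exactly.

## The mixed model and multimodel inference

The response is mass-specific RMR (ml O2 h⁻¹ g⁻¹). Fixed-term candidates
are T_nest (integer °C), habitat (forest reference), diel phase (day
reference), sampling run (1–4), housing half (second reference), and the
interactions habitat:T_nest and habitat:run. The random structure is
`(1 + t_nest_int | id) + (1 | housing_half:id)`: individual random
intercepts and temperature slopes, with additional intercepts for
individual-within-housing-half. That is one concrete reading of "different
intercepts and slopes per individual, individual nested in housing half" —
what the slopes vary over is unstated in the emulated procedure, and T_nest
is the only continuous predictor, so slopes on T_nest are assumed. Both the
random slope and the nesting are switchable (`random_slope`,
`nest_housing`). `housing_half` may appear in fixed terms and the random
nesting simultaneously; the collinearity this invites is tolerated, not
fatal.

Model selection fits every marginality-respecting fixed-term subset (52
candidates for the full term set) with ML; the reported top model is
refitted with REML. The parameter count $k$ in
$AICc = -2\log L + 2k + 2k(k+1)/(n-k-1)$ counts fixed coefficients plus
all variance/covariance components plus the residual variance (lme4's
log-likelihood df). Akaike weights, evidence ratios $ER_i = \exp(\Delta_i/2)$,
the 95% confidence set (smallest top-ranked prefix with cumulative weight
≥ 0.95) and per-predictor variable weights follow the standard
information-theoretic definitions; weights are normalised over the
candidate set actually fitted, so absolute weights depend on that set's
size and only Δ and ER are set-size-invariant. Model averaging is
deliberately absent (interactions make averaged coefficients
uninterpretable).

Fitting is backed by `lmerTest::lmer` with the bobyqa optimiser; on a
non-convergence message the model is refitted once from a perturbed start,
and if messages persist the fit is retained with a warning and a
`converged = FALSE` flag rather than aborting a 52-model batch. Singular
fits (boundary variance estimates, common under small random-slope
variance) are likewise retained and flagged. Confidence intervals are Wald
(±1.96 SE) with Satterthwaite df reported alongside; the CI method is a
convention choice, not an attempt to match a stated one.

**Effect sizes.** Marginal and conditional R² follow the
Nakagawa/Johnson variance decomposition, with the per-observation
random-effect variance computed as $\mathrm{mean}\,\mathrm{diag}(Z\Sigma Z')$
(valid under random slopes). ICC is the summed random-*intercept* variance
over the summed random variance plus residual. Cohen's
$f^2(X) = (R^2_m - R^2_{m,-X})/(1 - R^2_m)$ from drop-one refits (the
dropped set includes any interaction containing $X$), and the reported
value carries the sign of $X$'s coefficient (for factors, the largest-|coef|
level). Signed f² is nonstandard but mirrors the reporting style the
package emulates; the magnitude is the conventional part. Note a known
attenuation: with individual random T_nest slopes in the model, dropping
the fixed T_nest term lets the slope variance absorb much of the common
slope, so f² for T_nest is smaller than its coefficient's Wald statistic
would suggest.

## What the generator emulates — and what it does not

`simulate_cohort()` draws, per individual: a habitat (7 forest, 13 urban by
default), a sampling run (1–4, habitats interleaved), housing dates
(15 days, runs 3 weeks apart from early April), starting mass
(N(371.4, 27.0²) g forest, N(334.2, 19.0²) g urban) with linear gain over
housing (total gain N(4.9, 13.7²) / N(9.6, 13.7²) g), a nose–anus length
(N(22, 0.8²) cm), and random intercept/slope effects. Per measurement day
(3 per individual, giving 60 individual-days) it generates:

* a 10-min logger series: nest temperature as a sinusoid (mean 16 °C,
  amplitude 5 °C, peak 15:00) plus day effects (SD 2.5 °C) and noise
  (SD 0.5 °C), so that realised values essentially span the 8–29 °C
  analysis range; enclosure temperature is the nest series minus a 1 °C
  insulation offset; occasional animal-on-logger spikes exceed the +3 °C
  outlier threshold to exercise the replacement rule;
* a 24-h, 10-s analyser trace starting 14:00 local: true instantaneous VO2
  is `true_rmr(...) × mass × activity multiplier` (zero when absent), the
  excurrent fraction is the exact algebraic inverse
  $F'eO_2 = FiO_2 - V'O_2[1 - FiO_2(1-RQ)]/FR_e$, and the signal adds
  piecewise-linear drift (random-walk knots at the zero-window midpoints,
  held constant across each window so the hourly correction is exact by
  construction) plus Gaussian noise (SD 1e-5 O2-fraction, about 1% of a
  resting depletion);
* behaviour: daytime foraging absences totalling N(3.1, 2²) h (forest) or
  N(4.7, 2²) h (urban) per day in 1–3 bouts, and activity bursts at
  1.5 h⁻¹ lasting 3–10 min with multipliers U(2, 4). These are an
  *emulation* sized to the reported time-outside summaries, not an
  estimated behaviour model.

The generating coefficients default to the study system's fitted values:
intercept 0.612, T_nest slope −0.010, urban offset −0.103, urban slope
offset +0.005, night offset +0.051 (all ml O2 h⁻¹ g⁻¹ or per °C), run
offsets (0, 0.050, 0.075, −0.091). The variance components
(`sd_individual_intercept` 0.07, `sd_individual_slope` 0.002,
`sd_residual` 0.08) were derived once from the reported variance
decomposition — an ICC near 0.42 with marginal/conditional R² near
0.30/0.60 implies a random-to-residual variance ratio near 0.73 on a total
variance set by the coefficient scale — and are not tuned thereafter.

Known departures from real data: residuals are independent across hours
(no within-day autocorrelation structure is specified anywhere, so none is
imposed — a flagged choice, not a claim about the animals); there is no
humidity effect on metabolism, no CO2 channel, no chamber washout dynamics
(the configurable lag shift defaults to 0; at 80 l/h through a ~12 L box
the time constant is ~9 min, which blurs but does not bias hourly means);
no torpor (the emulated species is homeothermic year-round); and
temperature enters generation through the same integer-rounded value the
extraction uses, so tests isolate filter behaviour from binning error.
Passing recovery tests therefore show the chain is *self-consistent* and
unbiased under its own assumptions — they cannot certify behaviour under
autocorrelated residuals or sensor pathologies the generator does not
produce.

## Numerical choices and degenerate inputs

* Zero-variance groups in t-tests: pooled SD of 0 yields t = 0 for equal
  means and a flagged infinite t otherwise; constant paired differences are
  flagged degenerate.
* `aicc()` requires $k < n - 1$; the guard trips before a meaningless
  correction term can go negative.
* Candidate enumeration is deterministic (size, then lexicographic), so
  selection tables are reproducible run-to-run.
* All randomness flows from a single integer seed per cohort; reruns are
  byte-identical, and derived seeds stay below 2³¹.
* An hour with mixed diel classes after transition exclusion (possible only
  at the exclusion boundary) takes the majority class of its usable samples.

## Problem sizes used by the test suite

Exactness tests (round trip, baseline correction) run on 1–2 individuals ×
1 day of full-resolution traces. Parameter recovery runs 100 record-level
cohorts at the study's size (20 individuals, 60 individual-days, ~1,100
records) through the single interaction-bearing model; the AICc-parsimony
check compares the with/without-interaction pair over 30 null cohorts; the
full raw-trace pipeline runs end-to-end at 6 individuals × 2 days in the
suite and at full size in `scripts/acceptance.R`. These sizes are the
package's own balance of statistical resolution against a suite that a
maintainer will actually run; the acceptance script's recovery criterion
(sign and 20% mean accuracy over 100 replicates) is insensitive to
doubling any of them.

## Limitations

* Absolute Akaike weights depend on the candidate-set size and are not
  comparable across differently sized dredges; compare Δ and ER instead.
* With 20 individuals over 4 runs × 2 habitats, run-related terms sit on
  1–3 animals per cell and individual random effects can masquerade as
  run effects in any single cohort; selection occasionally promotes
  habitat:run spuriously. Across replicates the parsimony property holds.
* The f² attenuation under random slopes (above) means signed f² values
  for slope-carrying predictors understate their Wald evidence.
* Extraction's lowest-30% mean is a biased-low estimator of the generating
  resting rate in the presence of noise; with the default noise scale the
  bias is far below the residual SD, but it is not zero.
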
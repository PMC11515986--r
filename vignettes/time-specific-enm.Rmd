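---
title: "Time-specific presence-absence niche models for tick questing activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-specific presence-absence niche models for tick questing activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

Questing — the host-seeking behaviour in which a tick climbs vegetation and
waits for a passing host — is strongly seasonal, and it is questing ticks,
not resident populations, that expose people and animals to tick-borne
pathogens. `questenm` models the probability of detecting questing ticks as
a function of *short-term* climatic conditions, specific in both space and
time: each sampling visit is matched to the 8-day climate summary of the
grid cell and calendar period in which it took place, and the fitted model
is transferred back to every 8-day layer to produce weekly suitability
surfaces.

Two features distinguish this workflow from common correlative
species-distribution modelling:

* **True absences.** Records come from repeated, protocol-controlled visits
  to fixed sites, so a non-detection is informative. Models are binomial
  GLMs contrasting detections with non-detections; no pseudo-absence
  sampling is involved, and the package deliberately provides no
  presence-only mode.
* **An explicit sampling universe.** Field visits only happen under
  conditions suitable for collecting (roughly 2-32 °C and dry weather), so
  the sampled days are themselves environmentally biased. The niche-signal
  tests therefore compare detections against *all sampling events* rather
  than against climate at large.

## Data model

A presence–absence record is a unique combination of site, date and life
stage (`all`, `larva`, `nymph`, `adult`), with `detected` true if at least
one matching individual was collected during that visit. Assembly from raw
event lists is idempotent and produces exactly one record per visit per
stage. Dates are ISO-8601; day-of-year arithmetic uses the proleptic
Gregorian calendar, so leap years are honoured throughout.

Gridded climate uses six daily variables — maximum and minimum air
temperature (°C), precipitation (mm/day), shortwave radiation (W/m²),
water vapour pressure (Pa) and day length (hours) — on a regular
longitude/latitude grid with the origin at the upper-left corner and
half-open cell intervals. Because no raster I/O backend is assumed, stacks
are held in memory (`weekly_env`, `period_stack`) and serialize to a
documented plain-text CSV format.

### The 8-day calendar

Daily values are averaged (all variables, including precipitation) into 46
fixed periods per year, labelled by their zero-padded starting Julian day
(`001`, `009`, …, `361`). The last period absorbs the remainder of the
year: 5 days in a common year, 6 in a leap year, with day 366 belonging to
period `361`. The periods partition every year exactly, which the test
suite verifies by commuting compositing and extraction.

## Predictors: correlation screen and PCA

The six variables are strongly collinear (pairs such as `tmax`/`tmin` and
`tmin`/`vp` routinely exceed |r| = 0.8). After flagging pairs above the
configurable threshold (default 0.8), all six variables are replaced by
their six principal components.

Choices we had to make that the problem statement leaves open:

* **Correlation-matrix PCA.** The variables carry incommensurate units
  (°C, mm, W/m², Pa, h), so each is centred and scaled to unit variance
  before rotation.
* **Fitting sample.** The transform is fitted on the pooled cell-by-period
  values of all study years — the full modelled domain, not just the
  record locations — subsampled to at most 200,000 points with a recorded
  seed so that projection of any week of any year uses one fixed
  transform.
* **Sign convention.** Each loading column is flipped so its
  largest-magnitude entry is positive. Eigenvector signs are otherwise
  arbitrary, and fixing them makes projections identical across runs and
  platforms.

One idempotence caveat follows from the correlation-matrix choice:
refitting a PCA on already-rotated scores rescales them to unit variance,
making all eigenvalues equal and the rotation indeterminate, so "refit
gives the identity" is not a valid invariant here; orthonormality and
exact back-rotation are tested instead.

## Niche-signal tests

Before any model is fitted, the package asks whether detections are
environmentally non-random *given the sampling universe*:

* **Univariate randomization.** With N records of which x are detections,
  the null distribution of a statistic (mean, median, sd, range) of a
  variable is built from `n_randomization` (default 1000) random draws of
  x records from all N. The observed statistic among detections is
  classified `higher`/`lower` if it falls beyond the empirical 2.5% tails
  (type-7 quantiles; ties resolve to not-significant). Mean and median
  characterize niche position, sd and range niche breadth. All statistics
  of all variables share one set of row draws, so the summary table is
  internally consistent. Both x = 0 and x = N are errors: a species
  present in every sample manifests no niche signal in these data.
* **PERMANOVA.** A two-group permutational MANOVA (detections versus
  non-detections) on standardized variables with Euclidean distance;
  pseudo-F from the sums-of-squares partition and p by label permutation
  (default 999, p ≥ 1/(n+1) by construction). The problem could also be
  framed as detections versus the *pooled* universe; both contrasts are
  implemented (`contrast = "vs_all"`), with the estimable two-group form
  as the default. The centroid-based partition used internally equals the
  pairwise-distance formulation for Euclidean distance, which the tests
  check against both a hand oracle and `vegan::adonis2`.

## Model calibration and the four-filter cascade

Candidates are **all** non-empty subsets of the linear and quadratic terms
of the predictors: 2^12 − 1 = 4095 models for six PCs. Each candidate is

1. fitted to the full data by maximum likelihood (binomial GLM, logit
   link; AIC = 2k − 2ℓ with k counting the intercept), and
2. evaluated by class-stratified k-fold cross-validation (default k = 10,
   one recorded fold draw shared by all candidates): per fold, the model
   is refitted on the training folds, the held-out records are scored,
   and AUC plus sensitivity/specificity/TSS at the *training-data* maxTSS
   threshold are recorded. Reported metrics are fold means; the reported
   per-model threshold is the full-data maxTSS threshold, reconciling
   fold-wise evaluation with a single printed threshold per model.

Selection then applies four filters in order: (1) all quadratic
coefficients strictly negative on the full-data fit — quadratic-logistic
responses are then unimodal, a biological-realism constraint; models
without quadratic terms pass vacuously, and non-converged fits (complete
separation, aliasing) are dropped here with a reason; (2) cross-validated
AUC ≥ 0.5; (3) cross-validated TSS ≥ 0.4; (4) ΔAIC ≤ 2 relative to the
minimum AIC *among survivors of filters 1–3*. Akaike weights
w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2) are renormalized over the final set, and
the consensus prediction is the weighted mean of member probabilities —
always inside the envelope of member predictions.

Numerical details: the maxTSS threshold scans midpoints between
consecutive sorted unique predictions with "≥ threshold" meaning predicted
presence, breaking ties toward the lowest threshold; complete separation
is detected as a perfect fit (max |μ − y| < 10⁻⁶); leave-one-out
evaluation, where no held-out fold contains both classes, falls back to
pooled held-out predictions scored once at the full-data threshold.

## Projection and post-processing

The ensemble is transferred to every weekly PC layer (46 × years
suitability surfaces per life stage). Post-processing follows three rules:

* **Moving window.** Each period becomes the mean of the previous, focal
  and following periods, ordered chronologically *across* year boundaries
  (period `361` of one year neighbours period `001` of the next); the ends
  of the study series use the available two-period window rather than
  inventing data.
* **Monthly averages.** Month values are day-weighted means of overlapping
  periods — a period starting Julian day 25 contributes 7 days to January
  and 1 to February — and the weights of each month sum exactly to its
  number of days.
* **Site series.** Per-site suitability series are cell lookups, with
  optional cross-site mean overlays of raw variables for phenology plots.

## Extrapolation diagnostics (MOP)

Transfers beyond calibrated conditions are flagged with the
mobility-oriented parity metric. For each projection cell and period, the
distance is the mean Euclidean distance to the nearest `percent` (default
5%) of calibration points, computed in the model's own predictor space
(the PCs) standardized by calibration standard deviations; the strict mask
flags any cell-period with at least one variable outside the calibration
min–max range. The calibration reference is the set of annotated records
used to fit the models, not the whole study region. Monthly MOP summaries
day-weight the *binary* strict mask, so a monthly value is the fraction of
the month a cell spent outside calibration ranges. Reference space and
percent are deliberate, configurable choices: the metric's source
formulation leaves them open, and ours are recorded in every output
rather than presented as canonical.

## The synthetic study system

Because longitudinal tick-surveillance data of this kind are not publicly
deposited, the package ships a generator that emulates the essential
structure of the field study and the daily-climate inputs:

* A regular grid over the central Great Plains (default 20 × 20 cells,
  103–94.43° W, 33.62–40° N), 10 sites, and roughly 9 visits per site and
  year over 2–3 years, yielding approximately 180 visits with ~70% species
  prevalence — the scale of the motivating surveillance programme.
* Temperature follows a sinusoid in day of year (defaults: `tmin` mean
  9 °C, amplitude 12 °C, phase 105 d, so the warm peak falls in mid-July)
  plus a west–east gradient, daily noise, and a strictly positive diurnal
  range so `tmax ≥ tmin` holds by construction. Precipitation is truncated
  at zero. Vapour pressure is a Magnus transform of `tmin` plus noise and
  radiation a linear function of day length plus noise, reproducing the
  observed collinearity structure; day length itself is deterministic
  daylength geometry (via `geosphere`), noise-free as in gridded-climate
  products.
* Visits are drawn only on days passing the sampling gate (2–32 °C and no
  precipitation), reproducing the sampling-universe bias; wind and dew,
  which real protocols also gate on, are not simulated because no
  modelled variable represents them.
* Detections are Bernoulli draws from a known unimodal niche on PC space
  (`true_niche`, all quadratic coefficients ≤ 0), with per-stage intercept
  offsets (larva −0.4, nymph 1.4, adult 0.4 on a shared PC1 niche) chosen
  once to land near study-scale prevalence.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: spatially and temporally autocorrelated
weather (storm fronts), tick population dynamics and between-year
carry-over (detection probability here is a memoryless function of
concurrent climate), observer effects, and landscape covariates. Parameter
recovery and calibration results on synthetic data show the machinery is
correct, not that the climate-only model is ecologically sufficient.

## Reproducibility and problem sizes

Every random draw derives from one master seed through fixed per-stage
sub-seeds (simulation, site placement, visit draws, detections, PCA
subsample, folds, randomization, permutation), all below 2³¹ and recorded
in the run manifest together with record counts, filter-survivor counts
and numeric fingerprints of all gridded outputs; re-running a
configuration reproduces the manifest exactly.

The shipped examples, tests and the acceptance script use a 20 × 20 grid,
two study years, 10 sites and the full 4095-candidate calibration —
roughly a minute of computation — with smaller 10 × 10 or 6 × 6 grids and
reduced predictor sets where only the mechanics are under test. These
sizes are the package's own choices for a fully reproducible desk-scale
study; the machinery itself is size-agnostic, and nothing but memory and
patience changes at the ~1-km, three-year scale of a real deployment.

## Known limitations

* Suitability maps describe conditions associated with *questing
  activity*, not tick-borne-disease risk, and strictly extrapolated
  cell-periods (MOP mask) should be interpreted with caution.
* All inputs must share one grid; there is no reprojection or resampling.
* The GLM family is fixed to quadratic-logistic responses; no
  interactions, cubic terms or regularization.
* Snow water equivalent, available in gridded-climate products, is
  excluded throughout: sampling never occurs under snow cover, and its
  inclusion confounds rather than informs these models.
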
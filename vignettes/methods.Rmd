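---
title: "Methods: models, defaults, and boundary conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults, and boundary conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearcpet)
```

This vignette documents the modeling assumptions behind each module,
the default parameter values and why they were chosen, and every place
where a rule has a boundary whose open/closed side matters.

## 1. Motion-context inference

A smartwatch records HR opportunistically: densely during activity,
sparsely at rest. The classifier exploits this. Device-supplied context
labels are taken as authoritative. An unlabeled record is classified
**nonactive** if and only if both hold:

1. the recording interval to the adjacent HR record of the same
   participant-day **exceeds 60 s** (strictly), and
2. the clock hour containing the record has **fewer than 30 steps**
   (strictly).

Conventions adopted where the rule is underdetermined:

- The interval is taken to the *preceding* record; the first record of
  a participant-day uses the *following* interval instead, and a
  single-record day counts as a long interval. Rationale: the preceding
  gap reflects the state leading into the record, which is what the
  sparse-at-rest mechanism generates; the fallback keeps day-leading
  records classifiable without borrowing across midnight.
- "The hour" is the *clock* hour (floor to :00), not a centered 60-min
  window, so condition 2 is a pure lookup into the hourly step table
  and the step and HR pipelines agree on hour identity.

The synthetic generator plants the interval signature explicitly:
active-context intervals are log-normal with median
`gap_active_median_s = 40` truncated below the 60-s cut; sedentary
intervals have median `gap_sedentary_median_s = 420` truncated above
it. The log-SDs are calibrated so the *untruncated* distributions cross
the cut with probability 1% — matching the "99% below / 99% above one
minute" separation the classifier assumes. A configurable
`gap_leakage` (default 0.01) lets each draw come from the wrong side of
the cut, and `step_leakage` does the same for hourly steps, so
classifier sensitivity and specificity can be measured against planted
truth (both exceed 0.98 at the defaults; with leakage 0 agreement is
exactly 100%). Because record timestamps are quantized to whole
seconds, long-side interval draws are truncated at 61 s rather than
60 s — otherwise flooring could collapse a 60.4-s interval onto the
boundary and flip its classification.

One deliberate realism limit: activity is generated at whole-clock-hour
resolution (a first-order Markov chain over hours with
`active_fraction = 0.25` and mean active bout 2 h), so the step and
interval signatures of an hour always agree. Real streams mix contexts
within hours; the generator's per-record count is also higher than a
typical consumer device. Both are acceptable because the generator's
job is to provide *separable planted truth*, not device emulation.

## 2. Person-day and participant filters

- A day is a **valid wear day** when wear time (distinct
  record-bearing clock hours) is at least 5 h — days with *less than*
  5 h are excluded, so exactly 5 passes.
- A day is a **valid step day** when it is a valid wear day and daily
  steps are at least 1000 — *less than* 1000 excludes, exactly 1000
  passes.
- A participant enters the HR (steps) analysis with **30 or more**
  qualifying days — inclusive, 30 passes. The primary sample is the
  intersection. The HR inclusion additionally requires at least one
  nonactive record, since the phenotype is undefined without one.
- Nonactive HR is the **unweighted mean over records** (not a mean of
  daily means): the phenotype is a property of the record population,
  and day-weighting would up-weight sparse days.
- Peak RER **at or above 1.05** counts as adequate effort (inclusive).

## 3. CPET indices

All windowed statistics use a **trailing 30-s window, right-closed**
(`(t−30, t]`), over the irregular breath-by-breath grid, with at least
3 samples per window; "peak" statistics take the best window whose end
lies in the final 60 s of the ramp. Windowed medians make the indices
robust to single-breath outliers; the brute-force oracles in the test
suite pin the exact tie and boundary handling.

- **Peak VO2**: highest such median of VO2 (mL/kg/min).
- **Percent-predicted peak VO2** uses the Wasserman–Hansen reference:
  males `weight × (50.72 − 0.372·age)` mL/min, females
  `(weight + 43) × (22.78 − 0.17·age)` mL/min, converted to per-kg.
- **VAT (V-slope)**: continuous two-segment least squares of VCO2 on
  VO2 over exercise, breakpoint candidates restricted to interior
  sample values below the 90th VO2 percentile, and the upper slope must
  exceed the lower (the defining signature of buffering CO2). Before
  fitting, both gas channels are smoothed with a 10-s centered moving
  average: breath noise sits in the regressor (VO2), and
  errors-in-regressor attenuation otherwise biases the detected
  breakpoint downward by about 1 mL/kg/min at the default noise level.
  With smoothing, mean absolute recovery error on noisy synthetic
  sessions is ≈ 0.77 against an a-priori tolerance of 1.0 mL/kg/min
  (the tolerance was fixed before measuring and kept). When the broken
  fit improves residual sum of squares by less than 2% over a single
  line, the session is flagged `vat_low_confidence`.
- **VE/VCO2 nadir**: lowest 30-s median of the per-sample VE/VCO2
  ratio over unloaded plus ramp. The ratio is formed per breath and
  then median-smoothed (rather than a ratio of smoothed series), so the
  statistic is a median of observed ratios.
- **Percent-predicted maximum HR** uses Tanaka (208 − 0.7·age).
- **SBP/W slope** is `(peak SBP − rest SBP) / peak workload`; a
  negative value raises the hypotensive-response flag.

## 4. Association battery

Exposures are standardized to mean 0, SD 1 **within each model's
complete cases** with the population SD (denominator *n*); peak VO2 and
VAT VO2 are log-transformed first (right-skewed, multiplicative
physiology). Population rather than sample SD is a convention choice
with no effect at analysis sizes; it makes "per SD" exact for the
analyzed sample. Betas are outcome units per SD of (possibly logged)
exposure.

Benjamini–Hochberg adjustment is applied **within each outcome-by-model
family of six** exposures: the six indices measure overlapping facets
of one construct and the two outcomes/models answer distinct questions,
so the family is the set of simultaneous claims made per model. The BH
map is validated against a from-scratch step-up oracle; note it is a
decision-level correction — thresholding adjusted values at α
reproduces the step-up rejection set exactly, but the adjustment map
must not be re-applied to its own output.

Effect modifiers: sex; age split at the median with **ties assigned to
the younger group** (a fixed convention so the split is deterministic);
BMI categories `[−∞,25) / [25,30) / [30,∞)` with boundaries belonging
to the upper category, matching clinical convention. Interactions are
tested by the joint F-test between the fully adjusted models with and
without the exposure-by-modifier term; strata below 30 complete cases
are reported missing rather than fitted.

Sensitivity variants: effort-restricted sample (RER ≥ 1.05);
nonactive-HR model 2 additionally adjusted for daily steps; the
daily-steps analyses on the larger sample meeting only the step
criterion; and the role swap, in which standardized daily steps is the
independent variable and each (log-transformed where flagged) CPET
measure the dependent variable, keeping the daily-steps covariate set
(including wear time) since the watch phenotype is the exposure whose
measurement process needs adjustment.

## 5. Synthetic population defaults

Defaults in `cohort_params()` describe a middle-aged community cohort:
age 53 (SD 9), 59% female, 91% white, BMI ≈ 28, nonactive HR 73 bpm
(SD 6), daily steps ≈ 7300 (SD ≈ 2800), median wear 14 h, waking
window 07:00–22:00. The latent fitness SD is 1, with planted links of
**−2.4 bpm per SD** on nonactive HR and **+1268 steps per SD** on daily
steps — effect sizes at which the full battery reproduces the expected
sign pattern (three VO2-based measures negative against HR, positive
against steps) in essentially every seeded run at n = 300. CPET noise
defaults (`noise_sd = 0.8` mL/kg/min per channel) are large enough to
exercise the V-slope smoothing but keep breath series physiologic; the
generated RER ramps from 0.82 to ≈ 1.07 at peak so a realistic minority
(~4%) of sessions fail the effort cut.

`simulate_association_data()` is a separate calibration simulator: it
plants a coefficient on the *population-standardized* exposure so the
fitted model's estimand equals the planted value exactly, which is what
the type-I-error (0.05 ± 0.02), CI-coverage (93–97%) and recovery
checks in the acceptance suite require.

## 6. Determinism

Every generator call derives independent child seeds from the single
configured seed via a string-hash (`seed`, stream label) scheme, so
adding a stage never perturbs another stage's draws. `run_pipeline()`
with a fixed configuration is byte-identical across runs, and the
manifest records the seed, a configuration hash, and md5 digests of
every output table.

```{r example}
p <- cohort_params(n_participants = 30, follow_up_days_range = c(32, 34),
                   seed = 7)
out <- run_pipeline(pipeline_config(
  params = p, analysis = analysis_config(models = "model1")))
out$flow
```
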
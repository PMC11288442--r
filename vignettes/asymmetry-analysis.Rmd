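---
title: "Quantifying vertical movement asymmetry in trotting horses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vertical movement asymmetry in trotting horses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equisym)
library(dplyr)
```

## The measurement model

At trot, a horse's head and pelvis each describe two vertical oscillations
per stride — one per diagonal step. In a perfectly symmetric horse the two
minima (and the two maxima) within a stride sit at the same height. Lameness
or other left–right differences unbalance them, and the per-stride
differences between the two minima and between the two maxima are the four
standard asymmetry parameters:

* `HDmin`, `HDmax` — head minimum / maximum position difference (mm),
* `PDmin`, `PDmax` — the pelvic analogues (mm).

All four are signed: under this package's convention a stride starts at the
right-pastern reference event, the first extremum of each kind belongs to
the right diagonal step, and the difference is right-minus-left, so positive
values indicate right-limb-associated asymmetry. Only the *interpretation*
of the sign is fixed by convention; every classification rule below uses
absolute values, so the subtraction order cannot change any prevalence
result.

A trial (several dozen strides in one condition) is summarized by the mean
and SD of each parameter. A horse is **asymmetric** on a surface when at
least one parameter satisfies

* |trial mean| strictly above its threshold — 6 mm for head, 3 mm for
  pelvic parameters (the clinically used values), **and**
* stride-level SD strictly below that |mean| (the asymmetry must be
  consistent, not noise).

Horses whose |mean| exceeds a threshold but whose SD does not fall below it
are flagged *high variability* and classify as symmetric. A second flag
marks horses beyond **double** thresholds (12 mm / 6 mm); by default it
inherits the SD condition, and the count without that condition is reported
alongside.

The **Total Asymmetry Score** collapses the four parameters into one
magnitude:

$$\mathrm{TAS} = \tfrac{|HD_{min}|}{2} + \tfrac{|HD_{max}|}{2} +
  |PD_{min}| + |PD_{max}| \quad (\mathrm{mm}).$$

Halving the head terms equalizes contributions, because the head threshold
is exactly twice the pelvic one; a trial sitting at all four thresholds
scores $3+3+3+3 = 12$ mm regardless of parameter. For lungeing, the signed
trial means of the left and right circle are first summed per parameter and
the formula is applied to the sums, so asymmetries that reverse with
direction cancel.

## The processing chain

1. **Stride segmentation** (`segment_strides()`): rising midline crossings
   of a periodic reference signal (the right-pastern sensor), linearly
   interpolated between samples. Durations are exact on clean signals;
   a 4-fold spread in cycle lengths raises an error rather than producing
   nonsense strides.
2. **Parameter extraction** (`stride_asymmetries()`): local extrema by
   3-point comparison, plateau ties resolved to the earliest sample.
   Strides without exactly two minima and two maxima per trace are flagged
   and excluded from summaries — never silently dropped. No smoothing is
   applied by default (appropriate for clean synthetic signals); a
   moving-average window of roughly a tenth of a stride is available for
   noisy traces.
3. **Outlier removal** (`remove_stride_outliers()`): each stride's head
   parameter pair is compared with the trial average via the Mahalanobis
   distance; strides at 3 or more SD (inclusive) are removed and the
   procedure repeats until stable, which makes it idempotent and
   terminating. The distance is bivariate over (`hd_min`, `hd_max`) by
   default, matching the standard automatic head-parameter cleaning; a
   4-parameter variant and a plain univariate 3-SD screen are options, and
   a singular covariance (e.g. a constant parameter) automatically drops to
   the univariate screen, recorded in the QC report.
4. **Trial inclusion** (`apply_inclusion_rules()`): lunge trials need at
   least 25 strides; straight-line trials at least 20, except that 16–19
   strides are accepted when every parameter has SD < |mean|. Trials with
   exactly 20 strides pass the ordinary rule, so the exception range is
   half-open.
5. **Classification and reports** (`classify_trials()`,
   `population_summary()`, `concordance_summary()`,
   `exceedance_report()`): prevalence overall and per discipline,
   double-threshold proportions (denominator: all classified horses),
   high-variability counts, hard/soft concordance in three exhaustive
   disjoint categories, and descriptive tables of above-threshold values
   with top-quartile statistics.

All threshold comparisons are strict, following the rule's wording
("exceeds", "less than"). Percentages are reported to one decimal.

### Top-quartile convention

For the descriptive tables, the "top quartile" is the set of values
strictly greater than the linear-interpolation (type 7) 75th percentile.
This convention is not uniquely determined by the descriptive statistics it
must reproduce — fixed top-`ceiling(n/4)` and top-`floor(n/4)` conventions
are close competitors — so it is exposed as an option
(`quartile_type`) rather than hard-coded. On distinct values it yields 10
of 39 and 9 of 37, consistent with the reference descriptive tables.

## The sidedness association stage

Riders' perception of their horse's sidedness is recorded in a
five-question instrument (graded overall sidedness; weaker hind limb; rein
leaning; circle drift; rider's own handedness difficulty). Before
modelling:

* overlapping questions are reduced to the member with the fewest
  non-answers, ties resolved by declared order (`reduce_questions()`) —
  which questions overlap is a design input, not inferred from data;
* questions where more than half of the responders perceive no sidedness
  are excluded;
* directional answers are binarized (left/right to "yes"), and the rare
  "severe" grade of the overall question is merged into "moderate"
  (`binarize_response()`, `merge_sidedness_grades()`).

`fit_association()` then fits, per question and response variable, a linear
mixed model: the absolute asymmetry magnitude (|parameter mean| or TAS) as
response, the questionnaire factor plus mean stride duration (a speed
proxy) as fixed effects, and a random intercept per rider, one observation
per horse. Type III tests use Satterthwaite degrees of freedom; pairwise
group comparisons use estimated marginal means with Tukey adjustment
(configurable to none). For the lunge TAS the stride-duration covariate is
the mean of the two lunge trials' mean durations.

Numerical choices, made once:

* **Box-Cox trigger.** The refit triggers when the absolute skewness
  (bias-corrected, type 2) of the residuals exceeds 1.0; lambda is chosen
  by maximum likelihood on a 0.1-spaced grid over [-2, 2]; 1 mm is added
  before transforming because magnitudes can be zero. The trigger operates
  on the mixed-model residuals, after the rider term has absorbed its share
  of variance.
* **Singular fits.** When the rider variance estimates to zero (or the
  model cannot be fitted, e.g. one horse per rider), the model falls back
  to fixed effects only. The fallback is flagged in the result and the
  print method — in that limit the coefficients equal ordinary least
  squares, which is tested.
* **Degenerate responses.** A zero-variance response is flagged
  `degenerate`; no significance is ever reported for it.

Because the response is a magnitude (a folded, often bimodal mixture of
near-symmetric and clearly asymmetric horses), the F-approximation is
mildly liberal in the far tail: across 1000 null replicates at the study's
design size the sidedness term rejects at ~0.057 for nominal 0.05 and
~0.02 for nominal 0.01. The operating characteristics are checked by
simulation in the test suite with calibration bands at conventional working
levels rather than by a goodness-of-fit significance test, whose power at
1000 replicates would flag exactly this expected approximation error.

## What the simulators emulate — and what they do not

Two generators make every stage testable without any external data.

**Trace level** (`gait_config()`, `simulate_trial_traces()`): per stride,
vertical displacement is the second stride harmonic (two oscillations),
with the injected right-minus-left differences applied as periodic
Gaussian bumps (sd 0.06 stride) centred on the four extrema, Gaussian
sensor noise, stride-duration variability, sporadic outlier strides, and a
clean one-cycle pastern reference. Two constructions make the noiseless
pipeline *exact* rather than approximate, which the tests exploit: each
stride spans a multiple of eight samples, so the waveform's extrema fall
on the sample grid; and the bumps are periodic, so each bump's tails
contribute identically at the two extrema of the other kind and cancel in
the differences. Defaults — 200 Hz, 0.7 s strides, 40/30 mm head/pelvis
amplitudes — are typical trot values; they are plausible placeholders, not
estimates of any particular study population.

**Population level** (`population_config()`, `simulate_population()`):
draws a cohort with disciplines, riders (a rider may ride several horses),
a configured true-asymmetry prevalence (default 0.70, matching the
prevalence range reported for riding-horse populations), per-horse signed
parameter effects, per-condition stride tables, and questionnaire
responses with study-like marginals. Asymmetric horses receive at least
one triggered parameter drawn at 1.2–2.5 times its threshold; symmetric
horses stay at or below 0.7 times every threshold. These margins are what
make "prevalence recovery" a well-posed end-to-end check: with ~2 mm
stride noise over ~30 strides, the probability that sampling noise crosses
the margins is negligible, so the classified prevalence at 1000 horses
must land inside the 99% binomial interval of the configured rate.
Stride counts, missing-trial rates and questionnaire marginals default to
the observed study design (e.g. 33 ± 9.7 strides on the hard surface,
71/123 questionnaire coverage). Lungeing adds a systematic
direction-dependent shift (default 4 mm on `pd_min`, 3 mm on `hd_min`,
subtracted on the left circle, added on the right) — magnitude is a free
parameter, since only the existence of such systematic lunge asymmetry is
established. Under the alternative, a configured effect (mm per perceived
sidedness grade) inflates the lunge parameter magnitudes, which is what
the power checks exercise.

The generators deliberately idealize several things real data do not
grant: parameter effects are nearly stable across surfaces (so simulated
hard/soft concordance is higher than in field data), stride-level SDs are
small relative to triggered means (so high-variability horses are rare),
rider identity does not influence questionnaire style, and the pastern
reference is noise-free. Passing tests therefore demonstrate the
correctness of the arithmetic, rules and models — not that field data are
this clean.

## Problem sizes used in the checks

The test suite and the acceptance script run, by design, at the study's
scale: a 123-horse pipeline for the report stage, 1000 horses for
prevalence recovery, 1000 null replicates and 150 alternative replicates
at 71 horses / 51 riders for the association stage's size and power, and
100-trial oracle-equivalence sweeps for extraction and outlier removal.

## Known limitations

* The package starts at vertical displacement; reconstructing displacement
  from raw inertial data (sensor fusion, double integration) is out of
  scope, as is any proprietary preprocessing of commercial systems.
* Spreadsheet ingestion expects each workbook sheet exported as CSV (one
  file per condition sheet), mapped through an editable `sheet_schema()`.
* Reported p-values from any particular real data set depend on that
  data's rider structure; this package validates its association stage by
  operating characteristics (size, power) under its own generator instead.
* The sidedness grades are modelled as an unordered factor with pairwise
  contrasts, matching the reference analysis; ordinal modelling is not
  implemented.
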
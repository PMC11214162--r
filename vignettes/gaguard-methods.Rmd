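---
title: "Simulating and evaluating a gestational-age quality-control guardrail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating a gestational-age quality-control guardrail}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaguard)
```

## The problem

Fetal ultrasound biometry — biparietal diameter (BPD), head circumference
(HC), abdominal circumference (AC) and femur length (FL) — is the standard
way to estimate gestational age (GA) in the second and third trimesters,
via published polynomial dating formulas. As low-cost ultrasound reaches
settings without expert sonographers, a practical safety question arises:
can an independent GA estimator act as a *guardrail*, flagging scans where
an inexperienced operator's biometry would lead to a grossly wrong GA,
without disturbing the clinical workflow?

`gaguard` implements the full quality-control analysis for that question on
synthetic cohorts: it generates scans with a realistic error structure,
injects novice-level measurement error, calibrates discrepancy cut-points
on a tuning split, and reports the guardrail's operating characteristics
on a held-out test split with exact intervals. The deep-learning estimator
itself is out of scope; it enters the simulation only through its error
distribution.

## Dating formulas and inversion

Two formulas ship as versioned coefficient files:

* **Intergrowth-21st** (HC, FL; the default):
  $\log \mathrm{GA} = 3.813 + 0.03243\,(\log \mathrm{HC})^2 +
  0.001644\,\mathrm{FL}\,\log \mathrm{HC}$, GA in days, measurements in mm.
* **Hadlock** (four-parameter):
  $\mathrm{GA}_{weeks} = 10.85 + 0.060\,\mathrm{HC}\cdot\mathrm{FL} +
  0.670\,\mathrm{BPD} + 0.168\,\mathrm{AC}$, measurements in cm.

GA is handled in days everywhere internally (all thresholds in this
analysis are in days); weeks appear only in coefficient files that natively
use them, converted at evaluation. Measurements are always supplied in mm
and converted to each file's declared native unit, so mixed-unit formulas
cannot introduce silent factor-of-ten errors. Estimates outside a formula's
validity range are flagged, never clamped — clamping would silently distort
error distributions.

The cohort generator needs the reverse mapping: biometry consistent with a
chosen true GA. No dating formula is invertible measurement-by-measurement,
so `invert_formula()` parameterizes the fetus by a single latent age along
a reference median growth trajectory (growth-chart medians for BPD, HC, AC,
FL at weeks 12–46, interpolated with monotone Hermite splines) and solves
for the latent age at which the formula reproduces the target GA, by
bisection over a bracket wider than the validity range. Because the
formula estimate is strictly increasing in every measurement (checked
numerically whenever a coefficient file is loaded) and the median curves
are increasing, the objective is monotone and bisection is exact; 45
halvings leave a residual far below the 0.1-day round-trip contract that
the tests verify on a 50-point GA grid.

## The synthetic cohort and its error model

`generate_cohort()` simulates participants with $1 + \mathrm{Poisson}(0.5)$
visits (truncated at 8, matching typical 1–2 studies per participant), and
true GAs from a mixture 55% Uniform(98, 195) / 45% Uniform(196, 280) days,
reflecting the late presentation typical of the target population. Each
scan gets three error components:

1. **Shared dating error** (default SD 2.5 days): one Gaussian draw per
   pregnancy added to *every* GA estimate of that pregnancy. Ground truth
   in such cohorts is itself established from one earlier scan, so all
   later estimates err together; this component is the package's device
   for that correlation. No published decomposition exists, so the value
   is an explicit assumption — it is a config parameter, and the
   sensitivity machinery can sweep it.
2. **Independent model error**: a two-component zero-mean Gaussian scale
   mixture. A single Gaussian has a fixed MAE/RMSE ratio of
   $\sqrt{2/\pi} \approx 0.798$, while the calibration targets
   (MAE 3.87, RMSE 5.01 days) imply the heavier-tailed ratio 0.772, so a
   two-component mixture is the minimal family matching both moments.
   `calibrate_scale_mixture()` fixes the first weight at 0.8 and solves
   the two moment equations in closed form. Because the shared component
   adds to each mixture component in quadrature, the solver calibrates the
   *total* mixture to the targets and deflates each component SD by the
   shared variance — so the distribution of (model GA − true GA) matches
   the printed moments exactly, not just approximately.
3. **Expert measurement error**: independent multiplicative lognormal
   noise per structure (inter-observer error is quoted as a percentage in
   the 3–6% range). Relative biometry error propagates nonlinearly through
   the dating formula, so the scalar CV is calibrated at the GA level:
   `calibrate_expert_cv()` root-finds the CV whose simulated expert-GA
   RMSE (including the shared component) hits the target 6.47 days, using
   fixed inner draws so the objective is smooth and monotone. At the
   defaults it lands near 4.3%, comfortably inside the quoted
   inter-observer range.

Replicate measurements (each structure is conventionally measured twice)
are not simulated individually; the single drawn value is read as the mean
of two replicates with `cv` the effective CV, since no downstream
computation uses replicates separately.

Splits are assigned at the participant level — all scans of a participant
share a split — with `round(0.20 n)` participants in the test split and
the remainder divided 4:1 into training and tuning (tuning
`= max(1, round(remainder/5))`). The training split is carried for
protocol fidelity; no computation here fits anything to it.

## Novice error and gross-error labels

Novice biometry is emulated by perturbing the *expert* measurements:
each is multiplied by $1 + u$, $u \sim \mathrm{Uniform}(-2a, 2a)$,
independently per structure and scan. Since
$E|\mathrm{Uniform}(-w,w)| = w/2$, the half-width $2a$ delivers an average
absolute relative error of exactly $a$ (base case $a = 0.075$, multipliers
in [0.85, 1.15]; 5% and 10% in sensitivity analyses). Independence across
the four structures is the simplest reading of independent caliper
mistakes; structured novice biases (systematic plane-selection error) are
deliberately out of scope.

The novice GA is the dating formula applied to the perturbed biometry plus
the pregnancy's shared dating error (novice and expert read the same
reference). A **gross error** is a novice GA differing from the expert GA
by **at least** the threshold (boundary included), base case ±10 days —
the discrepancy that would justify GA recalculation in the mid second
trimester — with ±7 and ±14 days as alternates. Perturbed measurements are
checked against the formula's validity envelope widened by $2a$, so a
legitimate perturbation of an in-range value is never rejected; scans
pushed beyond even that are flagged unusable, counted, and excluded.

## The guardrail

At deployment the guardrail sees only two numbers per scan, so its flag
statistic is $|\mathrm{GA}_{model} - \mathrm{GA}_{novice}|$ in days; the
shared dating error cancels in this difference, which is what lets the
guardrail work without knowing the truth. (Published descriptions of such
guardrails leave the statistic implicit; a model-vs-expert variant can be
evaluated by passing expert GAs instead, but the model-vs-operator form is
the only one available without an expert present, and is the default.)

`calibrate_thresholds()` walks the tuning-split ROC: for each target
sensitivity (80/90/95%), the cut-point is the largest candidate threshold
whose tuning sensitivity still meets the target, candidates being the
observed flag statistics of the gross-error scans (step-function ROC;
midpoint interpolation is rejected for reproducibility). The flag rule is
`statistic >= threshold`, matching the inclusive gross-error convention.
Thresholds are therefore non-increasing in the target, and tightness holds
by construction: the next-larger candidate violates the target.

`evaluate_guardrail()` applies a calibrated cut-point to the test split
and reports sensitivity, specificity, PPV and NPV with exact
Clopper-Pearson 95% intervals (beta-quantile form), plus the AUC of the
flag statistic with a DeLong 95% interval (ties at 1/2; interval on the
AUC scale, clipped to [0, 1]). Degenerate inputs (a single class) raise
typed errors rather than returning NaNs.

## Comparison statistics

`comparison_report()` reproduces the standard accuracy table for model vs
expert GA against ground truth on the test split: MAE ± SE (SE = sample
SD/√n; the delta method on mean squared error for the RMSE's SE), the
paired t-test and t-interval on the per-scan difference of absolute
errors, the proportion of scans with absolute error strictly below 10 days
(strict `<`, following the table convention) with a paired Wald interval
on the difference and a McNemar test — exact binomial below 25 discordant
pairs, the continuity-corrected $(|b-c|-1)^2/(b+c)$ otherwise (the switch
point is an argument). Trimester subsets partition on true GA at a
configurable boundary, default 196 days with the scan at exactly 196 in
the third trimester; conventions differ between 195/196 and 185/186 across
published tables, which is exactly why the boundary is a parameter.
`one_scan_per_participant()` supports the within-participant-correlation
sensitivity analysis.

## Experiments

`run_base_case()` chains generate → split → novice(7.5%) → calibrate on
tune → evaluate on test; `run_sensitivity_grid()` computes the test-split
AUC over the 3×3 grid of gross-error definitions (±7/±10/±14 days) and
novice error levels (5/7.5/10%), twice: at the full model-error scale and
with the independent model-error draw inflated by a degradation factor
(default 1.1). The degradation emulates a weaker independent estimator —
an *analog* of feeding it impoverished input, not a reproduction of any
specific degradation mechanism. All grid cells share one cohort and one
set of underlying Uniform(−1,1) perturbation draws, scaled per error
level (common random numbers), so the monotonicity of the grid — AUC
rising with error level and with looser definitions, degraded ≤ full
cell-wise — is testable at moderate cohort sizes.

Reproducibility: every stage seed is derived from one master seed by a
fixed-order draw, so a run is a pure function of its configuration file,
which round-trips through YAML. `render_reports()` writes the comparison
table, operating points, grids, a JSON report, a manifest and a log, and
is deterministic given the same results.

```{r basecase}
cfg <- experiment_config(
  cohort = cohort_config(n_participants = 2000),
  master_seed = 42)
base <- run_base_case(cfg)
round(base$thresholds, 1)
base$guardrail[["80%"]]
```

```{r grid}
grid <- run_sensitivity_grid(cfg)
round(grid$full, 3)
```

## Problem sizes, tolerances, degenerate inputs

The package's own test suite runs cohorts of 300–5,000 participants
(roughly 450–7,500 scans) — large enough that the qualitative structure
(threshold ordering, grid monotonicity, degradation dominance) is stable,
which is what the tests assert; headline point values from any real cohort
depend on a real estimator's error correlation structure and are treated
as calibration inputs, not as numbers to reproduce. Moment calibrations
are verified by Monte Carlo at $10^6$ draws. Bisection runs to well below
the 0.1-day round-trip contract; the mixture solver verifies its closed
form to a relative $10^{-6}$. Noiseless configurations collapse exactly
(all discrepancies below 0.1 days) and the threshold calibrator then
raises a typed error for want of positives — degeneracy is an error, not
a NaN.

## What the generator does and does not emulate

It emulates: the late-presentation GA distribution, formula-consistent
biometry, percentage-scale expert measurement error, heavier-than-Gaussian
model error matched to printed MAE/RMSE pairs, within-pregnancy error
correlation via the shared dating component, repeat visits, and
participant-level splits. It does not emulate: ultrasound images or videos
(so the degraded-model grid is an error-inflation analog), site
differences, structured novice bias, multiple gestations, first-trimester
scans, or covariates (age, BMI, comorbidities) — none of which enter any
in-scope computation. One visible consequence: with a GA-independent model
error but percentage-scale expert error, the expert is relatively better
in the second trimester and worse in the third, so the model's advantage
concentrates in the third trimester; real cohorts show the same
qualitative pattern, but second-trimester point differences here should
not be over-read. Passing tests demonstrate the pipeline's statistical
machinery and its qualitative behavior under this error structure, not
the field performance of any particular estimator.
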
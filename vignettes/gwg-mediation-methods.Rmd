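---
title: "Methods: counterfactual mediation of maternal BMI effects through gestational weight gain"
author: "gwgmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: counterfactual mediation of maternal BMI effects through gestational weight gain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwgmediate)
```

## The scientific question and the causal model

Maternal obesity is associated with child obesity, and part of that
association may run through gestational weight gain (GWG): mothers with a
higher pre-pregnancy body mass index (BMI) more often exceed the Institute
of Medicine (IOM) weight-gain ranges, and excessive gain itself predicts a
heavier child. This package decomposes the effect of maternal
pre-pregnancy BMI (continuous exposure *A*) on the child's age-4 BMI
z-score (outcome *Y*) into the part transmitted through excessive GWG
(binary mediator *M*) and the part that is not, using the counterfactual
(potential-outcomes) definitions of the controlled direct effect (CDE),
natural direct effect (NDE) and natural indirect effect (NIE).

Two parametric models underlie the decomposition: a logistic model for the
mediator, `logit P(M=1|a,c) = β₀ + β₁a + β₂ᵀc`, and a linear model for the
outcome with exposure–mediator interaction, `E[Y|a,m,c] = θ₀ + θ₁a + θ₂m +
θ₃am + θ₄ᵀc`. Writing `p(a)` for the mediator probability at exposure `a`
and covariates `c`, the product-method decomposition at the contrast `a`
vs `a*` is

* CDE(m) = (θ₁ + θ₃m)(a − a\*)
* NDE = (θ₁ + θ₃p(a\*))(a − a\*)
* NIE = (θ₂ + θ₃a)(p(a) − p(a\*))

with TE = NDE + NIE and proportion mediated PM = NIE/TE. The identifying
assumptions are the usual four: no unmeasured exposure–outcome,
exposure–mediator or mediator–outcome confounding, and no mediator–outcome
confounder affected by the exposure. These are assumptions about the data,
not testable by the package; the default adjustment set (race, education
as an SES proxy, gestational diabetes, smoking during pregnancy, enrolment
period) is the minimal sufficient set of the study design the package
models, and an extended set (adding maternal age, delivery mode,
gestational age, infant sex, birth weight, parity) supports a sensitivity
analysis.

`decompose_effects()` implements the closed form;
`mc_counterfactual_oracle()` realises the counterfactual definitions
directly by simulating `M(a) ~ Bernoulli(p(a))` (coupled across exposure
levels through one shared uniform variate) and evaluating the structural
outcome equation. The oracle is the package's brute-force referee: the
test suite requires closed form and oracle to agree within Monte-Carlo
error over a randomised battery of coefficient sets (100 comparisons at
10⁶ draws each). Residual outcome noise can optionally be drawn in the
oracle to confirm that it cancels in the effect expectations.

## Key parameters and defaults

* **Contrast**: `a = 30` vs `a* = 22` kg/m² — an obese versus normal-weight
  mother; both configurable.
* **CDE mediator level**: `m = 0` (gain not excessive), the natural
  policy-relevant level; configurable.
* **Covariate conditioning**: effects are conditional on `c`. The default
  evaluates at the sample means of the indicator-coded covariate columns
  (`conditional = "means"`), the convention of the common mediation
  macros; `conditional = "marginal"` instead averages the decomposition
  over the empirical covariate rows. The two differ only through the mild
  nonlinearity of `p(·)` and agree closely on cohorts like the default.
* **Bootstrap**: `B = 1000` nonparametric resamples by default; 95%
  percentile intervals. The whole procedure — both refits, covariate
  means, decomposition — is recomputed inside each resample. Resamples
  whose mediator fit fails (separation, non-convergence) are dropped and
  counted; more than 10% failures aborts with advice to use a larger
  sample. PM intervals come from the bootstrap distribution of NIE/TE,
  dropping (and counting) replicates whose total effect changes sign
  relative to the full-data estimate, where the ratio is unstable.
* **Logistic fitting** uses iteratively reweighted least squares with a
  capped iteration budget and an explicit (quasi-)separation check
  (extreme fitted probabilities together with runaway coefficients);
  deterministic and testable against an independent Newton fit.

## Anthropometric derivations

* **BMI** is weight (kg) over squared height (m²).
* **Child z-scores** use the LMS method, `z = ((x/M)^L − 1)/(LS)` with the
  analytic limit `log(x/M)/S` as `L → 0`; the two branches agree to 10⁻⁶
  at the switch point `|L| = 10⁻⁸`. References are supplied as CSV in the
  CDC growth-chart dialect (`read_lms()`); parameters at non-tabulated
  ages are linearly interpolated between bracketing rows — monthly tables
  make any reasonable interpolation rule equivalent in practice, and
  interpolation keeps the z-score continuous in age. A fully synthetic,
  smooth reference covering 24–72 months ships with the package
  (`synthetic_lms_table()`, also at `inst/extdata/lms_synthetic.csv`,
  marked synthetic) so no external download is needed; it is **not** a
  real growth reference.
* **Outcome selection**: the last growth record with both height and
  weight at age 48–59 months; children without one are excluded and
  counted.
* **Child weight status** converts the reference percentiles (5th, 85th,
  95th) to z cutpoints through the standard normal quantile, with the
  upper boundary inclusive (z at exactly the 85th percentile is
  overweight).
* **GWG** is the last weight within 7 days of delivery minus the
  self-reported weight at the last menstrual period, converted at
  1 lb = 0.45359237 kg exactly; a longer gap sets GWG missing. The IOM
  adequacy ranges (normal 25–35, overweight 15–25, obese 11–20 lbs) are
  treated as closed intervals — the boundary counts as adequate, the
  conservative reading since the sources give ranges without boundary
  semantics. The mediator is the indicator of *excessive* gain.
  Underweight mothers (BMI < 18.5) are excluded with a counted exclusion;
  their conventional range (28–40 lbs) is carried in
  `iom_gwg_ranges()` for completeness but unused. Internal units are kg,
  cm and months throughout.

## Cleaning longitudinal height records

Child standing height should be non-decreasing across visits; recording
glitches violate this. `flag_nonmonotone()` flags a value when it falls
below the running maximum of the *usable* values before it (minus a
configurable tolerance, default 0 cm; ties are not departures). The
running-maximum rule — rather than an adjacent-pair rule — flags the
single dipping value instead of every correct value after a spuriously
high one. Each flagged (or missing) value is imputed as a weighted average
of two estimates: the mean of the nearest usable neighbours on either side
("Last & Next", weight 0.3) and the prediction of an OLS line through the
child's usable (age, height) points (fractional regression, weight 0.7).
The weight assignment follows the order in which the two methods are
conventionally listed; both weights are configurable. Flagging and
replacement iterate (bounded passes, default 5) until re-flagging finds
nothing; if the budget is ever exhausted the remaining departures are
raised to the running maximum, so cleaned output always satisfies the
monotonicity rule. Cleaning is idempotent and touches only flagged
positions. Weight (mass) is deliberately not cleaned — a child's weight
may legitimately decrease.

## Missing data

Covariate missingness is handled by fully-conditional-specification (FCS)
multiple imputation. After initialising missing cells from the observed
marginals, each sweep regresses every incomplete variable on all others
and redraws its missing cells from the fitted conditional: OLS plus
residual noise for continuous variables, a logistic Bernoulli draw for
binary ones, and — for nominal variables with more than two levels —
linear discriminant analysis posterior draws, the classic "discriminant"
flavour of FCS for categorical data (fast, deterministic, and a close
analogue of the discriminant option in the major FCS implementations). A
failed conditional fit falls back to a marginal draw and is counted.
Defaults are `m = 20` completed datasets and 10 sweeps, both
configurable; neither is critical at the cohort sizes involved.

For pooling, the package bootstraps **within** each completed dataset and
combines: points as the across-imputation mean, interval bounds as the
mean of per-imputation percentile bounds, plus classical Rubin pooling
(`pool_rubin()`: within-variance W, between-variance B, total
T = W + (1 + 1/m)B) using the bootstrap variances. Imputing within each
bootstrap resample would propagate imputation noise slightly more fully
but multiplies cost by B; the bootstrap-within-imputation ordering with
bound averaging is a documented package choice. With zero missingness the
pooled decomposition is exactly the complete-data decomposition. By
default only covariates are imputed — the exposure is always observed in
the modelled design, and rows with missing mediator or outcome are
dropped with a count — and the imputed set is configurable.

## The synthetic cohort generator

Real mother–child cohorts of this kind are rarely shareable, so the
generator is the package's test-bed: it inverts exactly the model pair the
estimator fits, so every downstream quantity has a known truth.

* Maternal BMI comes from a three-component normal mixture (weights
  0.46/0.22/0.32, means 22/27.3/35.5, SDs 1.8/1.4/4.0) truncated at
  18.5 kg/m², giving roughly 45% normal-weight, 25% overweight and 30%
  obese mothers without modelling the excluded underweight group.
* Covariates are drawn independently of the exposure by default (an
  optional `confounding` switch shifts BMI by race and education so tests
  can isolate adjustment behaviour); categorical distributions mimic a
  racially diverse prenatal-care cohort.
* The mediator and outcome are drawn from the logistic and linear models
  above. The default coefficients were calibrated once, before the
  validation suite was written, so that (i) the marginal prevalences
  match the cohort structure the package emulates — about 55% excessive
  gain and about 24% of children overweight or obese (U.S. prevalence
  estimates for this age range are variously reported as 24–25%; the
  generator targets 24%) — and (ii) the implied closed-form decomposition
  at the default contrast equals a published estimate of this effect:
  CDE 0.322, NDE 0.235, NIE 0.020 on the z-score scale. The truth object
  enforces TE = NDE + NIE exactly (0.255 here); the published total of
  0.246 alongside those addends reflects rounding and pooling, which is
  why the package recomputes totals rather than storing them, while the
  worked-example proportion mediated of 8.13% uses the printed ratio
  0.020/0.246 as printed.
* Growth series are built backward from the generated z-score along a
  constant-z trajectory (per-visit jitter SD 0.2 z units elsewhere, the
  selected age-4 record exact), with strictly increasing heights from
  positive per-visit increments; weights follow from the LMS-inverted
  BMI. Generated z-scores are clamped to ±4.5 to keep the LMS inversion
  defined — astronomically rare under the defaults.
* `inject_errors()` corrupts non-first height records with probability
  `glitch_rate` (default 0.03) by subtracting an offset large enough to
  undercut the previous visit, guaranteeing a detectable running-max
  departure (a first-visit drop is undetectable under the rule and is
  therefore not generated); it records every corruption. Covariate
  missingness (defaults 3–6% per variable; 2% of mothers have a
  delivery-weight gap beyond 7 days, 2% of children no window visit) has
  log-odds shifted linearly by the always-observed BMI, making it MAR
  given observed data — the assumption the FCS step relies on.

What the generator does **not** emulate: electronic-medical-record visit
processes, sibling correlation, gestational-age-specific weight-gain
trajectories, measurement error in self-reported weight, or real growth
references. Passing tests therefore demonstrate correctness of the
estimator and pipeline under the stated models, not robustness to
violations a real cohort may present.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle (brute
force running-max flagging, closed-form OLS, a hand Newton logistic fit,
the Monte-Carlo counterfactual oracle) and the pipeline against the
generator truth. Simulation sizes were chosen as the package's own
trade-off between resolution and a comfortable desk-scale run: 200
replications at the default 766 pairs for NIE recovery and 95% interval
coverage (coverage is required to land in [0.90, 0.98]; percentile
intervals for near-boundary indirect effects are known to run slightly
below nominal), 200 replications for pooled-NIE recovery at 20% MAR
missingness with m = 5 and 5 sweeps, 50 coefficient sets at 10⁶ draws for
oracle equivalence (asserted familywise: a 3-SE criterion over 100
comparisons is allowed the handful of expected chance exceedances, none
beyond 4.5 SE), and consistency checks at n = 50,000. The acceptance
script runs the full pipeline once at n = 766 with B = 1000 and m = 10
imputations.

## Known limitations

* The decomposition is for a continuous outcome and binary mediator only;
  no odds-ratio-scale decomposition, multiple mediators, or
  exposure-induced mediator–outcome confounding sensitivity analyses.
* Complete-case and MAR-based MI analyses share the MAR assumption; MNAR
  mechanisms are out of scope.
* The discriminant-draw FCS conditional is an approximation to a fully
  Bayesian imputation model (no posterior draw of the regression
  parameters); at the package's cohort sizes the practical difference is
  within simulation error of zero, as the recovery tests document.
* Percentile-bootstrap PM intervals are undefined when the total effect
  is near zero; the package reports the dropped-replicate count rather
  than pretending otherwise.
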
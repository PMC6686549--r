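# gwgmediate

Counterfactual mediation analysis of the effect of maternal pre-pregnancy
body mass index (BMI) on child BMI z-score at age four, mediated by
excessive gestational weight gain (GWG) — packaged as a complete, tested
pipeline: longitudinal growth-record cleaning, anthropometric derivation
(LMS z-scores, IOM weight-gain categories), the closed-form effect
decomposition with bootstrap inference, fully-conditional-specification
multiple imputation, and a synthetic cohort generator with known ground
truth for validating every stage.

It is written for epidemiologists and biostatisticians studying
intergenerational obesity who want a reproducible, inspectable
implementation of the counterfactual product-method decomposition on
cohort data — and for methodologists who want a calibrated synthetic
test-bed for it.

## The model

Two regression models are fit to one analysis row per mother–child pair,
with exposure *A* (continuous pre-pregnancy BMI), binary mediator *M*
(excessive GWG by the IOM range for the mother's weight status), outcome
*Y* (child age-4 BMI z-score against an LMS growth reference) and
covariates *C* (race, education, gestational diabetes, smoking, enrolment
period):

- mediator: logit P(M = 1 | a, c) = β₀ + β₁ a + β₂ᵀ c
- outcome: E[Y | a, m, c] = θ₀ + θ₁ a + θ₂ m + θ₃ a·m + θ₄ᵀ c

With p(a) = expit(β₀ + β₁ a + β₂ᵀ c), the decomposition at the exposure
contrast a = 30 vs a\* = 22 kg/m² is

- CDE = (θ₁ + θ₃ m)·(a − a\*)  — direct effect with the mediator fixed at
  m (default: not excessive),
- NDE = (θ₁ + θ₃ p(a\*))·(a − a\*) — direct effect with the mediator at
  its natural unexposed level,
- NIE = (θ₂ + θ₃ a)·(p(a) − p(a\*)) — effect transmitted through the
  exposure-induced change in the mediator,
- TE = NDE + NIE (exact), proportion mediated = NIE / TE.

Confidence intervals are nonparametric percentile bootstrap over the whole
refit-and-decompose procedure; a Monte-Carlo potential-outcomes oracle
(`mc_counterfactual_oracle()`) provides an independent brute-force check
of the closed form.

## Worked example

```r
library(gwgmediate)

coh <- simulate_cohort(cohort_config(seed = 7))   # 766 pairs, known truth
coh
#> Synthetic mother-child cohort: 766 pairs, 3786 growth records
#>   true effects (a = 30 vs 22): CDE 0.322, NDE 0.235, NIE 0.020, TE 0.255
#>   93 corrupted height records
#>   128 missing cells across 4 variables

rows <- derive_pairs(coh$mothers, clean_growth(coh$growth),
                     synthetic_lms_table())
attr(rows, "exclusions")
#>            rows_in underweight_mother    no_window_visit      rows_analyzed
#>                766                  0                 22                744

fit <- gwg_mediate(rows, boot = 500, seed = 7)    # complete-case fit
fit
#> Counterfactual mediation analysis
#>   exposure bmi -> mediator gwg_excessive -> outcome zbmi4 (n = 617, 127 incomplete rows dropped)
#>   contrast: a = 30 vs a* = 22; CDE at m = 0; adjusted for covariates
#>
#>              Estimate   2.5% 97.5%
#> CDE             0.320  0.160 0.487
#> NDE             0.291  0.185 0.384
#> NIE             0.002 -0.022 0.024
#> Total effect    0.293  0.196 0.382
#>
#> Proportion mediated: 0.65% (95% CI -6.97%, 9.79%)
```

The cohort is generated from known coefficients, so the printed estimates
can be read against the generating truth shown by `print(coh)`: an 8-unit
BMI contrast raises the child's expected z-score by ≈0.29 here (truth
0.255), almost all of it direct; the single-cohort NIE estimate (0.002) is
within sampling noise of the generating 0.020 — interval estimation, not
point reading, is the intended use at n = 766. `gwg_mediate_mi()` replaces
the complete-case drop with FCS multiple imputation of the missing
covariates, and `run_study()` drives the whole pipeline (including a
cohort summary by child weight status and an extended-covariate
sensitivity analysis) from one seeded configuration.

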
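# ambicox

Weighted Cox analysis of ambispective recurrent-event cohorts.

## The problem

Cohorts of patients with a recurrent disease often record events that
happened *before* study inclusion alongside prospectively collected
follow-up — an **ambispective design**. For risk factors that are fixed over
time (genetic variants, sex, age at the qualifying event), the pre-inclusion
events carry real information and can greatly increase power. But a
subject's history is only observed if the subject survived long enough for
it to be collected, so mortality between the qualifying event and data
collection selects the sample.

`ambicox` implements a weighted Cox proportional-hazards analysis for this
setting, motivated by studies of venous-thrombosis (VT) recurrence and its
association with genetically determined ABO blood groups. The hazard of
first recurrence is modelled as

```
lambda(t, Z) = lambda0(t) * exp(beta' Z),       t = years since first VT
```

and each subject *i* receives the standardized inverse of their estimated
probability `s_i` of surviving from the first VT to their own
information-collection time:

```
w_i = N * (1 / s_i) / sum_j (1 / s_j),          sum_i w_i = N .
```

The survival probabilities come from a delayed-entry Cox model of death on
the **age** time-scale (subjects enter the death risk set at their age at
inclusion), with sex, the provoked character of the first VT, age at first
VT and four genetic principal components as covariates. Weighted fits carry
a robust sandwich covariance `I^-1 (sum_i U_i U_i') I^-1` built from
per-subject weighted score residuals.

The package contains, all tested:

* `wcoxph()` — weighted Cox engine: Newton–Raphson on the Breslow partial
  likelihood, left truncation with half-open `(entry, exit]` risk sets,
  Breslow baseline cumulative hazard, robust variance, and the usual
  `print`/`summary`/`coef`/`vcov`/`predict`/`residuals` methods;
* `validate_cohort()`, `classify_case()`, `make_intervals()` — the cohort
  data model: timeline validation, the four ambispective case types
  (followed-up, post-inclusion recurrence, lost to follow-up,
  pre-inclusion recurrence), and at-risk intervals for the prospective or
  ambispective design;
* `fit_death_model()`, `compute_weights()` — the weighting stage;
* `fit_recurrence()` — the adjusted recurrence fit for either design;
* `infer_diplotype()`, `abo_additive()` — ABO diplotype inference from the
  five tag polymorphisms (O1: rs8176719-delG, O2: rs41302905-T,
  A1: rs2519093-T, A2: rs1053878-A, B: rs8176743-T) and additive O1-reference
  coding;
* `meta_fixed()` — fixed-effect (inverse-variance) meta-analysis of
  study-level hazard ratios;
* `mc_weight_sensitivity()` — Monte-Carlo sensitivity of the weighted fit
  to the sampling uncertainty of the weights;
* `generate_cohort()`, `bias_experiment()` — a synthetic ambispective
  cohort simulator with latent truth, and a replicated comparison of the
  naive and weighted estimators;
* a command-line interface (`inst/cli/ambicox.R`, see `?cli_main`).

## Worked example

```r
library(ambicox)

## a synthetic ambispective cohort with mild mortality
sim <- generate_cohort(sim_config(n_subjects = 2000, seed = 7, gomp_rate = 1e-4))
table(sim$records$case)
#> CASE1 CASE2 CASE3 CASE4
#>   795   305   470   343

## death model on the age scale, then selection weights
death_fit <- fit_death_model(sim$records)
#> 172 subject(s) with unknown vital status excluded from death model
w <- compute_weights(death_fit, sim$records)
print(w)
#> Selection weights for 1913 subjects
#>   sum = 1913.000000, range = [0.895, 5.490], ESS = 1813.0

## weighted ambispective recurrence fit with ABO coding
fit <- fit_recurrence(sim$records, "ambispective",
                      dosages = sim$dosages, weights = w)
round(summary(fit)$coefficients[1:5, c("hr", "lower", "upper", "p")], 3)
#>          hr lower upper     p
#> abo_A1 1.237 1.089 1.405 0.001
#> abo_A2 1.655 1.320 2.076 0.000
#> abo_B  1.186 0.972 1.446 0.092
#> abo_O2 1.224 0.858 1.747 0.265
#> sex    1.466 1.244 1.727 0.000
```

The `hr` column shows hazard ratios per haplotype copy against the O1/O1
reference (the generator's true values are 1.15, 1.27, 1.02, 1.19) and for
male sex (true 1.65); `lower`/`upper` are 95% confidence bounds from the
robust standard errors.

Combining two published study-level estimates of the male-sex effect on VT
recurrence:

```r
meta_fixed(hr = c(1.65, 1.81), lo = c(1.36, 1.46), hi = c(2.01, 2.25),
           studies = c("ambispective cohort", "prospective cohort"))
#> Fixed-effect (inverse-variance) meta-analysis of 2 studies
#> ...
#> Combined HR 1.72 (95% CI 1.49-1.99), z = 7.33, p = 2.2e-13
```

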
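---
title: "Weighted Cox models for ambispective recurrent-event cohorts"
author: "ambicox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted Cox models for ambispective recurrent-event cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambicox)
```

## The design and the selection problem

An ambispective cohort recruits patients some time after a qualifying
event — here, a first venous thrombosis (VT) — and collects two kinds of
recurrence information: the pre-inclusion history, recorded at the
inclusion visit, and post-inclusion follow-up, gathered at a later
recontact wave. Four observable patient types result:

* **CASE1** — responded at recontact, no recurrence observed;
* **CASE2** — responded, first recurrence between inclusion and recontact;
* **CASE3** — no recontact response (lost to follow-up, including deaths
  after inclusion), so only the event-free pre-inclusion period is known;
* **CASE4** — first recurrence before inclusion, recorded at the
  inclusion visit.

For risk factors fixed at the first VT (genotypes, sex, age at first VT,
characteristics of the first event), all four types can contribute at-risk
time from the first VT onward — the *ambispective* sample — instead of only
the post-inclusion time of CASE1/CASE2 — the *prospective* sample. The
prize is a large gain in events; the price is selection: a subject's
information enters the data only if the subject survived to the time it
was collected (inclusion for CASE3/CASE4, recontact for CASE1/CASE2), so
mortality thins the sample in a structured way.

## The model and the weights

Recurrence is modelled by a Cox proportional-hazards model on the
time-since-first-VT scale,
$\lambda(t, Z) = \lambda_0(t)\exp(\beta^\top Z)$, with additive ABO
haplotype counts (A1, A2, B, O2 copies; O1/O1 is the reference) and the
clinical adjustment set: sex, provoked character of the first VT, age at
first VT (reported per 10 years), type of the first VT (DVT vs PE), and
four genetic principal components. The prospective design uses delayed
entry at inclusion; the ambispective design starts every subject at
$t = 0$.

To counter the survivorship selection, each subject is weighted by the
standardized inverse of the estimated probability $s_i$ of surviving from
their first VT to their own collection time,
$$ w_i = N \frac{1/s_i}{\sum_{j=1}^N 1/s_j}, \qquad \sum_i w_i = N. $$
Standardizing to the sample size $N$ (rather than to 1) keeps the
weighted information on the scale of the actual sample, which matters for
the sandwich variance. The $s_i$ come from a delayed-entry Cox model of
death on the **age** time-scale: subjects enter at their age at inclusion
(they had to be alive then), exit at death or last vital information, and
the age effect is absorbed non-parametrically by the baseline hazard;
covariates are sex, provoked first VT, age at first VT and the four
principal components. Subjects with unknown vital status are excluded
from the death *fit* but still receive weights — prediction needs only
covariates.

Because the weights are estimated, weighted fits report the robust
sandwich covariance $I^{-1}\left(\sum_i U_i U_i^\top\right) I^{-1}$, with
$U_i$ the per-subject weighted score residual and one interval per
subject (so per-subject grouping is the natural clustering).

### Conventions the data leave open

* **Survival accumulated from the first VT.** Survival could be measured
  from inclusion instead; we accumulate from the age at first VT because
  the first VT starts the at-risk period that defines the target
  population. The convention is isolated in `collection_age()` and
  `compute_weights()` and can be switched by a caller.
* **Baseline support.** The Breslow baseline of the death model is zero
  outside the observed entry-age support, so ages before the earliest
  entry contribute no hazard mass. Equivalently, pre-support survival is
  taken as 1 rather than extrapolated.
* **No weight trimming.** Weights are used as computed; a warning is
  emitted when any weight exceeds 10, since such tails usually indicate
  baseline-hazard steps estimated from nearly empty risk sets at extreme
  ages.
* **Recurrence exactly at inclusion** is classified CASE2
  (post-inclusion): it is what the inclusion visit would record
  prospectively.
* **Unobservable rows are rejected, not repaired**: a flagged recurrence
  without a time, or a post-inclusion recurrence for a recontact
  non-responder, fails validation with a reason code.

## Numerical choices

The engine maximises the weighted Breslow partial likelihood by
Newton–Raphson from $\beta = 0$, with up to 10 step-halvings whenever a
step would decrease the likelihood and with overflow-protected trial
steps. Convergence requires a relative log-likelihood change below
$10^{-9}$ or a max-norm coefficient change below $10^{-8}$, within 50
iterations; any coefficient passing 20 in absolute value is reported as
non-convergence with a monotone-likelihood diagnostic. Ties are handled by
the Breslow method, which is what the weighted score-residual theory
behind the sandwich assumes, and risk sets follow the half-open
$(\text{entry}, \text{exit}]$ convention: an event exactly at a subject's
entry time does not see that subject. Interval survival is
$\exp\{-[H_0(t_1) - H_0(t_0)]e^{\beta^\top z}\}$ on the Breslow step
function, so degenerate intervals give exactly 1.

Study-level hazard ratios are combined by inverse-variance fixed-effect
meta-analysis on the log scale, recovering each study's SE from its 95%
CI as $(\ln hi - \ln lo)/(2 \times 1.959964)$. A Mantel–Haenszel
combination is sometimes named for this task, but MH weights need the
underlying cell counts, which hazard-ratio summaries do not carry; on
published VT-recurrence study pairs the inverse-variance combination
reproduces the printed combined HRs to their two printed decimals (see
`tests/testthat/test-acceptance.R`).

The Monte-Carlo weight-sensitivity analysis draws death-model
coefficients from a multivariate normal centred at the estimate with the
model-based covariance (the death fit is unweighted), recomputes the
Breslow baseline, the $s_i$, the weights and the recurrence fit for each
draw, and summarises the replicate coefficients. Semi-definite
covariances are handled by an eigenvalue square root; genuinely
indefinite inputs are projected to the nearest PSD matrix with a warning.

## What the simulator emulates — and what it does not

`generate_cohort()` draws a middle-aged VT-recurrence cohort: haplotype
frequencies (O1 0.498, A1 0.335, A2 0.059, B 0.093, O2 0.015), 34% male,
age at first VT Normal(41, 15.7) truncated to 18–85, 66% provoked and 79%
DVT first events, exponential recurrence with baseline rate 0.04/yr
(about a 30% recurrence fraction within 10 years), Gompertz mortality on
the age scale ($b e^{\theta a}$, defaults $b = 2\times10^{-5}$,
$\theta = 0.085$ per year) with death hazard ratios 1.44 (male), 0.42
(provoked) and 0.98 per year of age at first VT, exponential inclusion
delay with mean 6 years, recontact on average 9 years after inclusion,
76% response, and vital status known for 91%. Linear predictors are
centred at the theoretical covariate means so the baseline rates stay
interpretable when effects change. Subjects dead before their inclusion
date are dropped — the survivorship the weights address — and recurrences
are observable only in life, and post-inclusion only for responders alive
at recontact. A single knob, `post_recur_death_hr`, multiplies the death
hazard after a recurrence; its default of 1 keeps death and recurrence
conditionally independent, and values above 1 create informative
selection that no covariate-based weight can fully capture.

The simulator does *not* emulate calendar-period effects (in mortality,
treatment or event ascertainment), genotyping or imputation error,
multiple recurrences, or competing risks. Passing recovery tests on these
synthetic cohorts therefore show correctness of the estimators under the
stated mechanism, not robustness to everything real cohorts do.

Problem sizes in the tests and in `scripts/acceptance.R` — 200 replicates
of cohorts of 2,000 subjects for the recovery and bias experiments, and
single cohorts of 5,000–10,000 for one-shot recovery checks — were chosen
so Monte-Carlo standard errors are a few thousandths on the log-HR scale
while a full run stays in the minutes range.

## Known limitations

* **Constant weights versus time-varying selection.** The weight
  $1/s_i$ is constant over each subject's whole at-risk interval, and the
  collection time that defines $s_i$ differs by case type — recontact for
  CASE1/CASE2, inclusion for CASE3/CASE4 — which makes the weight depend
  on the observed outcome pattern. In pre-inclusion risk sets, the
  person-time of eventual responders then carries the larger
  1/S(→recontact) weight although observing that part of their history
  only required survival to inclusion. The exact inverse-probability
  accounting would use time-varying weights (1/S(→inclusion) before
  inclusion, 1/S(→recontact) after). `bias_experiment()` makes the
  consequence measurable: under recurrence-dependent mortality
  (`post_recur_death_hr > 1`) with strongly covariate-dependent death
  hazards, the weighted ambispective estimator of a
  mortality-associated conditional log-HR does not improve on the
  unweighted one in our replications (the acceptance suite runs this
  comparison and reports it honestly; `scripts/acceptance.R` writes the
  measured biases). Under conditionally independent death
  (`post_recur_death_hr = 1`) all estimators recover the truth within
  Monte-Carlo error, as the simulation tests verify.
* **Weight tails.** Baseline-hazard steps at extreme ages rest on tiny
  risk sets; subjects whose collection age lies beyond them can receive
  very large weights. The `max w > 10` warning flags this; trimming is
  deliberately left to the analyst.
* **The death model cannot condition on recurrence**, since recurrence
  information is exactly what is missing for subjects who died. This is
  the root cause of the residual bias above and is shared by any
  weighting scheme estimable from these data.
* **Single first recurrence only**; repeated-event structures and
  within-subject correlation across multiple recurrences are out of
  scope.

## Session info

```{r}
sessionInfo()
```
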
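---
title: "Separating practice effects from development in accelerated longitudinal data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating practice effects from development in accelerated longitudinal data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(practiceAdjust)
```

## Motivation

Repeated cognitive and motor testing confounds two sources of score
improvement: genuine developmental change and practice (retest learning).
Within any single person followed annually, age and the number of prior
test exposures advance in lockstep, so no within-person contrast can
separate them. Trajectories fitted to raw repeated scores therefore
overstate developmental gains, and the large first-retest gain can make a
truly linear developmental course look curved.

A cohort-sequential (accelerated longitudinal) design breaks the
confound *between* persons. With overlapping baseline age bands (12–14,
15–17, 18–21 here) and four annual visits, each visit's cross-section
covers a wide age range, and all subjects at a given visit share the same
exposure count. The visit-1 cross-sectional age curve is practice-free;
the visit-2 curve reflects exactly one prior exposure at every age. Their
difference at age $a$ estimates the learning gained from one additional
exposure by an average subject of age $a$ — the twice-minus-once-tested
principle, which this package extends cumulatively across visits.

## Model

Let $f_t(a)$ be the cross-sectional expectation of the score at age $a$
using visit $t$'s data only. Each $f_t$ is a penalized regression spline
of age fitted by `mgcv::gam` with smoothness chosen by generalized
cross-validation, with no random effects (each subject contributes one
row per fit). The learning increment accrued between visits $t-1$ and $t$
at age $a$ is

$$\widehat{\lambda}_t(a) = f_t(a) - f_{t-1}(a).$$

For subject $i$ observed at ages $a_{i1} < a_{i2} < \dots$, the adjusted
score at visit $t$ subtracts all increments accrued so far, each
evaluated at the age the subject held when it was accrued:

$$y^{\mathrm{adj}}_{it} = y_{it} - \sum_{s=2}^{t} \widehat{\lambda}_s(a_{is}).$$

Visit-1 scores are returned untouched. `adjust_visits()` also offers a
`"current_age"` convention that evaluates every increment at $a_{it}$;
the two agree exactly for two-visit data and whenever increments do not
vary with age.

### Trajectory fits and model comparison

Longitudinal trajectory models include a subject random intercept. The
smoothed-age model uses `mgcv::gamm` (cubic regression spline basis,
`k = 5`, i.e. three interior knots at age quantiles); the linear-age
model uses `nlme::lme`. Both are fitted by maximum likelihood so that
likelihood-ratio tests between nested mean structures use the marginal
likelihood. This is a deliberate design choice: comparing penalized fits
by their conditional (GCV-selected) likelihoods materially inflates the
type-I error of the shape and learning tests, whereas the marginal-ML
comparison holds its nominal size in simulation (the package's acceptance
checks verify a rejection rate within [0.03, 0.07] at $\alpha = 0.05$
under the null). For the cross-sectional fits, which feed the adjustment
rather than any test, GCV smoothness selection is retained.

Degrees of freedom for a comparison are the difference in likelihood
parameter counts for mixed fits, and the difference in mean-structure
effective degrees of freedom (parametric terms plus smooth edf) for
fixed-effect fits.

### Learning index and interaction tests

On a paired-visit dataset (subjects with both visits $t$ and $t+1$),
`estimate_learning()` compares the smoothed-age mixed model with and
without a visit factor. It reports the likelihood-ratio statistic and
p-value, the visit coefficient (the average learning gain in Z-units),
and a $\Delta R^2$ learning index — the additional adjusted $R^2$ from
the visit factor, also expressed as a percentage of the age-only $R^2$
(which can exceed 100% when learning explains more variance than age).
Age-graded learning is tested by an age-by-visit smooth interaction
(`s(age, by = visit)`), and sex-modulated learning by a sex-by-visit
interaction on top of it. With eight composites, tests are held to the
Bonferroni threshold $0.05/8 = 0.00625$.

### The slope triptych

`slope_triptych()` summarizes what the adjustment does to the estimated
rate of development:

* the **cross-sectional baseline slope** — ordinary regression of the
  visit-1 score on age, free of practice by construction;
* the **unadjusted** and **adjusted longitudinal slopes** — linear mixed
  models with a subject random intercept on all visits.

In an accelerated design, regressing on a single age term mixes the
within-person rate with the between-cohort age relation, which is
practice-free, and so *understates* the practice inflation. The
longitudinal models therefore disaggregate age into baseline age and
years since baseline (`y ~ age0 + time + (1 | subject)`), and the
reported slope is the `time` fixed effect — the within-person change per
year. If the adjustment works, the adjusted longitudinal slope should
agree with the cross-sectional baseline slope, while the unadjusted slope
exceeds both by (approximately) the per-year learning rate.

## The synthetic cohort generator

`simulate_cohort()` generates ground-truth data:

$$y_{it} = \beta_0 + g(a_{it}) + \sum_{s=2}^{t} \lambda_s(a_{is})
          + \gamma\,\mathbb{1}[\text{female}_i] + b_i + \varepsilon_{it},$$

with $g$ a developmental function (default linear, slope
`dev_slope = 0.08` Z/yr), per-visit learning increments
$\lambda_s(a) = \max\{0,\ \lambda_s + \delta\,(a - 16.5)\}$ (defaults
$\lambda = (0.4, 0.15, 0.05)$, gradient $\delta = 0$, optionally
multiplied for females), subject random intercepts
$b_i \sim N(0, 0.4^2)$ and noise
$\varepsilon_{it} \sim N(0, 0.5^2)$, for $n = 319$ subjects drawn from
the three baseline age bands with annual visits. The generator emits the
developmental and learning components alongside the observed value, so
tests can check exactness: with zero noise and random effects, adjusted
values reproduce the developmental component to floating-point accuracy.

The simulator's scope is intentionally narrow — a test harness with
analytically known answers, not a population model. Visit intervals are
exactly one year, learning gradients are linear in age, and there is no
dropout, no practice heterogeneity between subjects, and no
measurement-model structure below the composite level.

## Composites and eligibility

`build_composites()` standardizes each measure against the baseline
(visit-1) sample mean and standard deviation, flips sign for
lower-is-better measures (e.g. reaction times), and averages measures
within a domain, requiring at least two present members per composite
(otherwise `NA`). `efficiency_score()` is the sum of the total accuracy
and total speed composites. Composite definitions can be read from YAML
(`read_composite_specs()`; see `inst/extdata/example_composites.yaml`).

`apply_drinking_filter()` implements the no-to-low drinking eligibility
caps: lifetime drinking days bracketed by age (5 below 16; 11 for 16 to
16.9; 23 for 17 to 17.9; 51 at 18 and older) and drinks per occasion
bracketed by age and sex (3 for females at any age; for males 3 below 14,
4 for 14 to 19.9, 5 at 20 and older). A subject is retained only if both
caps hold at every visit — the stricter whole-subject reading of
"remained a no-to-low drinker for all included sessions".

## Numerical choices

* **Spline basis.** Cubic regression splines with `k = 5` (three interior
  knots at age quantiles) for all age smooths; small bases keep the
  cross-sectional fits stable at per-visit sample sizes of a few hundred.
* **Increment evaluation.** `predict_ages()` evaluates a fitted curve at
  arbitrary ages, extending linearly beyond the fit's observed age span
  using the boundary derivative, and flags extrapolated ages; adjusted
  datasets carry an `extrapolated` column.
* **Optimizer robustness.** Linear mixed fits use
  `nlme::lmeControl(opt = "optim", returnObject = TRUE)` so degenerate
  (e.g. noise-free) inputs converge instead of erroring.
* **Replication sizes.** Simulation-based checks use 100–500 replicates
  at $n = 120$–$319$ subjects, sized to give stable Monte Carlo estimates
  in minutes on one CPU.

## Limitations

The method estimates the learning of the *average* subject at a given
age; it cannot recover individual differences in practice gains, and
subtracting the average increment adds (small) estimation noise to every
adjusted score. Consecutive visit cross-sections must overlap in age for
the increments to be interpolations rather than extrapolations. The
whole-subject eligibility rule and the complete-case requirement in
`adjust_visits()` both discard data; attributes record how many subjects
were excluded. Finally, shape decisions inherit the usual caveats of
likelihood-ratio tests between penalized and unpenalized mean structures;
the package's convention (marginal ML, edf-based degrees of freedom for
fixed-effect fits) is calibrated by simulation, not exact.
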
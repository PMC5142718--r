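---
title: "Mixture cohort-depletion models of fecundability and bounds on early embryo mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture cohort-depletion models of fecundability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fecundmix)
```

## The problem

Prospective conception studies follow women attempting to become pregnant,
cycle by cycle, with daily monitoring of human chorionic gonadotrophin
(hCG). A rise in hCG about a week after ovulation signals that implantation
has begun; a missed menstrual period or serum confirmation about a week
later marks a clinical pregnancy. These studies report per-cycle aggregate
counts: women starting each cycle, hCG pregnancies, clinical pregnancies,
and women leaving the study (completing it non-pregnant, or withdrawing).

Pregnancy rates in such cohorts decline over successive cycles. The
explanation modelled here is selection: the cohort is a mixture of normally
fertile and sub-fertile couples, and as fertile couples conceive and exit,
the remaining risk set becomes progressively enriched in sub-fertile
couples. Crude per-cycle rates computed from the whole cohort therefore
underestimate the fecundability of normally fertile couples, and any embryo
mortality estimate built on them inherits that bias.

## The model

Probabilities are estimated as base-10 logits,
$\theta = \log_{10}\!\big(p/(1-p)\big)$, so every probability-scale
quantity below is the inverse transform $p = 10^\theta/(1+10^\theta)$ of an
unconstrained parameter.

The starting cohort of size $N(1)$ splits into sub-cohorts (two in the
preferred variant; one and three are supported) with starting fractions
$\%fert(1)$ and $1-\%fert(1)$. Each sub-cohort $c$ has a per-cycle
probability $FEC_{HCG,c}$ of an hCG-detected conception, and an hCG
pregnancy progresses to clinical recognition with probability
$\pi_{CLIN}$ (shared across sub-cohorts in the preferred variant), so the
per-cycle clinical fecundability is
$FEC_{CLIN,c} = FEC_{HCG,c}\,\pi_{CLIN}$. Expected counts follow the
cycle-by-cycle recursion, for cycle $k$:

* $N_c(k) = N(k)\cdot f_c(k)$ — split the cohort by the current fractions;
* $PREG_{HCG,c}(k) = N_c(k)\, FEC_{HCG,c}$ and
  $PREG_{CLIN,c}(k) = N_c(k)\, FEC_{HCG,c}\,\pi_{CLIN,c}$;
* $N(k+1) = N(k) - PREG_{CLIN}(k) - FIN(k) - DROP(k)$, where $FIN$ and
  $DROP$ are the *observed* exits (women finishing non-pregnant, and
  withdrawals) — only clinical pregnancy is predicted, the other exits are
  taken from the data;
* $f_c(k+1) = \big(N_c(k) - PREG_{CLIN,c}(k)\big)\big/\big(N(k) -
  PREG_{CLIN}(k)\big)$ — finishers and dropouts leave proportionally across
  sub-cohorts, so only clinical pregnancies reshape the mixture, and the
  fertile fraction declines monotonically whenever the fertile sub-cohort
  conceives faster.

Women with an hCG-only pregnancy (one that fails before clinical
recognition) remain in the risk set. When a study reports a long-horizon
count of women never clinically pregnant after $H$ cycles, its expectation
is $\sum_c N_c(1)\,(1 - FEC_{CLIN,c})^{H}$.

### Observation vector

One fit consumes, in this fixed order: the cohort sizes $N(k)$ for cycles
$2..K$ ($N(1)$ is fixed by design); the hCG pregnancy counts for the cycles
in which hCG was measured; the clinical pregnancy counts for all cycles;
and the long-horizon never-pregnant count when present. For the three
study shapes this gives $8+9+9+1 = 27$, $11+3+12 = 26$ and $13+14+14 = 41$
observations. Cycles without hCG measurement are recorded as *unobserved*
(empty cells on disk), never as zeros.

### Estimation

The objective is extended least squares,
$\sum_i \big[(y_i-f_i)^2/g_i + \ln g_i\big]$ with the power-of-the-mean
variance model $g_i = \sigma^2 \max(f_i,\varepsilon)^{\gamma}$; it plays
the role of $-2\log L$ under normal residuals ($\gamma = 0$ is
homoscedastic, $\gamma = 2$ a constant coefficient of variation). The
$n\ln 2\pi$ constant is omitted, so only objective *differences* are
convention-free, and all inference uses differences. Standard errors come
from the inverse Hessian of half the objective at the optimum, and 95%
intervals are Wald intervals on the estimation scale mapped through the
inverse logit (hence respecting $(0,1)$ by construction), using the normal
quantile 1.959964.

Model variants: `"0"` two sub-cohorts with shared $\pi_{CLIN}$ (the
preferred fit); `"00"` the same model re-parameterised to estimate the
fertile sub-cohort's $FEC_{CLIN}$ directly (with $\pi_{CLIN}$ derived),
which reaches the identical optimum and exists to give standard errors for
the clinical fecundability; `"1"` one sub-cohort; `"2"`/`"3"` three
sub-cohorts with shared / per-sub-cohort $\pi_{CLIN}$; `"4"` two
sub-cohorts with $\gamma = 0$. Likelihood-ratio tests compare nested
variants by the drop in objective against a chi-square with the
parameter-count difference as degrees of freedom: one vs two sub-cohorts
(2 dof), two vs three (2 dof), shared vs per-sub-cohort $\pi_{CLIN}$
(4 dof), and $\gamma = 0$ vs free (1 dof).

### The mortality-bounds calculus

A live birth requires five stages to succeed in one cycle: sperm-ovum
co-localisation ($\pi_{SOC}$), fertilisation ($\pi_{FERT}$), implantation
($\pi_{HCG}$), clinical recognition ($\pi_{CLIN}$) and survival to birth
($\pi_{LB}$), with $FEC_{HCG} = \pi_{SOC}\pi_{FERT}\pi_{HCG}$. hCG data
identify $FEC_{HCG}$ and $\pi_{CLIN}$; outcome counts give $\pi_{LB}$; the
split of $FEC_{HCG}/\pi_{SOC}$ into $\pi_{FERT}\times\pi_{HCG}$ is not
identifiable and is resolved by explicit scenario: the two equal, or one of
them fixed (0.90 by convention). $\pi_{SOC}$ is an assumption, not an
estimate; the library keeps it a required argument (0.80 is the
conventional choice, reflecting imperfect coital timing and anovulatory
cycles). Cumulative losses of fertilised eggs — before implantation,
clinical recognition, and live birth — are chained at full precision;
rounding the stage probabilities first visibly distorts the results
(e.g. the implantation-to-birth loss of the largest study comes out 34.3%
instead of 34.2% if the stages are first rounded to 3 decimals).

## The synthetic-study generator

`simulate_study()` draws one woman at a time: a latent fertility class from
the mixture fractions; per cycle, Bernoulli hCG conception with the class
probability, then Bernoulli clinical conversion; clinical pregnancy exits
the woman, an hCG-only pregnancy does not; women still at risk withdraw at
cycle end with a fixed dropout probability, and survivors of the last
reported cycle are recorded as finished. With a long horizon, every woman
not clinically pregnant in the reported phase is followed silently (one
aggregate draw per woman, distributionally equal to per-cycle draws) and
the never-pregnant count covers the whole starting cohort — the reading
under which the deterministic expectation reproduces the 14-of-221
long-horizon observation.

The generator's default conditions are the published study designs and
estimates: cohort sizes 221/200/518, 9/12/14 reported cycles, hCG measured
in all cycles except cycles 4–12 of the second study, a 24-cycle horizon
for the first, and the fitted two-sub-cohort parameters of each study. The
per-cycle dropout probability is not reported per study; 0.02 per cycle is
used as a realistic attrition rate for motivated volunteer cohorts. What
the generator does *not* emulate: covariates, within-woman changes in
fecundability over time, non-independent dropout, or reporting
idiosyncrasies of the original studies (e.g. first-pregnancy-only
reporting). Passing tests therefore show the pipeline recovers the model's
own data-generating process, not that the model is true of any real cohort.

## Numerical choices

* **Variance floor.** $\varepsilon = 10^{-6}$ women inside $g_i$ prevents
  variance collapse when predicted counts approach zero in late cycles.
* **Multi-start.** Eight starts: one at neutral values (logits 0, the
  fecundability logits spread downwards to break the sub-cohort symmetry,
  $\gamma = 1$), the rest jittered uniformly by up to one logit under a
  caller-supplied seed; ties in the best objective go to the lowest start
  index. Nested-model comparisons add an informed start at the simpler
  model's optimum (sub-cohort duplicated), which guarantees the nesting
  inequality between achieved objectives.
* **Optimiser.** BFGS (`stats::optim`) with relative tolerance $10^{-12}$;
  the convergence record stores per-start objectives and the numerical
  gradient norm at the optimum.
* **Label switching.** Every fit is canonicalised to decreasing
  $FEC_{HCG}$ order (the relabelled point is the same optimum); without
  this, the two-sub-cohort mirror optimum makes estimates incomparable
  across seeds.
* **Model `"00"` feasibility.** Points where the implied
  $\pi_{CLIN} = FEC_{CLIN}/FEC_{HCG}$ leaves $(0,1)$ get a penalty
  objective rather than an error, so the optimiser simply avoids them.
* **Noise-free recovery.** A dataset of exact expected counts drives
  $\log\sigma \to -\infty$ if $\sigma$ is free, and with $\gamma$ free the
  $\sum \ln g_i$ term rewards shrinking predictions; recovery tests
  therefore fix $\sigma$ and use the homoscedastic variant, for which the
  truth is an exact fixed point. This is a test-only mode.
* **Rounding.** `expected_counts(rounding = "nearest")` repairs
  conservation breaks caused by rounding by adjusting the finished counts
  (with a warning); `rounding = "none"` flags the dataset as real-valued so
  validation skips integrality.
* **Degenerate inputs.** Boundary probabilities in simulator
  configurations are clamped to $10^{-12}$ from the boundary when expressed
  as logits; fecundability 0 or 1 trajectories are exact in the forward
  model.

## Design choices that were genuinely open

* The deposited data files' column layout is not described in the article
  text, so the package defines a canonical CSV schema (`cycle`, `n_start`,
  `preg_hcg`, `preg_clin`, `finished`, `dropped`, with `# key: value`
  comment lines for the study name and horizon metadata) and accepts a
  column map for foreign layouts.
* The long-horizon never-pregnant record is dataset *metadata*, not a
  pseudo-cycle, because it is a different observation type with its own
  expectation.
* The three-sub-cohort mixture uses a stick-breaking parameterisation (two
  unconstrained logits) with the decreasing-$FEC_{HCG}$ ordering; the
  original analysis does not state its parameterisation, and this choice
  affects nothing identifiable.
* Hypothesis tests use the naive chi-square reference even though absence
  of a mixture component is a boundary hypothesis (under which the naive
  reference is, in the classical theory, conservative); this mirrors the
  original analysis.
* The problem sizes in the property-based tests — 20 recovery fits at
  cohort size 5000, 40+40 studies for size and power of the heterogeneity
  test, ~450 replicate studies for the Monte-Carlo oracle — were chosen as
  the smallest sizes at which the checked quantities are stable.

## Known limitations

* **Interval undercoverage and test size.** The observation vector is
  internally dependent: the cohort sizes $N(2..K)$ are deterministic
  functions of the clinical-pregnancy and exit counts, so the objective
  double-counts the clinical information, and the true noise is binomial
  rather than independent power-of-the-mean normal. Consequently, under
  individual-level simulation the inverse-Hessian Wald intervals undercover
  (about 70% observed at the nominal 95% in the 20-seed recovery check)
  and the heterogeneity LRT rejects a true homogeneous model more often
  than its nominal level (about 25% at $\alpha = 0.05$ in the 40-seed
  calibration check). Both are properties of the estimation convention, not
  of the code: when residuals are drawn from the working model itself, the
  same machinery attains near-nominal coverage and size in the
  corresponding checks. Point estimation is unaffected (median absolute
  probability-scale error below 0.01 at cohort size 5000), and the
  published heterogeneity chi-squares are an order of magnitude beyond the
  inflation, so the substantive conclusion — two discrete fertility
  classes — does not rest on the nominal calibration.
* **$\pi_{SOC}$ is an assumption.** The bounds calculus propagates it
  explicitly; nothing in the data identifies it.
* **No covariates or continuous heterogeneity.** The mixture is two- (or
  three-) point by design; continuous frailty alternatives are out of
  scope.
* **Printed-precision artifacts.** Chaining from the published 3-decimal
  logit estimates reproduces the published loss grid to its printed 0.1
  precision, but a few cells sit on a rounding boundary because the
  original chained unrounded estimates.

## What the analysis scripts do

`analysis/01_simulate_studies.R` generates synthetic counterparts of the
three studies at their published estimates; `02_fit_models.R` refits the
two-sub-cohort model to each and tabulates estimates with intervals;
`03_hypothesis_tests.R` runs the four nested-model tests;
`04_mortality_bounds.R` computes the stage-loss scenario grid and the
implied plausibility band for embryo mortality;
`05_refit_deposited.R` refits the original deposited tables when the user
supplies them locally. Tables land under `results/`.
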
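---
title: "Modelling zero-heavy polyp counts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling zero-heavy polyp counts: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypcount)
```

## The statistical problem

Colonoscopy screening data have a characteristic shape: a non-negative
integer count of detected polyps per subject, with a zero fraction often
above 50%. Two mechanisms produce those zeros. A *structural* zero is a
subject who genuinely has no polyps; a *sampling* zero is a subject whose
polyp was missed by the procedure, i.e. a zero emitted by the count
process itself. Because the mechanisms differ, a single count
distribution cannot represent both, and the excess mass at zero shows up
as apparent overdispersion and as biased group contrasts in ordinary
count regression.

`polypcount` provides the families an analyst needs to handle this:

* **LR** — logistic regression on the dichotomized outcome $y > 0$
  (the polyp detection rate, PDR). Valid but inefficient, and blind to
  differences in the *extent* of polyps.
* **PR / RP** — Poisson regression
  $\log E(Y) = X\beta$, with model-based or Huber sandwich variance. RP
  keeps the PR point estimates and replaces the variance with
  $A^{-1} B A^{-1}$, where $A$ is the observed information and
  $B = \sum_i s_i s_i^\top$ the outer product of per-subject scores; this
  is consistent under variance misspecification.
* **NB** — NB2 with variance $\mu + \alpha\mu^2$ ($\alpha \ge 0$), the
  standard overdispersed count model.
* **GP** — the restricted generalized Poisson (Consul–Famoye), chosen
  because it accommodates *under*dispersion as well. We parameterize by
  the mean: $P(Y=y) = \theta(\theta + \delta y)^{y-1}
  e^{-\theta-\delta y}/y!$ with $\theta = \mu(1-\delta)$, variance
  $\mu/(1-\delta)^2$, admissible $\max(-1, -\mu/4) < \delta < 1$. The
  literature contains several GP variants and applied reports rarely say
  which was used; we fixed the restricted GP-1 form and document it here.
  For $\delta < 0$ the support is finitely truncated and the pmf is only
  approximately normalized — an inherent property of this family, which
  is why the normalization test covers $\delta \ge 0$.
* **ZIP / ZIRP / ZINB / ZIGP** — the two-part mixture
  $$P(Y=y) = \begin{cases} \pi + (1-\pi)f(0) & y = 0\\
  (1-\pi) f(y) & y > 0\end{cases}$$
  with $\operatorname{logit}(\pi) = Zb$ and $\log \mu = X\beta$. The
  inflation part models the odds of an **excess zero**; an inflation OR
  below 1 therefore means *fewer* structural zeros in the exposed group,
  and since the OR is symmetric its inverse reads as the effect on the
  presence of detectable polyps. The inflation link is logit; probit is
  not implemented. The two design matrices may differ — in observational
  analyses a covariate sometimes belongs only in the inflation part.
* **ZHP / ZHNB** — hurdle models: a logistic fit on $y>0$ (identical, by
  likelihood factorization, to LR) and a zero-truncated count fit
  ($f(y)/(1-f(0))$, $y \ge 1$) on the positives. Hurdle models are the
  natural choice when zeros are believed to be purely structural;
  zero-inflated models when sampling zeros are plausible — which, for
  colonoscopy, they usually are. This judgment about the data-generating
  process cannot be made by the data alone, so the model selector takes
  the zero type as a declared input rather than inferring it.

All likelihood evaluation is in log space, with log-sum-exp for the
mixture zero cell: with 50–70% zeros the $f(0)$ terms dominate the
likelihood and would underflow otherwise.

## Estimation and numerical choices

Every family is expressed as one per-subject log-likelihood closure; the
optimizer, observed information, per-subject scores, and sandwich
variance all derive from it. Fitting is quasi-Newton (BFGS) with analytic
gradients for the logistic, Poisson, NB2, ZIP and truncated-Poisson
likelihoods, followed by a short damped-Newton polish that drives the
score max-norm to about $10^{-9}$. The GP variants, the ZINB/ZIGP
dispersion direction and the truncated NB use central finite-difference
gradients (step $6\times10^{-6}\max(1,|\theta_j|)$): their parameter
counts are small, they are off the Monte Carlo hot path, and the noise
floor of the difference quotient — not the optimizer — then limits the
achievable score norm, so a fit is declared converged at max-norm
$10^{-4}$. Starting values: a Poisson GLM seeds all count parts (the
truncated-data Poisson for two-part models); the inflation intercept
starts at $\operatorname{logit}$ of the excess-zero fraction relative to
the Poisson prediction (floored at 0.05); moment estimators seed the
dispersions.

Boundary handling deserves a note. On equidispersed data the NB2 profile
likelihood is flat as $\alpha \to 0$ with the maximum on the boundary;
chasing $\log\alpha \to -\infty$ produces slow zigzagging. Whenever an
NB-type fit lands below $\alpha = 10^{-4}$ — at realistic sample sizes
indistinguishable from zero — we pin $\alpha = 0$, refit the Poisson
counterpart for the coefficients, warn, and still count the dispersion in
the parameter total for AIC/BIC. Similarly, when a zero-inflated model is
fitted to data without excess zeros the inflation intercept drifts to
$-\infty$ (all $\pi_i \to 0$); a converged fit in that state is the
legitimate degenerate boundary, the count part equals the plain GLM, and
the flat inflation direction of the information matrix is handled by
inverting on the non-degenerate subspace (with a warning). Only
non-convergence with observed zeros raises the instability error that
recommends the hurdle fallback. Perfect separation in any logistic part
is reported as an error naming the offending column.

Wald 95% intervals on the log scale, exponentiated, with two-sided normal
p-values, are used throughout, matching standard reporting. Categorical
covariates are dummy-coded against the first sorted level, deterministic
without a formula interface.

## The diagnostic battery

* **Score test for zero inflation** (van den Broek):
  $S = \left[\sum_i (1\{y_i = 0\} - \hat p_{0i})/\hat p_{0i}\right]^2 /
  \left[\sum_i (1-\hat p_{0i})/\hat p_{0i} - n\bar y\right]$ with
  $\hat p_{0i} = e^{-\hat\mu_i}$ from the Poisson fit. We refer it to
  $\chi^2(1)$ — statistics of this magnitude (hundreds on real data) are
  only coherent on the chi-square scale, although some applied reports
  label the same quantity a Z-value. A non-positive denominator
  (underdispersion) makes the test inapplicable and is reported as such.
* **Bias-corrected Vuong test**: per-subject log-likelihood differences
  $m_i$ between the zero-inflated model and its single-distribution
  counterpart, AIC-corrected by default (subtracting the per-observation
  parameter penalty; BIC optional), $Z = \sqrt n \, \bar m / s_m$,
  one-sided with positive $Z$ favouring the inflated model. Identical
  models short-circuit to $Z = 0$.
* **Excess-zero removal**: the number of records removed is
  $m = \operatorname{round}(\sum_i \hat\pi_i)$, taken from the observed
  zeros in decreasing order of the posterior probability
  $\hat\pi_i / \hat P(Y_i = 0)$ of being structural, ties broken by
  record order. A deterministic rule was chosen over random thinning for
  exact reproducibility of everything downstream.
* **Dispersion after removal**: (a) the auxiliary regression of
  $((y-\hat\mu)^2 - y)/\hat\mu$ on $\hat\mu$ (NB2 variance function,
  no intercept) with a two-sided t-test whose slope sign gives the
  direction; and (b) the boundary likelihood-ratio test
  $2(LL_{NB} - LL_{P})$ against the $\tfrac12\chi^2(0) +
  \tfrac12\chi^2(1)$ mixture, reporting $\hat\alpha$.
* **Goodness of fit**: observed vs expected counts over cells
  $0, 1, \ldots, 5, 6{+}$ (the same topcoding convention used for
  fitting), cells with expected count below 1 merged upward. The degrees
  of freedom for this grouped test after maximum-likelihood estimation
  are a convention rather than a theorem; the default deduction is 2
  (df = cells − 3), it is configurable, and it is always printed with
  the result.
* **Flowchart selector**: no excess zeros → single-distribution family
  by dispersion direction; excess zeros → hurdle vs inflated by the
  declared zero type; within the branch, overdispersion after removal
  selects the NB count part, otherwise the Poisson part with sandwich
  variance; final ranking by BIC with the goodness of fit as tie-break
  (a BIC-best model whose GOF clearly rejects yields to the next-best
  that fits). Every branch decision is logged in the report's rationale.

## The synthetic-data generator

`generate_dataset()` emulates the mechanism the two-part models assume:
a Bernoulli structural-zero indicator multiplied by a Poisson or NB2
count, group assignment Bernoulli(0.5), and optionally a normal
confounder. Scenarios specify the *marginal* sampling-zero probability
rather than a count intercept; `calibrate_count_intercept()` root-finds
$\beta_0$ so that $E_x[P(\text{count} = 0 \mid x)]$ hits the target
under the scenario's covariate law (closed forms $\mu = -\log SZ$ and
$(1+\alpha\mu)^{-1/\alpha} = SZ$ in the covariate-free case). The
implied overall zero proportion is $TZ + (1 - TZ)\,SZ$.

The three preset conditions (N = 425, true count-part group coefficient
0.40) are: 52.5% structural / 18% sampling zeros with Poisson counts;
16% / 1% Poisson; and 52.6% / 28.9% with NB2 counts at $\alpha = 0.5$
plus a standard-normal confounder. The confounder's coefficients (0.2 on
the count log-mean, 0 on the inflation logit) are plausible placeholders
for an observational condition and are exposed in `scenario()`. By
default the structural-zero probability does not depend on the group
(`inflate_group_coef = 0`). That choice matters for interpretation: the
performance of *misspecified* single-distribution models in such designs
depends strongly on how the inflation relates to the exposure, so their
bias and coverage under this generator characterize only this
configuration; the correctly specified zero-inflated and hurdle rows are
robust to it, which is exactly the property the Monte Carlo study is
meant to show.

What the generator does **not** emulate: covariate-dependent detection
(e.g. withdrawal time affecting the miss rate), correlated polyps within
subject beyond NB overdispersion, measurement error in covariates, or
missing data. Passing simulation tests therefore demonstrates
correctness of the estimators under the stated mechanism, not robustness
to everything real colonoscopy data can do.

`run_monte_carlo()` derives one sub-seed per replication from the master
seed, fits each requested model, records the count-part group coefficient
and its Wald 95% CI, and reports average bias, relative bias, mean CI
width, and coverage; failed fits are dropped, counted, and flagged if
they exceed 20% of replications.

## Marginal standardization

Group effects from different families live on different scales, so the
package standardizes: set everyone's group to 1, average the model's
$\hat P(Y>0)$, repeat with 0, and report the difference and the odds
ratio of the two averaged detection rates. Confidence intervals are
percentile bootstrap over subjects (default B = 1000, seeded, model
refitted in every resample); a delta method spanning two model components
would be fragile across ten families, and the bootstrap is exact to
rerun. For a covariate-free logistic model the standardized OR equals
the fitted OR, which the tests assert. Note one reporting subtlety: for
inflated models the mean of $\hat P(Y=0)$ — not the detection rate — is
what some published tables label "estimated PDR"; the package reports
$\hat P(Y>0)$ and prints its complement alongside to avoid the
ambiguity.

## Problem sizes used by the test suite

The suite keeps everything generated-in-code: parameter-recovery checks
run one fit at N = 20,000; the type-I-error checks run 500 replications
at N = 600; the coverage checks run 200 replications of the N = 425
scenarios (Monte Carlo error about ±0.016, tested at ±0.04); the
acceptance script runs the full 1000 replications (±0.007). These sizes
make the whole suite complete in well under five minutes while keeping
the Monte Carlo error far below the tested tolerances.

## Known limitations

* ZIGP has no sandwich-variance variant, and hurdle models are fitted
  with model-based variance only.
* No offsets/exposure terms (colonoscopy counts have a common exposure),
  no repeated-measures or clustered extensions, no probit inflation
  link.
* The GP fit can be slow to converge near the underdispersion boundary
  of its admissible region; the optimizer penalizes invalid regions
  rather than reparameterizing them away completely.
* The flowchart is a structured sensitivity analysis, not a substitute
  for prespecifying a primary model in a trial analysis plan.
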
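---
title: "Simulating and analysing stepped-wedge cluster trials with few clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing stepped-wedge cluster trials with few clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swctsim)
```

## The problem

In a cross-sectional stepped-wedge cluster trial (SW-CT) every cluster starts
in the control condition and crosses over to the intervention at a staggered,
scheduled period; new individuals are sampled in each cluster-period cell.
These trials frequently run with very few clusters — designs with five or
fewer clusters are common — which makes them vulnerable to two related
problems: chance imbalance in cluster-level covariates, and (in
non-randomised rollouts) outright confounding between a cluster's underlying
outcome level and how early it receives the intervention.

The standard analysis is the Hussey–Hughes linear mixed model, which treats
cluster intercepts as random effects and relies on those intercepts being
uncorrelated with treatment timing. The alternative studied here is the
within-cluster *fixed-effects* model, which gives every cluster its own fixed
intercept: each cluster acts as its own control, and every time-invariant
cluster-level covariate — measured or not — is absorbed automatically.
`swctsim` implements both estimators, the small-sample corrections used with
the mixed model, separate-step estimation of the intracluster correlation
coefficient (ICC), and a Monte Carlo harness for comparing the two across
imbalance and confounding conditions.

## Data-generating model

Outcomes are generated from

$$Y_{ijk} = \phi_j + X_{ij}\,\delta + C_i\,\xi + \alpha_i + e_{ijk},
\qquad \alpha_i \sim N(0, \tau^2_\alpha),
\qquad e_{ijk} \sim N(0, \sigma^2_w),$$

for individual $k$ in cluster $i$ at period $j$, where $X_{ij}$ is the
staircase treatment indicator, $C_i$ a time-invariant binary cluster
covariate with effect $\xi$, $\phi_j$ a linear secular trend, and the cluster
random intercept $\alpha_i$ induces the intracluster correlation
$\mathrm{ICC} = \tau^2_\alpha / (\tau^2_\alpha + \sigma^2_w)$.

Cluster-period cell sizes follow a gamma–Poisson mixture: a mean size
$\bar n_i \sim \mathrm{Gamma}(k, \theta)$ per cluster, then
$n_{ij} \sim \mathrm{Poisson}(\bar n_i)$ per period, so sizes vary both
between clusters and between periods within a cluster.

### Default study conditions

The default grid (`scenario_grid()`, 320 scenarios) crosses:

* designs with 3, 4, 5, 6 and 10 sequences, one cluster per sequence
  (periods = sequences + 1);
* intervention effects $\delta \in \{0, 0.5\}$ (null and medium), with a
  secular trend of $+0.2$ per period anchored at $\phi_1 = 0$;
* $\tau^2_\alpha \in \{1/99, 1/19, 1/9, 1/4\}$ with $\sigma^2_w = 1$, i.e.
  ICC $\in \{0.01, 0.05, 0.1, 0.2\}$;
* mean cell sizes $k \in \{30, 100\}$ with $\theta = 1$;
* four covariate conditions: none ($\xi = 0$), chance imbalance
  ($C_i \sim \mathrm{Bernoulli}(0.5)$, $\xi = 0.3$), covariate confounding
  (covariates drawn then sorted so covariate-positive clusters are treated
  last, $\xi = 0.3$), and complete confounding (clusters sorted by
  $\alpha_i$, lowest treated first, with a proxy covariate and $\xi = 0$).

The anchoring of the trend at zero in period 1 is a normalisation choice
(only the per-period increment is specified by the conditions), and in the
confounding scenarios a degenerate all-0/all-1 covariate draw is retained as
drawn — the replicate simply carries no confounding — because the generative
rule is draw-then-sort. Cluster-to-sequence assignment is the identity in
the non-confounded scenarios: clusters are exchangeable draws, so a random
permutation would change nothing in distribution while complicating seed
bookkeeping.

## Estimators

**Fixed effects (within estimator).** OLS of $Y$ on $J-1$ period dummies,
the treatment indicator, and $I$ cluster dummies (no global intercept). The
residual variance uses the unbiased denominator $N - (I + J)$ and
$\widehat{\mathrm{var}}(\hat\delta) = \hat\sigma^2_w
\left[(\tilde Z'\tilde Z)^{-1}\right]_{\delta\delta}$.

**Mixed effects (Hussey–Hughes).** Variance components by REML, then
generalised least squares with the plugged-in block-exchangeable covariance
$V_i = \sigma^2_w I + \tau^2_\alpha J$, giving
$\hat\theta = (\dot Z'V^{-1}\dot Z)^{-1}\dot Z'V^{-1}Y$ and
$\widehat{\mathrm{var}}(\hat\theta) = (\dot Z'V^{-1}\dot Z)^{-1}$. A
covariate-adjusted variant adds $C_i$ to the fixed effects.

All fitting runs on cluster-period cell statistics (sizes, means,
within-cell sums of squares): with cell-constant covariates this weighted
aggregated fit reproduces the individual-level estimates, standard errors
and variance components exactly, which the test suite verifies against
dense-matrix GLS and pseudo-inverse OLS oracles on small instances. No
$N \times N$ matrix is ever formed; the exchangeable blocks are inverted
analytically via $V_i^{-1} = aI - bJ$.

REML is used for the variance components (rather than ML or moments):
it is the standard choice for this model class, is what the Kenward–Roger
machinery is defined on, and on balanced layouts coincides with the ANOVA
moment estimator (also verified in the tests). The profiled criterion is
one-dimensional in $\lambda = \tau^2/\sigma^2$ and is minimised by Brent
search on $\log\lambda$ over $[-13, 13]$, compared explicitly against the
$\tau^2 = 0$ boundary; boundary estimates are truncated at zero and
inference proceeds with the truncated value. A fit in which all residual
variation vanishes is reported as the $(0, 0)$ boundary with a degenerate
flag.

### Small-sample corrections

The default ("uncorrected") inference for every model is the
normal-approximation Wald interval. For the mixed model two corrections are
available:

* **Satterthwaite**: denominator degrees of freedom
  $\mathrm{df} = 2\hat v^2 / \widehat{\mathrm{Var}}(\hat v)$ for
  $\hat v = \widehat{\mathrm{var}}(\hat\delta)$, with
  $\widehat{\mathrm{Var}}(\hat v)$ by the delta method over the inverse
  *expected* REML information of $(\tau^2, \sigma^2)$,
  $\mathcal I_{rs} = \tfrac12\,\mathrm{tr}(P V_r P V_s)$.
* **Kenward–Roger**: the first-order adjusted covariance of the fixed
  effects. Because $V$ is linear in $(\tau^2, \sigma^2)$ the
  second-derivative term vanishes and
  $\Phi_A = \Phi + 2\Phi\{\textstyle\sum_{rs} W_{rs}(Q_{rs} -
  P_r \Phi P_s)\}\Phi$ with $W$ the variance-component covariance. For a
  rank-1 contrast the Kenward–Roger moment-matching degrees of freedom
  reduce algebraically to the Satterthwaite value and the $F$ scale factor
  equals 1 exactly (substituting $A_1 = A_2$ in the scalar case gives
  $m = 2/A_2$), so the correction acts through the inflated standard error
  $\mathrm{kr\_se} \ge \mathrm{se}$.

The expected information is used rather than an observed (finite-difference)
Hessian; the two agree asymptotically, and the Satterthwaite df computed
here tracks `lmerTest`'s observed-information value to within a few percent
on the instances tested. The empirical consequences mirror the method
comparison this package exists to run: Satterthwaite df are typically large
in SW-CTs (much of the information about $\delta$ is within-cluster), so
that correction only slightly tempers the mixed model's anti-conservatism,
while Kenward–Roger inflates the standard error enough to become
conservative at three clusters.

### ICC in a separate step

Because the fixed-effects model absorbs the between-cluster variance, the
ICC is estimated separately, by REML on three nested data subsets: the
unexposed first period only (intercept + random cluster), the first and
final periods (two period fixed effects + random cluster; a constant
treatment effect is absorbed by the final-period effect), and the full
Hussey–Hughes model. Using more data lowers the Monte Carlo standard error
(full $\le$ first/last $\le$ first-period); boundary fits report ICC 0.

### Hausman test

`hausman_test()` implements the basic scalar form on the treatment effect,
$H = (\hat\delta_{FE} - \hat\delta_{ME})^2 /
(\widehat{\mathrm{var}}_{FE} - \widehat{\mathrm{var}}_{ME})$ against
$\chi^2_1$. A non-positive variance difference is reported as a flagged
non-result rather than truncated. In SW-CTs this test has very low power
even under complete confounding, so it should not be used to decide between
the models.

## Monte Carlo harness

`run_scenario()` simulates independent replicates (replicate $r$ of a
scenario uses the child seed `derive_seed(seed, r)`, so results are
bit-reproducible and independent of any execution order or parallel
chunking), fits the requested models, and summarises: bias, relative bias
($\delta \ne 0$ only), precision $1/\overline{\widehat{\mathrm{var}}}$,
power / type I error and coverage of the nominal 95% interval, RMSE
(denominator $S$), and the Monte Carlo standard error (sample SD,
denominator $S-1$), satisfying
$\mathrm{RMSE}^2 = \mathrm{bias}^2 + \tfrac{S-1}{S}\mathrm{MCSE}^2$.
Replicates whose fit fails are dropped and counted, with a hard error above
a 1% failure rate. With three clusters a quarter of Bernoulli(0.5) covariate
draws are constant, leaving the covariate-adjusted model aliased; the
harness fits such replicates without the inestimable covariate column (the
exact limit of the adjusted fit) and counts them separately rather than
treating them as failures.

`run_quantile_stratified()` implements the imbalance-severity experiment for
the 3-cluster design: replicates are classified by their covariate triple
into Q1 (covariate concentrated in late-treated clusters), Q2 (balanced),
Q3 (early-treated), with the two constant triples excluded, and summaries
are produced per model within each stratum. The unadjusted mixed model is
biased downward in Q1 and upward in Q3 by roughly equal magnitudes — hence
unbiased on average — while the fixed-effects and covariate-adjusted models
are unbiased within every stratum.

## Problem sizes and what the tests show

The package's test and acceptance runs use 2,000 replicates per scenario
(5,000 in the acceptance script) on a handful of grid points, chosen so
binomial Monte Carlo error ($\pm 2\sqrt{p(1-p)/S} \approx \pm 0.01$ for a
proportion near 0.05 at $S = 2{,}000$) sits inside the assertion bands; the
full 320-scenario grid at 10,000 replicates (30,000 for the quantile
experiment) is available through the same functions and the bundled CLI
script. The ICC-recovery checks use the 10-sequence design, where the
skew and boundary truncation of small-$I$ variance-component estimates do
not dominate the mean.

What passing these simulations shows — and does not show — should be read
against the generator's assumptions: normal residuals, an immediate and
constant treatment effect, an exchangeable (not nested) correlation
structure, non-informative cluster sizes, and cluster-level (not
individual-level) covariates. Real trials that violate these (e.g.
time-on-intervention learning effects, cluster-period interactions,
informative sizes) are outside what these operating characteristics
certify; the fixed-effects model also cannot estimate effects of
cluster-level time-invariant covariates, since it absorbs them.

## A worked example

```{r example, eval = FALSE}
cfg <- scenario_config(swct_design(3), delta = 0.5, tau2 = 1 / 19,
                       cell_size_shape = 30, seed = 42)
trial <- simulate_trial(cfg)
fit_fixed_effects(trial)
kenward_roger_adjust(fit_mixed_effects(trial))
icc_full(trial)
run_scenario(cfg, reps = 200, models = c("fe", "me"))
```

## Known limitations

* Designs are restricted to one cluster per sequence with no transition
  periods and no never-/always-exposed arms.
* The Kenward–Roger implementation covers the scalar treatment contrast in
  the two-component exchangeable model (which is all this design family
  needs), not arbitrary contrasts in arbitrary covariance structures.
* The Hausman variant is the basic scalar form; full-vector versions are not
  implemented.
* Satterthwaite/Kenward–Roger degrees of freedom use the expected REML
  information; software built on observed information will differ in the
  third significant figure or so.
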
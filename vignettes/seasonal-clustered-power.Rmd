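---
title: "Methods: powering seasonal, clustered surveillance designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: powering seasonal, clustered surveillance designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasonpower)
```

## The design problem

Vector surveillance revisits the same trapping locations through a season.
Two dependence structures make the naive "independent samples" power
analysis wrong: successive catches at one location are **temporally
correlated** (seasonality), and catches at nearby locations are **spatially
clustered**. The first means each additional visit brings less than one
visit's worth of information; the second means each additional mosquito
within a location brings less than one independent unit's worth. A sound
design balances visits against locations under both penalties.

## Model and assumptions

**Temporal correlation.** Measurements a lag $l$ apart correlate as
$\rho_\Delta = \rho^{\,l^\theta}$ ([seasonal_model()],
[lag_correlation()]). $\rho \in [0,1)$ is the correlation of successive
values; $\theta \ge 0$ dampens the decay. $\theta = 0$ collapses to
compound symmetry, which is how an externally estimated autocorrelation
(ACF) value is entered directly. The law is stationary and monotone in the
lag; non-monotone or harmonic seasonal correlation is out of scope.

**Repeated-measures sample size.** With $k$ visits per location,
correlation $\rho_\Delta$ among them, between-unit effect variance
$\sigma_b^2$ and measurement error variance $\sigma^2$, the locations per
group needed to detect an absolute difference $x$ are

$$n(k) = \frac{2}{x^2}\Big[\sigma_b^2 + \frac{\sigma^2}{k}\big(1 + (k-1)\rho_\Delta\big)\Big](Z_{\alpha/2} + Z_\beta)^2 .$$

**Cluster sample size.** With $m$ correlated units per location and
intra-cluster correlation $\rho_c = \tau^2/\sigma_T^2$, the locations per
group are $n_c = (2/x^2)\,\sigma_T^2\,[1+(m-1)\rho_c]\,(Z_{\alpha/2}+Z_\beta)^2$;
the bracket is the variance inflation factor and $n_c m$ the full sample.

**Design matching.** The optimiser evaluates $k = 1\ldots 2k_{max}$
(sub-unit visit frequency is allowed, hence the doubled grid), computes
$n(k)$ for each, and selects the $k$ minimising $|n(k)\,k - n_c m|$ — the
visit schedule whose seasonal-design effort best matches the cluster-design
full sample. The search starts at $k = 2$ (a single visit cannot express
seasonality; $k = 1$ still appears in the sweep table), ties break to the
smallest $k$ (fewest field visits), and the reported number of locations is
$\lceil n_c m / k^\ast \rceil$ — the fewest locations that reach the
cluster-mandated full sample with $k^\ast$ visits.

## Calibrated conventions

The formulas above leave three things unresolved: how the single
user-supplied standard deviation maps onto $(\sigma_b^2, \sigma^2,
\sigma_T^2)$, what lag the correlation law is evaluated at for a $k$-visit
design, and what cluster size drives the variance inflation in the matching
target. These conventions were **calibrated against the published 18-row
reference grid of optimal designs** for the interactive tool this package
reimplements (frozen in `tests/testthat/helper-oracles.R` and asserted by
the acceptance suite); an exhaustive structural search found an essentially
unique convention set reproducing every printed $(k^\ast, n^\ast,$
effort$)$ cell:

* **Effect scale.** The detectable difference is absolute:
  $x = (\text{effect\%}/100)\cdot m$ mosquitoes per trap-visit (3 for the
  reference inputs). With two species, the mean of the two standard
  deviations and of the two expected catches is used.
* **Variance mapping.** $\sigma_b^2 = \sigma^2 = s^2(1-\rho_c/2)$, the
  average of the total variance $s^2$ (the user's squared standard
  deviation) and the within-location share $(1-\rho_c)s^2$. The cluster
  formula uses the total variance, $\sigma_T^2 = s^2$.
* **Visit-spacing lag.** $k$ visits spread over the season are
  $4(k_{max}+1)/k$ sub-units apart (quarter time-units, e.g. weeks when the
  unit is a month, spanning the $k_{max}+1$ unit boundaries of the
  season); $\rho_\Delta(k)$ is the dampened AR law at that lag
  ([visit_lag()]). Denser schedules are more correlated, which is what
  makes large $\rho$ favour *fewer* visits and large $\theta$ more. A
  literal reading that evaluates the law at lag $k-1$ is provably
  incompatible with the reference grid: the sample-size formula is affine
  in its correlation bracket, and no affine variance mapping can reconcile
  the printed optima at $\rho = 0.1, 0.5, 0.9$ under that lag.
* **Matching target.** $n_c$ is computed with cluster size 2 — the paired
  comparison conditions hosted by each location — giving design effect
  $1+\rho_c$ ($n_c = 19$, $n_c m = 285$ at the reference inputs). Using the
  per-trap catch $m = 15$ inside the inflation factor ($n_c m = 900$) is
  incompatible with every printed effort (285–294). The module-level
  [sample_size_cluster()] keeps the general $m$-unit formula; the choice of
  cluster size 2 is the optimiser's.
* **Sampling totals.** The optimal design collects
  $n^\ast k^\ast m$ mosquitoes. The independent baseline is the classic
  two-sample size $n_2 = 2(s/x)^2(Z_{\alpha/2}+Z_\beta)^2$ per group (the
  $k=1$ limit of the repeated-measures formula); without the pooling of
  $m$ units per visit, each group needs $n_2 m$ independent measurement
  events, so the independent total is $2 n_2 m^2$ mosquitoes (kept
  unrounded; the ratio is the quantity of interest). For the reference
  inputs the ratio is 61.2%, matching the published "almost 61%" summary,
  and coincides to three decimals with the variance ratio at the optimum
  (0.610) — the two displays of the same efficiency gain.

These are package design decisions, not re-derivations: the reference
implementation's source was not available, its printed outputs were. The
acceptance tests are the guardrail — any change to a convention that
breaks a printed cell fails the suite.

## Parameters that matter

| Parameter | Units | Reference value | Notes |
|---|---|---|---|
| `k` ($k_{max}$) | survey time units | 10 | season length; grid runs to $2k_{max}$ |
| `rho` | — | 0.2 | successive-value correlation; 0 = independent (conservative) |
| `theta` | — | 0.1 | decay dampening; 0 = enter an ACF directly |
| `effect_size` | % of expected catch | 20 | small effect by convention; 50 medium, 80 large |
| `sd_effect_species_*` | counts | 3 | SD of the effect |
| `n_mosquitoes_species_*` | counts/trap/visit | 15 | expected catch $m$ |
| `between_site_clustering` | — | 0.2 | ICC $\rho_c\in[0,1]$ |
| `alpha` | — | 0.05 | one of 0.1, 0.05, 0.025, 0.001 |
| `power` | — | 0.8 | target $1-\beta$ |
| `N`, `seasonality_noise`, `random_seed` | counts, counts², — | 2, 2, 2 | curve visualisation **only**; never touch power outputs |

The shipped defaults are illustrative, not field-derived; the CLI warns
when run with them untouched.

## The seasonal-curve generator

[simulate_seasonal_curve()] draws a stationary Gaussian process of length
$k_{max}$ with mean $N$, marginal variance `noise`, and lag-$l$ correlation
$\rho^{l^\theta}$, truncated at zero. It emulates what the correlation
parameters *look like* — larger $\rho$ smooths, larger $\theta$ roughens,
`noise = 0` exposes the flat noiseless signal — so users can tune
$(\rho,\theta)$ against curves from the literature. It does **not** emulate
real catch data: counts are not Gaussian, variance is not
time-constant, truncation at zero biases the ACF when `noise` is large
relative to $N$, and no data flows from this module into any sample-size
computation (enforced architecturally and by the invariance tests). A green
ACF-recovery test therefore establishes that the generator honours its own
correlation law, not that field data will.

## Numerical choices

* All sample sizes are ceiled and floored at 2 (at least two units are
  needed to estimate a variance); sizes above $10^9$ raise a domain error,
  and grid points whose total exceeds the feasibility cap (default $10^6$
  mosquitoes) are marked infeasible rather than returned.
* The classic t-test size $(t/(Z_\alpha x))^2$ is circular in $n$ through
  the t quantile's degrees of freedom. A naive fixed-point iteration
  oscillates for large effects, so the implementation returns the smallest
  integer $n \ge 2$ with $n \ge c\,(t_{df(n)}/(Z_\alpha x))^2$ — the stable
  resolution of the same fixed point, verified against a brute-force scan.
* The exact small-sample adjustment ([small_sample_adjustment()]) finds the
  smallest $n$ whose noncentral-F power (one-way design, $df_1 = k-1$,
  $df_2 = k(n-1)$, noncentrality $(n/n_{raw})(Z_{\alpha/2}+Z_\beta)^2$)
  reaches the target. It is exposed as a standalone operation and **not**
  applied inside the optimiser: the plain normal-quantile formulas
  reproduce the reference grid exactly, so the calibration arbiter keeps
  the switch off.
* Cholesky factorisation of the curve covariance applies an escalating
  diagonal jitter ($10^{-10}$ to $10^{-4}$ of the variance) before
  declaring the matrix numerically non-positive-definite.
* Optimiser ties break to the smallest $k$; the power sweep lists the
  eight standard levels 60–95% plus the user's target when it differs
  (eight rows when the target is one of the defaults, nine otherwise).

## Limitations

No explicit spatial autocorrelation model (clustering enters only through
the ICC); variance is assumed separable and time-stationary; seasonality is
a single correlation law, not a year-to-year varying process; Taylor's
power law is provided as a standalone historical utility and does not enter
the optimiser; estimating $\rho$, $\theta$, $a$, $b$ or the ICC from field
data is out of scope — they are inputs.
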
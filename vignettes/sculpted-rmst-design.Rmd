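---
title: "Two-stage RMST trial designs with sculpted critical regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage RMST trial designs with sculpted critical regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design problem

Phase II double-arm survival trials compare an experimental regimen E against
a control C, usually with 1:1 randomization and an interim look that can stop
the trial early for futility. The restricted mean survival time
(RMST), $R(\tau) = E\min(T, \tau) = \int_0^\tau S(t)\,dt$, measures the
treatment effect as life expectancy up to a clinically meaningful horizon
$\tau$ and, unlike the hazard ratio, stays interpretable when hazards are
non-proportional.

The conventional RMST superiority test rejects
$H_0\!: R_E(\tau) = R_C(\tau)$ when the estimated difference
$\hat D(\tau) = \hat R_E(\tau) - \hat R_C(\tau)$ is large. Under $H_0$,
however, $\hat D$ can be large merely because the *control* arm happened to do
badly. The **sculpted critical region** guards against such control-driven
rejections by also requiring the experimental arm itself to look good:

$$\hat D(\tau) > m \;\cap\; \hat R_E(\tau) > q.$$

In the two-stage version the trial stops for futility at the interim when
either $\hat D_1(\tau_1) \le m_1$ or $\hat R_{E1}(\tau_1) \le q_1$ and
rejects $H_0$ only when all four comparisons
$\hat D_1 > m_1,\ \hat R_{E1} > q_1,\ \hat D_2 > m_2,\ \hat R_{E2} > q_2$
hold (strict inequalities throughout; boundary equality never rejects). The
interim horizon $\tau_1$ is data-driven: the smaller of the two arms' largest
observed follow-up times, so both interim RMSTs live on a common, estimable
time window. The final horizon $\tau_2$ is fixed at design time.

## Trial worlds simulated by the package

`scenario_spec()` describes one generative world: entry times uniform on
$[0, a]$ (accrual period $a = N/r$ at constant rate $r$), dropout censoring
uniform on $[b, a+b]$ with minimum follow-up $b$, and per-arm event times
that are exponential or piecewise exponential,
$S_E(t) = \exp\{-\Delta_1 \lambda_0 (t \wedge CT) - \Delta_2 \lambda_0
(t - CT)_+\}$, which expresses proportional hazards ($\Delta_1 = \Delta_2$)
as well as early ($\Delta_2 = 1$) or late ($\Delta_1 = 1$) treatment
differences with a hazard-ratio change at time $CT$. Under $H_0$ both arms
follow the control model. The final analysis is at calendar time $a + b$;
the interim analysis at the expected accrual time of the interim cohort,
$a \tilde N / N$, which makes simulated operating characteristics
deterministic given the seed. Allocation is an exact $N/2$–$N/2$ split, so
sample-size grids move in steps of two.

What the generator deliberately does **not** emulate: non-uniform accrual,
covariates, unequal allocation, cure fractions and competing risks. Passing
operating-characteristic checks here therefore says nothing about, say,
accrual that accelerates over time — a real trial with a very different
censoring pattern should be re-simulated with its own generator.

## Calibrating the four critical values

Four thresholds cannot be identified from a single error constraint. The
package follows a three-part construction:

1. **Control function.** $f(\tilde N) = \exp(-\gamma \tilde N / N)$, with
   $\gamma > 0$, sets the conditional probability target
   $P(\hat R_{Ei} > q_i \mid \hat D_i > m_i) = f(\cdot)$ for each stage —
   $f(\tilde N)$ at interim, the stricter $f(N)$ at the final stage — so
   sculpting is lenient while information is scarce.
2. **Conditional quantiles.** With $(\hat D_i, \hat R_{Ei})$ treated as
   bivariate normal (their large-sample behavior), the moments of
   $\hat R_{Ei} \mid \hat D_i > m_i$ follow the truncated-normal identities
   implemented in `conditional_moments()` (inverse-Mills-ratio mean, the
   matching variance deflation), with the marginal means, variances and
   correlation estimated by Monte-Carlo from trials simulated **under the
   alternative only** (`stage_moments()`, outer-product covariance with
   divisor $B$). `q_from_m()` then maps any $m_i$ to its $q_i$ as a normal
   quantile of that conditional law. The conditional distribution is not
   exactly normal; the approximation avoids re-sampling at every grid point
   and its accuracy is checked against brute-force rejection sampling in the
   test suite.
3. **Empirical error control.** A grid over $(\gamma, m_1, m_2)$ —
   $m$-grids spanning the 1st–99th percentile of each stage's simulated
   differences under the alternative — is evaluated on $B$ paired null and
   alternative replicates (the same simulated trial contributes its interim
   and final statistics, preserving within-trial dependence). Combinations
   with empirical type I error above $\alpha_0$ are dropped; among the rest
   `rule = "max"` picks maximum empirical power (used when comparing rules
   at a fixed sample size) and `rule = "closest"` the smallest power at or
   above $1 - \beta_0$ (used inside the design search, where minimum
   over-power buys the largest early-stopping probabilities). Ties prefer
   larger $PET_0$, then larger $q_2$. The cross-stage joint normality of
   $(\hat D_1, \hat D_2)$ is deliberately *not* modeled — the control
   function is the only bridge between stages.

The **simple RMST rule** is the degenerate case $q_1 = q_2 = 0$ (an RMST is
non-negative, so only the differences are thresholded); the **two-stage
log-rank comparator** grid-searches its interim boundary $c_l$ and solves the
final boundary $c$ from the bivariate-normal constraint
$P(W_1/\sigma_1 > c_l,\ W/\sigma > c \mid H_0) = \alpha_0$ with the
between-stage correlation $\hat\rho_0 = \sqrt{\widehat{Var}(W_1) /
\widehat{Var}(W)}$ estimated from null replicates (the independent-increments
identity, free of proportional-hazards assumptions).

### Numerical choices

* **Gamma grid.** The default `default_gamma_grid()` spaces 56 values in
  $(0, 3]$, fine below $0.2$. The reachable sculpting threshold at a stage is
  $q = \mu_{cond} + z_{1 - f}\,\sigma_{cond}$; since
  $z_{1-f(\gamma)} = \Phi^{-1}(1 - e^{-\gamma})$ changes fastest for small
  $\gamma$, a uniform grid there would leave holes exactly where the
  empirical type-I-error boundary usually lies — a coarse grid that cannot
  reach the boundary silently sacrifices power. Calibration cost is linear
  in the number of grid values, so the grid is configurable.
* **m-grids** use quantiles of the *alternative-hypothesis* differences
  (81 points by default). Data-adaptive ranges cover the feasible boundary
  without scenario-specific tuning, and anchoring them under $H_1$ — the same
  replicates the conditional moments are estimated from — keeps the
  difference thresholds inside the range plausible for a real effect. Grids
  that reach into the null's left tail would let maximum-power selection pick
  strongly negative $m_2$, a degenerate rule that rejects even when the
  experimental arm is doing worse than control provided its own RMST is
  high; restricting the grid forecloses that near-single-arm behavior.
* **RMST estimation.** Product-limit estimate with Greenwood-type variance
  over event times before $\tau$; ties resolved events-first. The public
  `rmst()` refuses a $\tau$ beyond the largest observed time by default, but
  the Monte-Carlo engine evaluates the summation
  $\sum_j (t_{j+1} - t_j)\hat S(t_j)$ with $t_{D+1} = \tau$, which simply
  carries the step function to $\tau$ (`extend = TRUE`). Heavy-event
  configurations — e.g. a control hazard of 1.53/year with $\tau = 2.5$
  years — routinely exhaust every observation in an arm before $\tau$, so a
  strict estimability rule would discard most replicates; the carried
  integral is always defined and coincides with the strict value whenever
  the data do reach $\tau$.
* **Degenerate inputs.** Zero conditional variance returns $q$ equal to the
  conditional mean; a truncation point where $1 - \Phi(\theta)$ underflows
  raises an explicit error; zero-variance log-rank replicates are flagged
  and treated as non-rejections.
* **Selection among equal-power designs** prefers larger $PET_0$ and then
  larger $q_2$, a mild robustness heuristic (a larger final sculpting
  threshold keeps the experimental-arm requirement meaningful).

## Design search

`single_stage_n0()` first finds the smallest single-stage sample size
reaching the power target — the anchor $n_0$. `search_designs()` then scans
total sizes $N$ ascending from $0.9\,n_0$ (rounded up to even) with all
interim sizes $\tilde N < N$ on a configurable grid, calibrating each
requested method on shared replicate banks (final-stage statistics are
computed once per $N$; every interim size reuses the same simulated trials,
so methods are compared like-for-like). Designs with
$\alpha_E \le \alpha_0$ and $power_E \ge 1 - \beta_0$ are stored. When the
starting $N$ is itself feasible the scan also descends until no design is
found, since a smaller total size may still work; and it continues a few grid
steps (default 5) past the first feasible $N$, because the minimum-$EN_0$
design often sits at a slightly larger $N$ with an earlier interim. The
**minimax** design minimizes $N$ (ties by smaller $EN_0$), the **optimal**
design minimizes the expected null sample size
$EN_0 = \tilde N \cdot PET_0 + N (1 - PET_0)$ (ties by smaller $N$). The
stop-after-five-steps window is a pragmatic cap: $EN_0$ improvements beyond
it were not observed in the scenarios exercised here, and the window is a
plain argument (`n_extra_steps`) when a wider sweep is wanted.

Seeds follow a fixed discipline: one root seed deterministically spawns a
substream per (hypothesis, total sample size) via a Lehmer-style derivation,
so any design row can be reproduced in isolation and reruns are
byte-identical.

## Robustness

`robustness_profile()` freezes a calibrated rule and applies it to data
simulated under drifted hazards. Drifting the experimental hazard only moves
the alternative, so the type I error curve is flat; drifting the shared
control/null hazard moves both hypotheses, and there the sculpted rule is
more sensitive than the simple or log-rank rules — the price of cutting the
rejection region along the experimental-arm axis. The practical remedy is a
small sensitivity sweep over plausible control hazards (the profile makes
this a one-liner) and, if uniform error control is required, taking the most
conservative sample size in the sweep.

## Problem sizes used in the automated checks

Calibration examples and the packaged acceptance analysis use $B = 10{,}000$
replicates per hypothesis (the fixed-size comparison of simple versus
sculpted rules at $N = 100$, $\tilde N = 60$). Full design searches are
exercised at $B = 2000$ with sample-size strides of 4–8 and coarse interim
grids (strides 16–32 above floors matched to each scenario) — a deliberate
scaled-down profile: strides enter the reported sample sizes directly (a
stride-4 search can only land within 4 of any reference design), and
$B = 2000$ leaves roughly a one-percentage-point Monte-Carlo standard error
on power, which the feasibility filter turns into a systematic few-grid-step
downward drift of the smallest "feasible" size, so reproduced design rows
are expected to wobble by several grid steps. The unit and
property tests run on much smaller synthetic configurations whose expected
values are computed by independent oracles (closed forms, quadrature,
rejection sampling, `survival::survfit`, `survival::survdiff`).

## Known limitations

* Early stopping is for futility only; efficacy stopping would need four
  more boundaries and is out of scope.
* The conditional-quantile step is a normal approximation; it is accurate in
  the regimes tested but is not exact, and extreme truncation points are
  refused rather than extrapolated.
* Reported operating characteristics are in-sample for the calibration
  replicates; maximum-power selection over a large grid carries mild
  optimism. Re-evaluating a selected rule on fresh replicates
  (`empirical_oc()` on new `simulate_stage_stats()` output) quantifies it.
* The generator's idealizations listed above; in particular the interim
  analysis time is the *expected* accrual time of the interim cohort, not a
  random recruitment milestone.
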
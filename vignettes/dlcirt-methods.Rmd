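---
title: "Modeling disengaged responding with dependent latent class IRT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling disengaged responding with dependent latent class IRT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dlcirt)
```

## The model and its assumptions

Each person-by-item encounter carries a latent engagement class
$C_{ij} \in \{0, 1\}$. Conditional on solution behavior ($C_{ij} = 1$) the
response follows a Rasch model in ability $\theta_i$ and difficulty
$\beta_j$; conditional on disengagement the success probability is the
guessing constant $z_j = 1/M_j$, independent of person and item
characteristics. The observed response probability is the two-class
mixture

$$P(Y_{ij} = 1) = \pi_{ij}\,\mathrm{logit}^{-1}(\theta_i - \beta_j) + (1 - \pi_{ij})\, z_j,$$

and the engagement probability $\pi_{ij}$ is itself a logistic regression
on observables:

$$\mathrm{logit}\,\pi_{ij} = \alpha + \alpha_j d_j + \gamma \, l_{ij}
  + \gamma_{ac}\,AC_{ij} + \gamma_{tr}\,TR_{ij} + \gamma_{iv}\,IV_{ij}
  + \textstyle\sum \gamma_{uv} x_u x_v + \psi_i,$$

with $l_{ij}$ the natural log of the item response time in seconds
(uncentered, unstandardized), three dichotomous process indicators, their
optional six pairwise interactions, and a person-level engagement
threshold $\psi_i \sim N(0, \sigma_\psi^2)$ that may covary with
$\theta_i$. Key assumptions: responses are conditionally independent
across items given $(\theta_i, \psi_i)$; the covariates of the engagement
regression are treated as exogenous (fixed) regressors; missing responses
and encounters missing a covariate required by the fitted spec are
dropped from the likelihood rather than imputed.

## Identification conventions

Two conventions are defensible and both are implemented
(`theta_variance_mode`):

* **`free` (default):** $\theta$ has mean 0 and a *free* variance, all
  $\beta_j$ free. This is the unique convention that reproduces the
  published parameter counts of the six-model comparison menu
  (15/17/23/25/28/34 for 14 items with six item intercepts) and the
  implied LR dfs (2, 6, 2, 3, 6).
* **`fixed_1`:** $\mathrm{Var}(\theta) = 1$, as stated in the footnote of
  the published coefficient table. This conflicts with the published
  parameter counts, so it is exposed as an alternative, not the default.

Item-specific engagement intercepts are coded as a retained general
intercept plus dummy offsets for a selected subset of items; the full
per-item dummy coding is empirically underidentified in data of this
size, which is why a sequential selection procedure
(`select_item_intercepts()`) exists: each item's single-intercept
augmentation is tested by a df-1 likelihood-ratio test against the same
common-intercept base fit, and items significant at $\alpha = .05$
(default) are retained.

## Estimation

The marginal likelihood integrates $(\theta, \psi)$ out by
**non-adaptive Gauss–Hermite quadrature**, default 15 nodes per
dimension, with standard-normal nodes pushed through the Cholesky factor
of the latent covariance, and log-sum-exp stabilization (probabilities
floored at $10^{-12}$ inside logs). Optimization runs on an
unconstrained scale: variances via log, the $\psi$–$\theta$ correlation
via atanh, a freed guessing probability via logit. Analytic gradients
are implemented in compiled code and were verified against central
finite differences (agreement to $10^{-8}$); the pure-R reference
implementation of the same marginal likelihood (`marginal_loglik()`) is
kept as a second route and tested against the compiled kernel and
against brute-force Monte-Carlo integration.

**Multi-start:** the published analyses used a proprietary two-number
start specification whose exact semantics are not public; it is emulated
generically as `n_starts` jittered starts (start 1 unjittered, jitter SD
0.3 on the unconstrained scale), screened on a coarse 7-node grid, with
the best `n_final` polished to tight tolerance on the full grid. The
default is (20, 5); a replication flag records whether the two best
polished starts agree within 0.01 log-likelihood units. The coarse
screening grid is purely a warm-start device — every reported quantity
(estimates, SEs, information criteria, entropy, posteriors) is computed
on the full grid.

**Standard errors** come from the numerically differentiated observed
information (central differences of the analytic gradient) with a
delta-method transform to the natural scale. Wald $t = $ estimate/SE and
two-sided normal $p$ values follow the convention of structural-equation
software reports.

**Fit indices:** AIC $= -2LL + 2k$; BIC $= -2LL + k\ln N$; aBIC
$= -2LL + k\ln((N+2)/24)$ with $N$ the number of *persons* — persons are
the independent sampling units of the marginal likelihood, so they, not
encounters, enter the penalty. LR tests use the naive $\chi^2$ reference
even when a variance component sits on the boundary
($\sigma^2_\psi = 0$); this mirrors the published df-2 test of the
two-level extension and is anti-conservative there.

**Classification:** the posterior solution probability of an encounter
marginalizes — not plugs in — the latent variables over the person's
posterior on the quadrature grid. Entropy is the relative (normalized)
two-class form $1 - \sum_e H(p_e) / (n_e \ln 2)$, bounded in $[0, 1]$;
hard classification uses threshold 0.5 with ties assigned to solution
behavior.

## Process-data indicators

Navigation and option-selection events are the input. Definitions:

* **Response time**: sum of all of the item page's visit durations; a
  visit runs from the navigation click that led to the page to the click
  that leaves it. A final visit with no leaving click is closed at the
  person's last logged event and flagged.
* **Answer change**: a selection of a *different* option than the one
  previously selected on the same item; first selections and same-option
  re-clicks never count.
* **Text reread**: a navigation from the item's page to a text page of
  the same task; a hop between two pages of a long text is not counted
  again, and whether the person later returns to the item is not
  required (only the outgoing transition counts — the return leg is
  deliberately not a condition because the published definition names
  only the outgoing navigation).
* **Item revisit**: a navigation to the item's page that is not the
  first visit and with at least one *other item* visited since the last
  visit — so returning from a text reread is not a revisit.

All three are dichotomized (occurred at least once vs not) before
entering the engagement regression. When the response time is missing or
does not exceed zero seconds, all four indicators are set missing; such
encounters are excluded from the likelihood for specs that require them,
not imputed (in the motivating data, nonpositive response times occurred
only together with missing responses, so exclusion is the conservative
generalization).

**Navigation filter.** The published preprocessing removed "intermediate"
navigation events whose exact rules are in unpublished supplementary
material. The implemented stand-in removes a navigation event when its
resulting visit lasts under `min_dwell_ms` (default 1000 ms) *and* the
next navigation continues in the same direction of page order — the
signature of paging through, not staying. The filter is applied to a
fixed point, making it idempotent, and `min_dwell_ms = 0` is the
identity. Its reduction rate on the original logs cannot be validated
here; it is fully configurable.

Timestamp ties are broken by the log sequence number. Navigation by
panel click and by button are treated identically.

## The simulator: what it emulates, and what a green test establishes

`sim_config()` defines three stated worlds:

* **`recovery`** (the world under which parameter recovery is
  *guaranteed to be well-conditioned*): 14 four-option items,
  $\beta$ spread over $[-1.5, 1.5]$; log response times standard normal
  ($\mu_j = 0$, person slowness loading 0.6, residual SD 0.8);
  engagement coefficients $\alpha = 1.5$, $\gamma_{rt} = 1$,
  $\gamma_{tr} = -0.8$, other indicator coefficients and the six item
  intercepts 0; $\sigma^2_\psi = 1$, $\mathrm{corr}(\psi, \theta) = 0.5$,
  $\mathrm{Var}(\theta) = 1$. Crucially, the slowness factor is drawn
  **independent of $(\theta, \psi)$**: if response time loaded on
  $\psi$, the fitted model — which conditions on response time as an
  exogenous covariate — would be misspecified and unbiased recovery
  could not be expected. This was a deliberate design choice for the
  recovery world.
* **`paper_like`**: item response-time means spanning 17–36 s with
  log-RT SD 0.59, indicator marginal rates (0.14, 0.33, 0.07) hit by
  solving each indicator's logit intercept against its slowness loading,
  slowness correlated 0.5 with $\psi$, and 3% unvisited encounters.
* **`table5_like`**: the published extreme coefficients
  ($\gamma_{rt} = 11.26$, intercept $-21.52$, $\sigma^2_\psi = 7.26$,
  near-perfect $\psi$–$\theta$ correlation). These sit near separation
  and the parameter boundary; the scenario exists as a stress world,
  explicitly without recovery guarantees.

Indicator counts are a Bernoulli occurrence flag times a geometric tail
whose continuation probabilities approximate the published count
distributions. The response-time generator (lognormal with a person
slowness factor) is an implementation choice: the fitted model treats
response time as a covariate, so any positive generator is admissible.

What the simulator does *not* emulate: cognitively realistic reading
processes, position effects, not-reached patterns beyond unvisited
pages, or the empirical dependence structure of real navigation logs. A
green recovery test therefore establishes that the estimator is
consistent and approximately calibrated *under the model's own
assumptions* — it cannot establish that the model is right for any
particular test.

The event-log generator (`simulate_event_log()`) builds, per task, a
text visit, optionally a fast forward scan that the navigation filter
provably removes, one working visit per item carrying the planted
selections and text-reread cycles, and a revisit schedule arranged so no
two consecutive visits hit the same item (working visits are ordered by
decreasing revisit count so the schedule can always open on a different
item). Planted response times are split over the item's $1 + tr + iv$
visits in whole milliseconds with every visit at least 1200 ms — above
the filter threshold, so no real visit can be mistaken for noise. Plants
that violate these constraints (revisit in a single-item task, response
time shorter than $1.2 (1 + tr + iv)$ s) are generation errors, and
`simulate_plants()` trims random draws to feasibility before generating.

## Numerical choices

* Quadrature: 15 nodes per dimension default; doubling to 31 moves the
  marginal log-likelihood by under $10^{-4}$ per person on
  simulator-default data (tested). The degenerate-collapse acceptance
  check uses 61 nodes so quadrature truncation ($\sim 10^{-11}$) sits
  far below its $10^{-6}$ tolerance.
* Probability floor $10^{-12}$ inside logs; linear predictors clamped at
  $\pm 200$ before exponentiation in the compiled kernel (the logistic
  saturates at machine precision long before).
* The $y = 0$ mixture branch is computed as the exact complement of the
  $y = 1$ branch so the two sum to 1 in floating point.
* Start values: $\beta_j$ from the logit of the corrected
  proportion-correct, $\gamma_{rt} = 1$, other coefficients 0,
  $\alpha = 2$, $\sigma^2_\psi = 0.5$, correlation 0.
* Hard-classification ties (posterior exactly 0.5) go to solution
  behavior.

## Design decisions where the design was open

* **Sequential intercept selection** tests each candidate independently
  against one common base fit (not re-estimated per step), df = 1,
  default $\alpha = .05$; candidates are warm-started from the base
  estimates. Type-I calibration is verified by simulation.
* **BIC/aBIC sample size** is persons (see above).
* **Average classification probability** is reported both as the mean
  posterior probability and as the hard-class share, because the two
  summaries differ and published practice is ambiguous about which is
  meant.
* **Reporting scale**: the latent covariance is reported as
  $(\mathrm{Var}(\theta), \sigma^2_\psi, \mathrm{Cov}(\psi, \theta))$
  with delta-method SEs from the unconstrained
  $(\log, \log, \mathrm{atanh})$ parameterization.

## Known limitations

* The $\chi^2$ reference for boundary variance tests is
  anti-conservative; no mixture-$\chi^2$ correction is applied.
* SEs near the parameter boundary (e.g. $\sigma^2_\psi \to 0$,
  $|\mathrm{corr}| \to 1$, as in the `table5_like` world) are unreliable;
  the observed information can fail to invert, in which case SEs are
  returned as `NA`.
* The navigation filter is a principled approximation to unpublished
  preprocessing; extraction results on real logs will depend on its
  threshold.
* Only dichotomous responses, two classes, and the Rasch
  solution-behavior kernel are supported (no 2PL/3PL, no polytomous
  items, no three-class "slow guessing" variant).
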
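---
title: "Multiphase nonrespondent subsampling for hunting bag surveys: methods"
author: "multibag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiphase nonrespondent subsampling for hunting bag surveys: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multibag)
```

## The estimation problem

A population $U$ of $N$ active hunters carries bag counts $y_k \ge 0$ for a
given species, area and season; the target is the total
$t = \sum_{k \in U} y_k = N\bar y$. Bags are collected by mail
questionnaire, and only a subset of the sampled hunters reply. The split of
an SRSWOR sample $s$ into respondents $r$ and nonrespondents $m$ is not
random with respect to $y$: hunters with a null harvest (inactive or
unsuccessful — the overwhelming majority for most species) are the least
motivated to reply, so $\bar y_r$ overestimates $\bar y$. Because usable
auxiliary variables are rarely available in hunting-bag frames, the package
takes the design-based route: follow up an SRSWOR subsample of the
nonrespondents after each wave, ending with a personal-interview phase
meant to reach everyone.

## Estimators

**Two-phase (Hansen–Hurwitz).** Phase 1 samples $n_{s1} = N\nu$ hunters;
phase 2 interviews $n_{s2} = n_{m1}\nu_m$ of the $n_{m1}$ nonrespondents.
With full response at phase 2,
$$\bar y_{HH} = \frac{n_{r1}\bar y_{r1} + n_{m1}\bar y_{r2}}{n_{s1}}$$
is design-unbiased: the realized fractions $n_{r1}/n_{s1}$ and
$n_{m1}/n_{s1}$ estimate the weights of the (latent) respondent and
nonrespondent strata, so the design is a special case of two-phase sampling
for stratification. Its variance is
$$V_p(\bar y_{HH}) = \Big(\tfrac{1}{n_{s1}} - \tfrac{1}{N}\Big)S^2 +
\tfrac{1}{n_{s1}}\Big(\tfrac{1}{\nu_m} - 1\Big) W_M S_M^2,$$
with all dispersions in the $1/(N-1)$ convention — the package uses that
convention everywhere, including in the classical two-phase formulas that
were originally printed with $1/N$ dispersions. `hh_variance_estimate()`
implements the nonnegative unbiased estimator of this variance, whose
expectation the test suite confirms *exactly* by enumerating the complete
design space of a toy population (every first-phase sample, every
randomized-rounding branch, every subsample).

**Multiphase (El-Badry).** With $\ell$ mailing waves and an interview phase
$L = \ell + 1$, each wave subsamples the previous wave's nonrespondents.
The package writes the point estimator with realized sample sizes,
$$\hat t_{EB} = \sum_{i=1}^{L} \Big(\sum_{k \in r_i} y_k\Big)
\prod_{j=1}^{i} \frac{n_{m,j-1}}{n_{sj}}, \qquad n_{m0} = N,$$
rather than with the design fractions: randomized rounding makes realized
sizes the meaningful quantities, and the two forms coincide when sizes are
exact (a test asserts this). Three *different* products appear in this
theory and are easy to conflate; the implementation names them separately:

* the **forward-fraction product** $\prod_{j \le i} \nu_j$ in the
  stratum-weight estimators $\hat W_{Ri}$;
* the **inverse-fraction product** $\prod_{j < i} 1/\nu_j$ in the compact
  closed-form variance (`eb_variance_true()`);
* the **size-ratio products** $\prod_{j<i} n_{m,j-1}(n_{m,j-1}-1) /
  (n_{sj}(n_{sj}-1))$ in the unbiased variance estimator
  (`eb_variance_estimate()`), which also evaluates the backward recursions
  $t_i = \sum_{r_i} y_k + (n_{mi}/n_{s,i+1})\,t_{i+1}$ (and likewise $z_i$
  with $y_k^2$) from phase $L$ down to phase 1.

At $L = 2$ every multiphase quantity reduces to its two-phase counterpart;
the suite asserts equality to $10^{-10}$ relative on random datasets, and
checks the $L = 3$ closed-form variance against an independently coded
explicit version.

## Behaviour when the interview phase falls short

The unbiasedness above needs a 100 % response rate at phase $L$. In
practice some interviewees are never reached. The package adopts one
convention for that regime, applied consistently to the point estimator and
the variance estimator: **unreached last-phase units are treated as null
harvests** — the last-phase stratum total is estimated by
$\sum_{k \in r_L} y_k$ spread over the whole subsample $n_{sL}$. This is
the convention under which the reference bias-index table and curves are
reproduced; it makes both estimators biased *downwards* when
$\pi_m(L) > 0$ (the Monte Carlo engine quantifies by how much), and it
leaves all formulas unchanged whenever the interview phase does reach
everyone. A phase whose nonrespondent pool empties, or whose drawn size
rounds to zero, simply terminates the chain: later phases are vacuous and
only realized terms are summed.

Degenerate sizes in variance estimation are never silently zeroed: a
dispersion whose algebraic coefficient vanishes is not evaluated, but a
dispersion that is needed with fewer than two contributing units yields
`NaN` together with a warning of class `"multibag_degenerate_variance"`.

## The superpopulation model

Finite populations are drawn from the hurdle-at-zero Poisson model
$$\Pr(Y = 0) = p, \qquad
\Pr(Y = y) = \phi\, e^{-\lambda}\lambda^y / y! \;\; (y \ge 1), \qquad
\phi = \frac{1-p}{1-e^{-\lambda}},$$
with mean $\mu = \phi\lambda$ and variance
$\mu_2 = \phi\lambda(1+\lambda) - \phi^2\lambda^2$; $\phi = 1$ recovers the
plain Poisson. Given a target mean, `solve_lambda()` uses the closed form
$\lambda = W_0(De^D) - D$, $D = \mu/(p-1)$ (upper Lambert branch, via
pracma), with a bisection fallback on the transcendental equation when the
Lambert evaluation is numerically unreliable; a solution exists iff
$\mu > 1 - p$, and out-of-domain input names the violated condition. The
pmf normalization test truncates the support where the Poisson upper tail
drops below $10^{-12}$.

The reference study population is $N = 10\,000$ hunters with $p = 0.955$
and $\lambda = 7$ ($\mu \simeq 0.315$) — magnitudes estimated from a
national hunting-bag survey for a duck species at the scale of one
administrative department. Within a simulation study the population is
generated **once** and held fixed; only sampling and response are
replicated (the design-based frame conditions on $U$). Any specific
realized population (and in particular its exact count $N_0$ of null bags)
is seed-dependent; checks on generated populations are therefore
distributional (binomial spread of $N_0$, CLT band on the mean).

## The nonresponse mechanism

Nonresponse is simulated by partitioning the current pool into respondents
$R$ and nonrespondents $M$ with two propensities: $\pi_m \in [0,1)$, the
propensity to nonrespond (all causes confounded), and $\pi_z \in [0,1]$,
the propensity *among nonrespondents* to nonrespond because the bag was
zero. Concretely: $N_M$ and $N_Z$ are drawn with expectations $N\pi_m$ and
$N\pi_z\pi_m$ (randomized rounding); $Z$ is an SRSWOR of $N_Z$ zero-bag
units; $R$ is an SRSWOR of $N - N_M$ units from the pool minus $Z$; $M$ is
the complement. The "hole" $Z$ under-covers the null-bag stratum among
respondents, so $E(n_m) = n_s\pi_m$, $E(n_z) = n_s\pi_z\pi_m$, and the
respondent-mean bias index is $1/(1 - \pi_z\pi_m)$ — driven by the product
only, independent of the sampling fraction and symmetric in the two
propensities (all asserted by tests). $\pi_z = 0$ gives the ignorable MCAR
limit.

Two choices here were genuinely open:

* **Feasibility clipping.** $N_Z$ is clipped to $\min(N_M, N_0)$; clipping
  events are counted and reported (`clip_events`) so a user can detect
  regimes — e.g. almost no null bags in the pool — where clipping distorts
  $E(N_Z)$. At the reference settings clipping does not occur outside
  deliberately extreme fixtures.
* **Fresh partitions per phase.** Respondence is redrawn independently on
  each nonrespondent pool: a hunter who refused because of a null bag at
  wave $j$ may respond at wave $j+1$. This follows the mechanism's
  phase-by-phase definition; persistent reluctance (correlated response
  behaviour across waves) is a plausible alternative that the plan type
  does not currently model. $\pi_z$ is shared across phases by default,
  with per-phase overrides for sensitivity analysis.

## Monte Carlo engine and random numbers

`run_scenario()` fixes one population, then for each grid cell replicates
survey + estimation and reports the bias index $r = E(\hat\omega)/\omega$
with its Monte Carlo standard error, and optionally
$r_V = E(\hat V)/V_{MC}$ for the variance estimator. The truth for $r$ is
the fixed population's $\bar y$, not the superpopulation mean. All
replicate randomness uses R's `"L'Ecuyer-CMRG"` generator (MRG32k3a): one
substream per replicate via `parallel::nextRNGStream`, chained across grid
cells in row order, so a whole scenario is reproducible bit-for-bit from
`(config, seed)` — and per-phase target sizes are materialized by
randomized rounding between $\lfloor\alpha\rfloor$ and
$\lceil\alpha\rceil$ in every replicate, since deterministic rounding would
bias the expected sample sizes.

Randomized rounding has one theoretical side effect worth noting: the
closed-form variances assume exact fractional subsample sizes, and
$E(1/n_{s2})$ under rounding slightly exceeds $1/(\nu_m n_{m1})$ by
convexity. The effect is negligible at realistic sizes (the Monte Carlo
agreement tests absorb it in their error bands); the exact enumeration test
of the closed form therefore uses a census first phase, where no rounding
occurs. The enumeration fixtures also keep every realizable
$n_{m1}\nu_m \ge 1$, because a subsample rounded to zero would make the
phase-2 term vacuous and break exact unbiasedness — a regime far from any
realistic design.

## Problem sizes used by the test suite

Structural and oracle tests run on toy instances (populations of 8–9 units
enumerated exhaustively; populations of 200–400 for moment and
stratified-response checks, 3 000–4 000 replicates). The end-to-end checks
use the reference population ($N = 10\,000$) with 1 000 replicates per
table cell, 10 000–20 000 replicates for point-estimator bias indices and
50 000 for the variance-estimator index; the acceptance script uses the
same sizes. Stochastic assertions use 4 Monte Carlo standard errors
(comparisons against the reference table add the table's own equal-sized
Monte Carlo error in quadrature).

## Limitations

* The simulator models a single nonignorable cause (null-harvest
  reluctance). Response error, prestige bias, recall error,
  misclassification and coverage error are out of scope, as are
  reweighting/imputation adjustments and regression corrections across
  waves.
* Only equal-probability designs are supported (SRSWOR at every phase); no
  stratified or unequal-probability first phases, and no cost/precision
  optimization of the fractions $\nu_i$.
* The hurdle-at-zero Poisson is the only superpopulation model; it
  reproduces the zero inflation and overdispersion that matter for the
  bias mechanism, but not, e.g., hunter-level covariate structure — so
  passing tests demonstrate properties of the design and estimators, not
  of any particular real survey.
* Confidence intervals are limited to standard errors; distributional
  approximations for $\hat t_{EB}$ are not provided.
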
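---
title: "Modelling cumulative fertility across populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cumulative fertility across populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fertgrowth)
```

## The problem

Comparative demography often asks how women's subsistence strategies and
market integration relate to fertility across small-scale societies. The
raw material is cross-sectional reproductive histories: each woman's age at
interview, her cumulative number of live births (parity), and individual
measures of economic life — the share of her activities in foraging,
farming or wage labour, diet composition, livestock, land, income, years of
education, occupation and residence type. Populations differ enormously in
baseline fertility, so the interesting comparisons are *within* population,
pooled across populations by a multilevel model.

`fertgrowth` implements this analysis end to end: data validation and
within-population standardization, a hierarchical Bayesian count model,
posterior summarization, fertility contrasts, and a synthetic-data
generator with known ground truth so the whole pipeline is testable without
any field data.

## The model

Cumulative parity is a saturating function of age: zero before
reproductive maturity, rising through the reproductive years, flat after
menopause. We model the expected parity of woman $i$ at age $a_i$ with a
growth curve

$$\lambda_i = M_i \left(1 - e^{-k (a_i - a_0)}\right)^{b},$$

where $M_i$ is the woman's asymptotic (completed) parity, $k$ (per year)
sets how fast the curve saturates, and $b$ delays the take-off, reproducing
the slow start of reproductive careers. $a_0$ (default 0) anchors where the
curve leaves zero; it is configurable because the data (ages 14 and above)
carry little information on the pre-reproductive segment.

The observed count is one-inflated Poisson,

$$y_i \sim \theta\,[y_i = 1] + (1 - \theta)\,\mathrm{Poisson}(\lambda_i),$$

because observed parity distributions carry excess mass at exactly one
live birth relative to a Poisson fit — a mixture of reporting conventions
and genuinely truncated reproductive careers. $\theta$ is global by
default; a per-population option exists (`theta_scope = "population"`) and
matters only when the parity-1 excess varies strongly by site.

The hierarchy and the focal predictor enter the log asymptote:

$$\log M_i = \alpha + \alpha_{pop[j(i)]} + \left(\mu_\beta + \beta_{pop[j(i)]}\right) z_i,$$

with $\alpha_{pop} \sim N(0, \sigma_{pop})$ and $\beta_{pop} \sim N(0,
\sigma_\beta)$. $z_i$ is the focal predictor as a *within-population*
z-score (or a 0/1 category), so $\mu_\beta$ is the cross-cultural pooled
effect of one within-site SD and $\beta_{pop}$ the partially pooled
population deviation. Exactly one focal predictor is fitted per model:
the predictors measure overlapping dimensions of subsistence and are
deliberately not entered jointly. A population-level grouping
(market-integration level, subsistence typology) can replace the woman-level
predictor, entering as fixed effects on $\log M$. An optional woman-level
deviation $u_i \sim N(0, \sigma_u)$ on $\log M$ (`woman_effect = TRUE`)
captures stable individual heterogeneity; it is off by default because the
reported estimands are population-level and the extra $n$ parameters slow
mixing considerably.

Predictors enter $M$ only (not $k$ or $b$): the reported quantity is
asymptotic fertility, which $M$ governs; age-pattern effects are not
separately identified in cross-sectional parity data of this shape.

### Priors

All priors are weakly informative and were fixed once, by prior-predictive
reasoning (completed parity spanning roughly 1–15 births), before any
recovery experiment: $\alpha \sim N(\log 5, 1)$, $\mu_\beta \sim N(0,
0.5)$, hierarchical scales half-Normal(0.5), $\log k \sim N(\log 0.05,
0.5)$, $\log b \sim N(0, 0.5)$, $\theta \sim \mathrm{Beta}(2, 18)$ (mean
0.1), group effects $N(0, 1)$. They are all overridable through
`oipgrowth_priors()`.

## Reported quantities

Predicted cumulative fertility is the model expectation at age 60,

$$\mathrm{CF} = E[y \mid \text{age} = 60] = \theta + (1 - \theta)\,\lambda(60),$$

computed *per posterior draw* and then summarized — the posterior median
($\widetilde{CF}$) with a 90% highest-posterior-density interval, never a
summary of summaries. Note the full mixture expectation is used, including
the $\theta$ term, because that is what the outcome model says the expected
count is. Contrasts $\Delta\widetilde{CF}$ are per-draw differences: $z =
1$ minus $z = 0$ for a 1-SD contrast (category 1 minus category 0 for
binary predictors; later minus earlier level for ordered groupings, so the
high-versus-low market-integration contrast is negative when market
integration predicts lower fertility). The pooled contrast sets
$\beta_{pop} = 0$ (the population-mean woman); per-population contrasts
condition on the partially pooled $\beta_{pop}$ draws from the same fit
rather than refitting per site.

Evidence strength follows the posterior sign probability
$PP = \max(\Pr(\Delta > 0), \Pr(\Delta < 0))$: *strong* at $PP \ge 0.9$,
*moderate* at $0.8 \le PP < 0.9$, *weak* below. The HPDI is the
deterministic sorted-sample shortest window (ties broken toward the lower
bound) rather than a kernel-density construction, so it is exactly
reproducible and checkable against a brute-force oracle; the equal-tailed
interval is emitted alongside it since the two differ on skewed
posteriors.

## Inference

Fitting is by the package's Hamiltonian Monte Carlo sampler: leapfrog
trajectories over the analytically differentiated log posterior,
dual-averaging step-size adaptation (target acceptance 0.8), a diagonal
mass matrix estimated during warmup, and non-centred parameterizations of
all hierarchical effects. Trajectory lengths are drawn uniformly between
half and all of `max_leapfrog` (default 48 — the growth-shape parameters
$\alpha$, $k$, $b$ are strongly correlated in the posterior and short
trajectories mix poorly). Transitions with non-finite or exploding energy
(error > 1000) are counted as divergences. Each fit reports split
$\widehat{R}$ and effective sample size for every parameter and warns —
never silently passes — when $\widehat{R} > 1.01$ or any divergence
occurs. Every entry point takes an explicit seed, and a fit is
bit-reproducible given (seed, chains, data) on a fixed platform.

Numerical notes: parities other than one use the Poisson log-density in
closed form with precomputed normalizing constants; the parity-one mixture
density is bounded below by $\theta$, which keeps its gradient stable; a
non-finite log posterior anywhere in a trajectory simply rejects the
proposal.

## The synthetic-data generator

`fert_truth()` fixes a complete data-generating process — the very process
the model assumes: population intercepts (optionally pinned to group-level
CF baselines), partially pooled slopes, ages uniform on 14–85 (the age
distribution of the motivating field data is not published; a uniform is a
neutral default and a stationary pyramid changes nothing structurally,
because age enters only through the saturating curve), within-population
standard-normal predictors, one-inflated Poisson outcomes.
`simulate_fertility()` is deterministic given the truth's seed and emits
the same CSV dialect the data model reads, plus a YAML truth sidecar.
`inject_missingness()` blanks predictors in chosen populations to mimic
real coverage, where each measure is available in only a subset of sites.

`paperlike_truth()` is the study-scale scenario: 27 populations, 10,250
women, group-level CF baselines solved by least squares to sit at the
published posterior medians (5.5 / 4.5 / 3.53 by market-integration level,
4.6 / 5.61 / 4.09 by the three main subsistence typologies — the
medium-MI, pastoralist and fisher values are not published and were set
once to plausible interpolations of 4.5, 4.5 and 5.0), with subsistence
types crossed with market integration the way small-scale societies
pattern empirically (foragers mostly low-MI, agriculturalists mostly
medium/high). The two sets of published group medians are not exactly
compatible as margins of one population-level quantity (their implied
overall means differ), so the solved baselines are a least-squares
compromise that lands within about 3% of every target. The scenario's one
generated predictor carries a pooled effect calibrated in closed form so
the true pooled 1-SD contrast equals +0.33 births.

Because this scenario exists to pin group-level truths, it conditions the
realized ensemble on them (`exact_calibration = TRUE`): population
intercept deviations are projected orthogonal to the group indicators and
slope deviations are recentred, so the generated dataset's group-level
baselines equal the scenario's targets for *every* seed rather than only
in expectation (free draws would let 27 populations' noise move a group
mean by 10–20% between seeds). Population-to-population spread is
retained; uncalibrated `fert_truth()` scenarios — including everything the
recovery tests use — keep fully free draws.

What passing recovery tests on these data does *not* show: robustness to
real-data features the generator omits — age-heaping, recall error,
mortality selection of high-parity women, non-normal predictor
distributions, or confounding between predictors. The generator checks the
pipeline, not the portability of the model to any particular field
dataset.

## Validation scales

The test suite exercises recovery at desk scale, chosen to keep the full
suite in the tens of minutes on one core: twenty replicates of 5
populations × 2,000 women for the pooled 1-SD contrast (true $\mu_\beta =
0.3$, $\theta = 0.1$; the 90% HPDI must cover the true contrast in at
least 14 of 20 and get the sign right in at least 18 of 20), one
6-population, 1,500-woman two-group scenario with a true CF difference of
−2.0 births, and bit-level determinism of the simulate–fit–report
pipeline. The full-data replication against the archived cross-cultural
deposit is exposed as `fit_all_predictors()`, a long-running optional
workflow run only when the deposit CSV is available locally.

## Known limitations

- The exact growth-curve parameterization used by the original analysis is
  not published; ours is the standard saturating family from the
  life-history literature, and $k$ and $b$ are only weakly identified from
  parity data at ages that mostly sit past saturation (the CF estimand is
  insensitive to this).
- Mortality/selection processes are not modelled: women must survive to
  interview, which the generator also does not emulate.
- Per-population estimates are conditional (random-effect draws from the
  joint fit), not independent per-site fits.
- The sampler is a fixed-length HMC, not a dynamic no-U-turn sampler;
  badly scaled custom priors may need a larger `max_leapfrog`.
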
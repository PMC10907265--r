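# fertgrowth

Hierarchical Bayesian modelling of women's cumulative fertility across
populations.

## What it does

Cross-cultural demography asks whether individual subsistence strategies
(foraging, farming, wage labour, livestock, land, education, ...) predict
fertility once populations' very different baselines are respected. The
raw data are cross-sectional reproductive histories: each woman's age at
interview, cumulative live births, population, and predictor measurements
that are each available in only a subset of sites.

`fertgrowth` models cumulative parity `y_i` of woman `i` in population
`j(i)` as a **one-inflated Poisson** whose rate follows a saturating
**growth curve** of age:

```
y_i  ~  θ·[y_i = 1] + (1 − θ)·Poisson(λ_i)
λ_i  =  M_i · (1 − exp(−k·(a_i − a0)))^b
log M_i = α + α_pop[j(i)] + (μ_β + β_pop[j(i)])·z_i
```

with partially pooled population intercepts `α_pop ~ N(0, σ_pop)` and
slopes `β_pop ~ N(0, σ_β)`, and `z_i` the focal predictor standardized
*within* population. Fitting is by the package's Hamiltonian Monte Carlo
sampler (analytic gradients, dual-averaging step-size adaptation, diagonal
mass matrix, split R-hat / ESS / divergence diagnostics). The headline
quantities are the predicted cumulative fertility at age 60,
`CF = θ + (1 − θ)·λ(60)`, summarized per posterior draw as the median
(`CF~`) with 90% highest-density interval, and its contrasts `ΔCF~`
(+1 within-population SD of a predictor, or between population groups),
labelled by the posterior sign probability (strong ≥ 0.9, moderate ≥ 0.8,
weak below).

A synthetic-data generator with known ground truth
(`fert_truth()` / `simulate_fertility()`) makes every stage testable with
no field data; `paperlike_truth()` reproduces the scale and group-level
structure of the published 27-population, 10,250-woman cross-cultural
database.

## Worked example

```r
library(fertgrowth)

# a known truth: 5 populations, 2,000 women, pooled 1-SD effect 0.3 on log M
truth <- fert_truth(n_populations = 5, n_women = 2000,
                    mu_beta = c(z = 0.3), theta = 0.1, seed = 11)
sim <- simulate_fertility(truth)

fit <- oipgrowth(sim, predictor = "z", chains = 2,
                 warmup = 500, iter = 500, seed = 5)
print(fit)
#> One-inflated Poisson growth model of cumulative fertility
#>   focal predictor: z
#>   data: 2000 women, 5 populations
#>   draws: 1000 ( 2 chains x 500 iterations, seed 5 )
#>   max R-hat 1.008, min ESS 179, 0 divergent transition(s)
#>   pooled CF~ at age 60: 4.39 (90% HPDI [3.72, 5.17])

contrast_1sd(fit, scope = "pooled")
#> Cumulative-fertility contrasts for 'z'
#>  predictor  scope scope_id cf_or_delta median hpdi_lower hpdi_upper    pp  label    n
#>          z pooled   pooled       delta  1.462      0.704      2.144 0.998 strong 2000
```

The pooled `ΔCF~` of ~1.46 births per within-population SD, with 90% HPDI
covering the generating value (`true_delta_cf(truth)` = 1.57) and a
"strong" evidence label, is the parameter-recovery pattern the test suite
checks systematically. For group-level questions, fit
`oipgrowth(sim, group = "market_integration")` and summarize with
`group_cf_contrast()`; `contrast_table()` writes the fixed reporting
schema to CSV and `plot_forest()` draws the per-population forest plot.

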
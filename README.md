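# lugshift

Behavioural game models of minority-language shift for locality-level
survey data.

In bilingual societies like the Basque Country, Ireland and Wales, everyone
speaks the majority language A while a minority also speaks B — yet the
observed use of B (street conversations in Basque, daily use of Irish and
Welsh) falls well short of what the share of bilinguals would allow, even
with education systems producing new speakers. `lugshift` models this as
the outcome of strategic language choice under imperfect information: in
the **Language Use Game (LUG)** each bilingual either **Reveals**
bilingualism (speak B with any bilingual; pay a frustration cost
$c(\alpha)$ when forced back to A by a monolingual) or **Hides** it (speak
A, answer in the partner's language). With bilingual proportion $\alpha$,
payoff $m(\alpha)$ for conversing in B and $n$ for A, the replicator
dynamics

$$\dot p = p(1-p)\left[\alpha\,(m(\alpha)-n)(1-p) - c(\alpha)(1-\alpha)\right]$$

drives the Reveal fraction $p$ to the evolutionarily stable convention

$$p^* = 1 - \frac{(1-\alpha)\,c(\alpha)}{\alpha\,(m(\alpha)-n)} \in (0,1),$$

so a fraction $(1-p^*)^2$ of bilingual-bilingual encounters is conducted in
A: language shift is built into the stable equilibrium. The empirical layer
fits the derived predictive models of street use,
$PKE(\alpha) = \tilde\beta_1\alpha^2(1-\alpha)(\alpha^{\beta_3}-\alpha)^{\beta_2-1}$,
and daily use,
$PDU(\alpha) = \check\beta_1\alpha(1-\alpha)(\alpha^{\beta_3}-\alpha)^{\beta_2-1}$,
to locality tables by constrained nonlinear least squares, with
pairs-bootstrap confidence bands and a local-linear nonparametric
specification check.

The package is for quantitative sociolinguists and modellers of cultural
trait competition who want the full pipeline — game theory core, dynamics,
estimation, validation — runnable end-to-end on synthetic survey data with
the statistical structure the analysis assumes (binomial observation noise
from finite conversation/respondent counts).

## What's in the box

| Layer | Functions |
|---|---|
| Game core | `payoff_spec()`, `lug_payoff_family()`, `validate_assumptions()`, `expected_payoffs()`, `weighted_benefit()`, `ess_equilibrium()` |
| Dynamics | `rd_rhs()`, `integrate_rd()`, `classify_rest_points()`, `abm_state()`, `simulate_abm()` |
| Predictive models | `empirical_p_star()`, `predict_street_use()`, `predict_daily_use()`, `street_use_random_match()`, `random_match_ceiling()`, `aggregate_localities()` |
| Estimation | `fit_predictive_model()`, `bootstrap_band()`, `nonparametric_check()` |
| Synthetic data | `synthetic_config()`, `generate_localities()`, `generate_panel()` |
| I/O & pipeline | `read_locality_table()`, `write_locality_table()`, `pipeline_config()`, `run_pipeline()` |

## Worked example

```r
library(lugshift)

# Theory: a locality with 40% bilinguals under the built-in payoff family
spec <- lug_payoff_family(mu = 2.5, kappa = 0.5, n = 1, alpha_star = 0.9)
ess_equilibrium(spec, alpha = 0.4)
#> LUG equilibrium at alpha = 0.4
#>   ESS p* (Reveal fraction): 0.700000
#>   shift probability (1-p*)^2: 0.090000
#>   B-use probability in bilingual pairs: 0.910000
```

70% of this locality's bilinguals Reveal in equilibrium, and 9% of
bilingual-bilingual street encounters still happen in the majority
language — that is the predicted shift. Integrating the replicator ODE
from any interior start confirms the closed form:
`attr(integrate_rd(0.05, 0.4, spec), "converged_to")` returns `0.7`.

```r
# Estimation: synthetic street-use survey, 150 localities, 500 recorded
# conversations each, fitted and validated end to end
truth <- empirical_params(0.9, 1.4, 0.3, model_kind = "street")
cfg <- pipeline_config(
  synthetic = synthetic_config(150, truth, obs_counts = 500, seed = 42,
                               year_label = 2016),
  model_kind = "street", language_label = "synthetic_street",
  n_boot = 199, seed = 7, out_dir = "demo_run")
run <- run_pipeline(cfg)
run$results[["2016"]]$fit
#> Predictive street-use model fit (150 localities)
#> Empirical street-use model parameters:
#>   beta1 = 0.678938, beta2 = 1.29165, beta3 = 0.0001, c2 = 0
#>   RSS: 0.00915057   converged: TRUE
#>   bootstrap band: 90% pointwise, 199 replicates
run$results[["2016"]]$np_check
#> Nonparametric specification check: 88% of grid inside the band (bandwidth 0.04276, loo-cv)
```

The fitted curve tracks the generating truth closely even though the
individual shape parameters sit on a weakly identified ridge at this noise
level (see the methods vignette, `vignettes/language-use-game.Rmd`); the
nonparametric regression stays inside the 90% band on 88% of the grid,
endorsing the parametric specification. The output directory contains the
per-year fit report, band, nonparametric-check and prediction-curve tables
plus a JSON manifest; reruns with the same config and seed are
bit-identical.

```r
# The aggregation pitfall: locality-level vs aggregate street use
aggregate_localities(weights = c(1, 5), alpha = c(0.8, 0.2),
                     use = c(0.5, 0.02))
#> $alpha
#> [1] 0.3
#> $use
#> [1] 0.1
random_match_ceiling(c(0.8, 0.2, 0.3))
#> [1] 0.64 0.04 0.09
```

Each locality sits far below its own random-matching ceiling (0.5 < 0.64,
0.02 < 0.04) — clear shift — while the aggregate (0.1) exceeds the
aggregate ceiling (0.09), masking it entirely.

## Data format

Locality tables are plain CSV with columns `locality_id`, `year`,
`n_bilinguals`, `alpha`, `observed_use`, `use_kind` (`street` or `daily`).
`read_locality_table()` supports column remapping for survey-style headers
and a `percent_cols` flag for tables that store percentages; proportions
above 1 without that flag fail loudly rather than being silently rescaled.
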
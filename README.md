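# colliderbias

Studies that regress an outcome on a polygenic score *G* together with an
environmental or phenotypic covariate *E* — to separate genetic from
environmental contributions, or to test G×E moderation — implicitly
assume *E* is exogenous. When *E* is heritable (gene-environment
correlation, pleiotropy) and also shaped by unmeasured factors *U* that
affect the outcome, adding it to the model conditions on a collider: the
blocked path G → E ← U → Y opens, the score coefficient deflates, the
covariate coefficient inflates, and R² overstates the variance the model
truly explains. `colliderbias` provides the machinery to quantify,
simulate and correct this endogenous selection bias.

## The model

With `G, U, Z ~ N(0, 1)` independent and *E* standardized to unit
variance,

    E = λ·G + δ·U + π·Z + ε_E,        Var(ε_E) = 1 − λ² − δ² − π²
    Y = β·G + γ·E + θ·G·E + κ·U + φ·E·U + ε_Y,   ε_Y ~ N(0, σ_Y²)

so λ, δ, π are exactly corr(G,E) (the rGE), corr(U,E) and corr(Z,E). For
the additive model the large-sample OLS biases have closed form

    bias_G = − λδκ / (1 − λ²)         bias_E = + δκ / (1 − λ²)

and the R² inflation is `(2γδκ + (δκ)²/(1−λ²)) / Var(Y) ≥ 0`, zero
exactly when δκ = 0.

The package exposes four layers, each tidyverse-native (tibbles in and
out, `tidy()`/`glance()` methods, `autoplot()`):

| layer | functions |
|---|---|
| structural simulator | `collider_params()`, `generate_cohort()` |
| closed-form analytics | `collider_bias_g()`, `collider_bias_e()`, `population_fit()`, `sensitivity()`, `percent_reduction()` |
| estimators | `fit_additive()`, `fit_interaction()`, `fit_iv()` (2SLS) |
| experiment grids | `grid_spec()`, `run_grid()`, `run_exu_scenario()`, `export_results()`, `plot_bias_curves()`, `plot_r2_inflation()` |

## Worked example: auditing a published attenuation

A score coefficient of 0.185 drops to 0.055 once a heritable covariate
(years of schooling) enters the model. How much of that drop could be
collider bias, assuming corr(G,E) = 0.300 and a confounder correlated
0.250 with both covariate and outcome?

```r
library(colliderbias)

sensitivity(0.185, 0.055, 0.300, 0.250, 0.250)
#> <collider_sensitivity>
#>   implied collider bias : -0.0206
#>   observed attenuation  : 0.1300
#>   fraction attributable : 15.8%

percent_reduction(0.185, 0.055)
#> [1] 70.27027
```

Under those assumptions the collider mechanism alone produces a bias of
magnitude 0.021, about 16% of the observed 70% reduction — a real but
minor share; the rest must come from mediation or other confounding.

The population-level decomposition for the same correlations:

```r
population_fit(collider_params(lambda_ge = 0.3, delta_ue = 0.25, kappa_uy = 0.25))
#> <bias_decomposition> population OLS of Y on (G, E)
#>   G: plim 0.5794  (truth 0.600, collider bias -0.0206)
#>   E: plim 0.6687  (truth 0.600, bias +0.0687)
#>   R2 fitted 0.4897 vs true share 0.4514 (inflation +0.0382)
```

And the simulated counterpart — 200 cohorts of 10,000 per cell, strong
confounder, rGE swept over 0, 0.25, 0.5:

```r
spec <- grid_spec("additive", rge_values = c(0, 0.25, 0.5),
                  u_strengths = 0.38, n_reps = 200)
res <- run_grid(spec)
dplyr::filter(res, term == "g") |>
  dplyr::select(rge, u_label, mean_estimate, mean_bias, r2_inflation)
#> # A tibble: 3 × 5
#>     rge u_label mean_estimate  mean_bias r2_inflation
#>   <dbl> <chr>           <dbl>      <dbl>        <dbl>
#> 1  0    strong          0.600 -0.0000504       0.0952
#> 2  0.25 strong          0.563 -0.0369          0.0889
#> 3  0.5  strong          0.504 -0.0956          0.0841
```

With no rGE the score estimate is unbiased even under strong confounding;
as the rGE grows the deflation tracks the closed form
(−0.25·0.38²/0.9375 = −0.0385 and −0.5·0.38²/0.75 = −0.0963).
`plot_bias_curves(res)` and `plot_r2_inflation(res)` draw the
corresponding figures, and `fit_iv()` demonstrates the instrumental
variable correction (`run_grid(grid_spec("iv"))` recovers β = γ = 0.6
under confounding that biases OLS).

A thin command-line front end (`inst/cli/collider-sim.R`) exposes
`simulate`, `grid`, `bias`, `sensitivity` and `iv-demo` subcommands over
the same functions.

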
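# sockidx

Spatio-temporal index standardization for juvenile sockeye salmon
trawl-survey catches.

Late-summer surface trawl surveys of the eastern Bering Sea shelf catch
juvenile sockeye salmon at stations whose coverage varies from year to
year, with many empty tows and strongly right-skewed positive catches.
Design-based annual means confound real changes in abundance and
distribution with changes in where the boat went.  `sockidx` is for
fisheries and quantitative ecologists who want model-based annual
summaries of such data — how much fish, where, and how concentrated —
together with estimates of how temperature, prey, and competitor
densities shape the underlying density surface.

## The model

Each station-tow record carries two linear predictors built from year
intercepts, a time-invariant spatial Gaussian random field ω, a
year-specific spatio-temporal field ε (both Matérn, ν = 1, on a k-means
knot mesh), and optional covariate terms (linear or 2-df B-spline):

    p1 = α1[t] + ω1(s) + ε1(s,t) + Σ γ1 X      (log number density)
    p2 = α2[t] + ω2(s) + ε2(s,t) + Σ γ2 X      (log catch per group)

The Poisson-link map converts them into an encounter probability and a
positive catch rate,

    r1 = 1 − exp(−a·exp(p1)),    r2 = a·exp(p1)/r1 · exp(p2),

with area swept `a` as effort, so E[catch] = a·exp(p1+p2).  Zero catches
occur with probability 1 − r1; positive catches are gamma distributed
with mean r2 and an estimated CV.  Estimation maximizes the
Laplace-approximated marginal likelihood (via TMB) and declares
convergence only when the maximum absolute gradient is below 1e-3.

From the fitted density surface d(s,t) = r1·r2 on an extrapolation grid
with cell areas a_s, the package derives, per year: the abundance index
I_t = Σ a_s d(s,t); the center of gravity z_t = Σ z_s a_s d(s,t) / I_t
(km from the Equator / km from 180°); and the effective area occupied
A_t = I_t / D_t with D_t the biomass-weighted mean density.  All three
are corrected for retransformation bias by averaging over draws of the
random effects from their Laplace-Gaussian approximation.  Covariate
contributions are summarized as percent deviance explained and as the
percent reduction in spatio-temporal (ε) variance; diet data are
summarized by the stomach content index SCI = 10000 × prey weight /
predator weight; annual series are related by second-order polynomial
regressions.

A synthetic survey generator (`simulate_survey()`) reproduces the
statistical structure the analysis assumes — unbalanced station layouts,
warm/cool temperature stanzas, dome-shaped temperature effects,
zero-inflated skewed catches — so the whole pipeline is testable without
any data download.

## Worked example

```r
library(sockidx)

scenario <- sim_scenario(seed = 1)          # 8 years x 120 stations
survey   <- simulate_survey(scenario)

fit <- fit_delta_model(survey$stations,
                       delta_model_config(n_knots = 25,
                                          grid_spacing_km = 20),
                       mesh = survey$mesh)
fit
#> Poisson-link delta GLMM fit
#>   records: 960  years: 8  knots: 25
#>   sd(omega) = 0.935 / 0.344  sd(eps) = 0.550 / 0.225  range = 118 km
#>   gamma CV = 0.832  logml = -1912.262  max|grad| = 0.00079 (converged)

idx <- bias_correct_indices(fit, n_draws = 300, seed = 2)
round(idx[, c("year", "index", "se_index", "northing_km", "eao_km2")], 1)
#>   year     index se_index northing_km eao_km2
#> 1    1  239691.8  29752.9      6511.6 24135.0
#> 2    2  440888.5  52263.3      6533.0 26685.9
#> 3    3 1972716.1 207102.2      6475.8 18773.8
#> ...
```

The fitted field SDs and range recover the generator's truth (0.7/0.4
spatial, 0.5/0.3 spatio-temporal, 150 km range) within the precision a
single 8-year survey affords.  The index column is in catch units (kg)
summed over the modeled area; `northing_km` is the biomass-weighted mean
distance from the Equator, and `eao_km2` shrinks as the population
concentrates.  Relating an annual index to annual mean temperature:

```r
ann_temp <- tapply(survey$stations$temp20, survey$stations$year, mean)
fit_trend(ann_temp, idx$index)
#> trend_fit (n = 8): y = 1.154e+06 -2.305e+05 (x - 10.48) -1.095e+05 (x - 10.48)^2
#>   p(b1) = 0.351, p(b2) = 0.639, R2 = 0.182
#>   quadratic not significant; linear slope -2.016e+05 (p = 0.358)
```

(with only 8 annual points and this draw of year effects, no significant
trend — as it should be, since this scenario ties no density effect to
temperature).

A YAML-configured end-to-end driver is available as `run_pipeline()`,
and `inst/cli/sockidx.R` exposes `simulate`, `fit`, `indices`, `diet`,
`trends`, and `pipeline` subcommands for shell use.

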
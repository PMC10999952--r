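---
title: "Spatio-temporal index standardization for juvenile salmon surveys: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal index standardization for juvenile salmon surveys: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sockidx)
```

# The problem

Pelagic trawl surveys of juvenile sockeye salmon (and their prey and
competitors) on the eastern Bering Sea shelf produce station-level catch
records with three awkward properties: many tows catch nothing, positive
catches are strongly right-skewed, and station coverage is spatially
unbalanced across years.  Design-based annual means are therefore biased
and noisy.  `sockidx` addresses this with a model-based standardization:
a Poisson-link delta generalized linear mixed model whose spatial and
spatio-temporal Gaussian random fields absorb the unbalanced sampling,
plus derived annual summaries — a biomass index, a center of gravity
(COG), and an effective area occupied (EAO) — that describe how much
fish there were, where they were, and how concentrated they were.

# The observation model

Each record $i$ (year $t_i$, nearest knot $s_i$, effort $a_i$ km$^2$ of
area swept) carries two linear predictors,

$$p_{1i} = \alpha^{(1)}_{t_i} + \omega_1(s_i) + \varepsilon_1(s_i, t_i) + \sum_p \gamma^{(1)}_p X_p(i), \qquad
  p_{2i} = \alpha^{(2)}_{t_i} + \omega_2(s_i) + \varepsilon_2(s_i, t_i) + \sum_p \gamma^{(2)}_p X_p(i),$$

interpreted as log number density and log catch per group.  The
Poisson-link map turns them into an encounter probability and a positive
catch rate,

$$r_{1i} = 1 - \exp(-a_i e^{p_{1i}}), \qquad
  r_{2i} = \frac{a_i e^{p_{1i}}}{r_{1i}} e^{p_{2i}},$$

so that the expected catch obeys the identity
$r_{1i} r_{2i} = a_i e^{p_{1i} + p_{2i}}$ regardless of parameter
values.  A zero catch has probability $1 - r_{1i}$; a positive catch is
gamma distributed with mean $r_{2i}$ and a single estimated coefficient
of variation.  We chose the (mean, CV) gamma parameterization with one
shared CV because the dispersion of positive catches is a property of
the gear and the schooling behaviour rather than of individual years;
nothing in the data structure identifies year-specific CVs at desk
scale.

# Random fields

The fields $\omega_k$ (time-invariant) and $\varepsilon_k$ (drawn
independently each year) live at a set of knots obtained by k-means
clustering of the pooled station locations (10 restarts, best
within-cluster sum of squares, seeded).  All four fields share one
Matern correlation with smoothness $\nu = 1$ — the standard choice for
two-dimensional spatial modelling — parameterized by the distance at
which correlation falls to 0.1 (the "range", in km).  We work with the
dense correlation matrix at knots rather than a sparse
stochastic-partial-differential-equation precision: at the knot counts
this package targets (tens to a few hundred), dense Cholesky factors
are faster and simpler than sparse mesh machinery, and the two agree in
the dense limit.  Stations and grid cells inherit the value of their
nearest knot (piecewise-constant projection), consistent with treating
the knots as the resolution of the analysis.

Two deliberate simplifications, each behind a documented default: the
fields are isotropic (no geometric anisotropy), and $\varepsilon$ has no
temporal autocorrelation.  A single factor per field is used throughout.
All four fields share one range; at desk scale, per-field ranges are
weakly identified and invite boundary estimates.

Estimation maximizes the Laplace-approximated marginal likelihood with
TMB providing exact derivatives; the inner Newton optimization over all
random effects and the outer quasi-Newton optimization (variance
parameters on log scale) follow standard mixed-model practice.
Convergence requires the maximum absolute gradient of the marginal
log-likelihood to fall below $10^{-3}$ (configurable), with up to three
optimizer restarts from the incumbent; a fit that still fails the
criterion is returned with `converged = FALSE` and a warning, never
silently accepted.  Starting values: year intercepts from year-wise log
mean catch per unit effort, variance parameters at $\log 0.5$, covariate
coefficients at zero.

# Covariates

One covariate per fitted model (the covariates of interest — temperature
at 20 m, prey and competitor densities — are themselves correlated, so
separate models avoid collinearity artifacts).  Count-like covariates
are $\log(x + 1)$ transformed; all covariates are z-scored after
transformation for optimizer conditioning, with coefficients also
reported on the raw scale for linear terms.  The nonlinear form is a
degree-2 B-spline with no interior knot and boundary knots at the
observed extremes — two basis columns after the intercept is dropped, so
together with the year intercepts it spans exactly the quadratics on the
observed range.  Boundary knots and scaling constants are stored in the
fit, which makes basis evaluation on new data bit-reproducible;
out-of-range prediction clips to the boundary with a warning rather than
extrapolating a polynomial.  Covariates enter both linear predictors by
default (a flag restricts them to the first).

The contribution of a covariate is summarized two ways:

* **Percent deviance explained**, $100(1 - D_{\rm cov}/D_{\rm base})$
  with $D = -2\log L$ (the saturated-model constant cancels in the
  ratio); and
* **Percent spatio-temporal variance explained**,
  $100\,(1 - (\hat\sigma^2_{\varepsilon_1,{\rm cov}} +
  \hat\sigma^2_{\varepsilon_2,{\rm cov}})/(\hat\sigma^2_{\varepsilon_1,{\rm base}} +
  \hat\sigma^2_{\varepsilon_2,{\rm base}}))$.

The two definitions coexist in the literature under the same name and
need not agree numerically; `deviance_explained()` returns both, and we
treat the $\varepsilon$-variance version as the headline number because
it directly answers "how much of the spatio-temporal structure in
density does this covariate absorb?".

# Derived quantities

With $d(s,t) = r_1 r_2$ evaluated at unit effort on an extrapolation
grid (a regular lattice clipped to a buffer radius around the knots,
each cell carrying its area $a_s$):

$$I_t = \sum_s a_s d(s,t), \qquad
  z_{t,m} = \frac{\sum_s z_{s,m}\, a_s d(s,t)}{I_t}, \qquad
  A_t = I_t / D_t .$$

The "average density" $D_t$ in the EAO is the biomass-weighted mean
$\sum_s a_s d^2(s,t) / I_t$.  This convention makes $A_t$ equal the
total modeled area under uniform density and a single cell's area under
complete concentration, which is the behaviour the quantity's name
promises; an unweighted (arithmetic cell-mean) alternative is available
by flag.  Coordinates are reported as kilometres north of the Equator
and east of the 180th meridian, from an equirectangular projection
(111.195 km per degree of latitude; easting scaled by $\cos$ latitude).
This keeps COG units directly interpretable as kilometres of
displacement; at the ~1000 km scale of the shelf the distortion relative
to a conformal projection is immaterial for the derived summaries.

Because $I_t$, COG, and EAO are nonlinear in the random effects,
plugging in the random-effect modes underestimates them
(retransformation bias: $E[f(u)] \ne f(E[u])$).  `bias_correct_indices()`
corrects this by simulation: the random effects are drawn from the
Gaussian (Laplace) approximation at their mode, $N(\hat u, H^{-1})$ with
$H$ the inner Hessian, the full surface and all three summaries are
recomputed per draw (500 draws by default), and the draw mean and SD are
reported as the corrected value and its standard error.  This targets
the same retransformation-bias-corrected expectation as derivative-based
epsilon estimators while remaining checkable against closed forms (for
a lognormal functional the corrected mean must approach
$e^{\mu + \sigma^2/2}$, which the test suite verifies to 2% at $10^4$
draws).  All three summaries are corrected, not only the index — the
correction machinery is identical and there is no reason to privilege
one functional.

# Diet and trends

The stomach-content index of a pooled station sample is
$\mathrm{SCI} = 10^4 \times$ prey weight / predator weight per taxon.
Annual category summaries average station SCIs without weighting by the
number of stomachs pooled — the station is the sampling unit — and diet
proportions divide each category mean by the sum of category means, so
they close to 1 by construction.  A weighting flag exists for
sensitivity analysis.  Volumetric plankton densities convert to areal
densities by multiplying by (depth − 10 m), the sampled water-column
height.

Relationships among annual series (index, COG, EAO versus annual
covariate means) are described by ordinary least squares on a centered
second-order polynomial, with t-tests at $\alpha = 0.05$, a linear
submodel when the quadratic term is not significant, and the vertex
$\bar x - b_1/(2 b_2)$ reported for significant quadratics.  No
multiple-testing correction is applied, matching standard practice for
these descriptive regressions; the number of tests run is recorded so a
reader can discount accordingly.  Index standard errors are not
propagated into these regressions (a weighted option exists): the
regressions are descriptive of the point series.

# The synthetic-data generator

`simulate_survey()` is first-class, tested code, not a fixture.  It
emulates the features of the survey that the analysis relies on:

* a jittered station lattice with random dropouts, optionally unbalanced
  across years (default 8 years x 120 stations on a 600 x 400 km
  domain);
* warm/cool temperature stanzas (defaults 11.3 and 8.8 °C annual means
  in a warm-cool-warm sequence, SD 0.5 °C across years), a north-south
  gradient (−0.004 °C/km), a smooth knot-level spatio-temporal
  temperature anomaly (SD 0.8 °C) — the component that lets temperature
  genuinely explain spatio-temporal density structure — and station
  noise (SD 0.5 °C);
* truth random fields with SDs 0.7/0.4 (spatial) and 0.5/0.3
  (spatio-temporal) and a 150 km range, year intercepts drawn around a
  log density of 1.8, effort uniform on 0.1–0.2 km$^2$ (a 55 m net
  opening towed 1.8–3.6 km);
* catches drawn from exactly the Poisson-link delta-gamma observation
  model (CV 0.8), so roughly half the tows are empty and positive
  catches are right-skewed;
* optional covariate effects: a linear slope on a standard-normal
  covariate, or a dome — log density falling quadratically away from a
  stated peak (11 °C in the temperature experiments), which the 2-df
  spline is correctly specified for up to basis rotation;
* an optional year-by-northing tilt of log density for
  distribution-shift experiments.

These defaults were chosen once, as a realistic desk-scale caricature
of a late-summer surface trawl survey, and sized so a full fit runs in
seconds on one CPU; the tests and the acceptance script use them as
stated (20 replicate fits at 400 stations x 8 years x 25 knots for
coefficient recovery; single fits elsewhere).  What the generator does
*not* emulate — coastline masking, bathymetric domains, the cold pool,
current-driven anisotropy, species interactions — bounds what passing
tests show: parameter recovery on these simulations demonstrates that
the estimator is consistent with its own assumptions, not that those
assumptions hold for any particular sea.

# Numerical choices and degenerate inputs

* The Matern scale constant solves $x K_1(x) = 0.1$ numerically (no
  closed form); correlation matrices carry a $10^{-8}$ diagonal jitter.
* `poisson_link()` computes in log space; $\log(1 - r_1)$ for zero
  catches is the exactly stable $-a e^{p_1}$.
* Mapped-off fields (variance fixed at zero) are removed from both the
  parameter vector and the likelihood, so the Laplace approximation
  degenerates exactly to the fixed-effect likelihood — a property the
  tests exploit.
* Years without a single encounter are flagged (their first-predictor
  intercept is weakly identified) but do not abort the fit.
* Pearson residuals are undefined where $r_1$ is numerically 0 or 1;
  such records are emitted as missing with a count.
* Covariate gaps are filled within year by a local plane through the
  three nearest non-collinear observed stations (inside the convex
  hull) or nearest-neighbour (outside), with a 1-D linear fallback for
  collinear layouts and a provenance flag per filled value.  At survey
  station spacing this differs negligibly from spline-surface
  interpolation.
* Grid cells are assigned uniquely to their nearest knot; buffer
  regions around knots are not double-counted.  The buffer radius
  should be at least the typical station-to-knot distance, so
  desk-scale meshes with few knots warrant a larger buffer than the
  25 km used with dense knot sets.

# Known limitations

Single-species, single-factor fields; no anisotropy; no temporal
autocorrelation in $\varepsilon$; piecewise-constant (not bilinear)
projection from knots; Wald uncertainty for covariate effects; the
bias correction conditions on the estimated fixed parameters (it
propagates random-effect uncertainty only).  Cross-validation uses a
simple random partition of records, which is optimistic relative to
spatially blocked designs when the goal is transfer to unsampled areas.
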
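---
title: "Methods: spatial ex ante analysis of fertilizer profitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial ex ante analysis of fertilizer profitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `agroprofit`, the assumptions they
rest on, the tunable parameters and their defaults, what the synthetic data
generator does and does not emulate, and the numerical choices made where the
design was genuinely open. It states no empirical result that the package's
tests and `scripts/acceptance.R` do not themselves compute.

## The question the package answers

Fertilizer profitability for a smallholder is a local quantity. The same
nitrogen dose produces different grain responses on different soils and under
different rainfall; the grain is worth the *farm-gate* price (market price
minus the cost of hauling it to the best market), and the nitrogen costs the
market price marked up by delivery costs. `agroprofit` composes these pieces
into per-pixel maps of the economically optimal N rate, the expected net
revenue, and the uncertainty of that revenue across rainfall years, then asks
whether the resulting profitability map predicts observed adoption.

## Market access

Travel speeds are assigned per cell: cells crossed by a road take their road
class speed (defaults: primary 80, secondary 50, tertiary 30 km/h, fastest
class wins on overlap), all other cells take a land cover speed (cropland and
grassland 10, forest 5 km/h, water impassable). No sources state these
off-road values authoritatively; they are configurable in `speed_table()`.

Travel time from each pixel to each market town (population above a
configurable 50,000 threshold) is the exact single-source shortest path over
the raster adjacency graph. Two choices define the graph:

* **8-connectivity** with diagonal steps `sqrt(2)` cells long — the standard
  cost-distance convention (4-connectivity is available).
* **Step cost = step length / harmonic mean of the two cells' speeds.** The
  harmonic mean is the "half the time in each cell" interpretation and makes
  step costs symmetric, so travel time is a metric on the traversable part of
  the grid.

The implementation runs Dijkstra via `igraph`; the test suite checks it cell
by cell against an independently written textbook Dijkstra on random grids,
and checks the metric properties (zero at sources, symmetry, and that adding
a road never increases any travel time).

## Price surfaces

**Market prices.** Observed market prices are modelled with a regression
forest (`ranger`, 500 trees, minimum node size 5, fixed seed) on travel time
to the nearest market, distance to the port (taken as the most populous
town), rural population, maize cropland, mean seasonal rainfall, and the
coordinates. Out-of-bag variance explained and RMSE are stored on the fitted
object.

**Farm-gate maize prices.** Spatial arbitrage over markets:
`p_fg(x) = max_m [p_m - c T(x, m)]` with `c = 0.01` USD/kg/hr. Market prices
`p_m` are read off the predicted price surface at the town cells — the
minimal choice consistent with predicting a price *surface* but arbitrating
over discrete market locations. Pixels where every market nets a nonpositive
price are set to nodata and flagged rather than truncated to zero: downstream
revenue is never computed at a fictitious zero price.

**Farm-gate nitrogen prices.** A logistic delivery-cost multiplier
`m(t) = L / (1 + exp(-k (t - t0)))` scales a base nitrogen price of 0.95
USD/kg N (the urea-derived market price; `urea_to_n_price()` converts urea
prices at 46% N content). Two constraints calibrate the curve: `m(0) = 1`
(no markup at the market) and `m(5) = 3` (delivered price trebles at five
hours). With the upper asymptote fixed at `L = 4` these force `t0 = 2.5` h
and `k = ln(3)/2.5` per hour in closed form. `L = 4` is a design choice: it
is the smallest integer asymptote comfortably above the treble constraint,
and it makes the curve symmetric around a midpoint multiplier of 2. Whether
fertilizer should use its own market-town set is unknown; the package reuses
the maize market travel-time raster (overridable).

## Yield response

A regression forest predicts plot-level maize yield from the applied N and P
rates, ten management dummies, weeding count, plot and household covariates,
and five spatial layers (elevation, slope, SOC, pH, seasonal rainfall).
"Seasonal rainfall" is the December–May total, labelled by the January year,
with December taken from the prior calendar year. Countrywide surfaces hold
every non-spatial predictor at its survey mean. Skill is reported as
out-of-bag variance explained; hyperparameters (500 trees, leaf size 5) are
config defaults, not tuned.

**Monotone projection in the scenario layer.** Per-pixel forest predictions
are not exactly monotone in N even when the underlying response is; the
pixel-level wiggles are estimation noise. Before rate search and scenario
reporting, the per-rate yield surfaces are projected to be non-decreasing in
N (running maximum along the 0–200 kg/ha grid). This is an agronomic shape
constraint — responses over this range do not bend downward — and it
guarantees the dominance and stochastic-ordering properties the scenario and
robustness analyses rely on. `predict_yield_surface()` itself stays
unprojected.

**Scenarios.** ZERO, BK (blanket 55 kg/ha), OPyield and OPnetrev share one N
grid (0–200 kg/ha, step 5), so the optimised scenarios dominate the fixed
ones pixel by pixel, exactly. Ties break toward the lowest rate: forests
give piecewise-constant responses, ties are real, and the cheaper dose is
the conservative recommendation. Net revenue subtracts only the nitrogen
cost, by the framework's convention. Regional summaries weight per-hectare
gains by maize area (not population — gains are per hectare; population is
reported alongside). The 0–200 grid covers reported optima (up to ~175
kg/ha) with headroom; step 5 keeps the search exact and cheap.

**Agronomic efficiency and robustness.** `AE = (Y_N - Y_0)/N`; the
robustness transform `Y_s = Y_0 + s (Y_N - Y_0)` multiplies AE by `s`
exactly, so a mean AE of 7.2 kg/kg maps to 9.0 at `s = 1.25` and 10.8 at
`s = 1.5`. The robustness report tabulates the empirical CDF of BK-over-ZERO
gains per `s` and the share of maize area above 100 USD/ha.

## Rainfall uncertainty

Scenario N rates are frozen at their long-run-mean-rainfall optima and then
exposed to the 40 historical seasons: farmers commit to a dose before the
season. For each season the forest predicts yield at that season's rainfall
total; net revenue follows; per-pixel mean, **population** SD (the ensemble
is the full historical record, not a sample) and CV summarise the
distribution. CV is nodata where the mean is nonpositive, avoiding
sign-flipping ratios. Only rainfall is varied — model residual noise is not
resampled, and price volatility is out of scope.

## Adoption validation

Fertilizer use (0/1) is regressed by OLS — a linear probability model, for
interpretability — on log expected net revenue, its standard deviation (in
levels; its coefficient is naturally of order 1e-3), household covariates,
log travel time, mean rainfall, full region and year indicator sets, and the
Mundlak–Chamberlain device: household time-averages of the time-varying
regressors (cultivated area, head age, members, log assets), which absorb
time-invariant heterogeneity correlated with those covariates. The
time-averages are estimated but not interpreted. On a balanced panel the
device reproduces the within (fixed-effects) slopes exactly; the test suite
verifies this to 1e-8 against a hand-built demeaned estimator.

Inference clusters at the enumeration area with the CR1 factor
`G/(G-1) * (n-1)/(n-k)`; with singleton clusters this collapses exactly to
HC1, and both behaviours are tested against `sandwich`. P-values use a
t(G-1) reference. Households on pixels with nonpositive or missing net
revenue are dropped before taking logs and counted (an additive-shift
alternative exists but is off by default). The "baseline scenario" whose net
revenue enters the regression is BK, a config-level choice.

## The synthetic landscape generator

The generator is the package's ground truth and defines the study
conditions; it is designed for testability, not geographic realism.

* **Fields.** Elevation, SOC, pH and long-run seasonal rainfall are
  Gaussian-filtered white noise rescaled to plausible ranges (0–2500 m,
  5–40 g/kg, 4.5–8, 300–1500 mm) with a ~4 km correlation length — short
  enough that realized field variances are stable across seeds on the
  default 60 km domain. Slope derives from the elevation gradient. Land
  cover (cropland/grassland/forest/water) comes from quantiles of its own
  smooth field. Roads are a spanning tree over the towns (classes by
  endpoint population), which guarantees connectivity; two towns always
  exceed the 50,000 market threshold.
* **Rainfall history.** Each season gets a spatially smooth lognormal
  anomaly factor (CV 0.15 by default; 0 gives identical seasons), split into
  months with fixed wet-season weights (Dec–May summing to the seasonal
  total). There is no climate-model realism — no trends, no teleconnections,
  no intra-seasonal timing.
* **Yield DGP.** `Y = Ymax(soc, elev) * (1 - exp(-k_N (N + N_soil))) *
  rain/(rain + rain_halfsat)` with `Ymax` log-linear in SOC and elevation —
  one closed form giving diminishing returns in N and positive rainfall and
  SOC effects. The defaults (`Ymax_base = 6520` kg/ha, `k_N = 0.004`,
  `N_soil = 203` kg/ha, `rain_halfsat = 400` mm) were solved analytically so
  that at mean covariates the zero-N yield is ~2510 kg/ha and the agronomic
  efficiency at 55 kg/ha is 7.2 kg grain per kg N.
* **Survey.** 455 households, 601 plot observations. Binary covariates are
  drawn as exact counts at their target shares; continuous covariates are
  moment-matched to their target mean/SD; N rates among users are lognormal
  (CV 1.8, capped at 300 kg/ha) scaled to mean 35.2. Yields are *not*
  moment-matched — they come from the DGP plus additive management effects
  and Gaussian noise — so the sample mean yield is a genuine check of the
  calibration. The noise SD (1000 kg/ha) was chosen so the fitted forest's
  out-of-bag variance explained centres near one quarter, the skill level
  typical of observational smallholder yield data; total yield dispersion is
  consequently below the dispersion of real surveys, whose unexplainable
  component no generator with observed covariates can reproduce. Passing
  tests therefore demonstrate correctness of the machinery and estimators
  under a favourable, known world — not performance on real data.
* **Prices.** Observed prices sample a known smooth function of remoteness
  (flat at distance zero, ~25 km length scale), population and location,
  clipped to 0.07–0.94 USD/kg, plus optional noise. The length scale is
  chosen so the function is resolvable at realistic sampling densities.
* **Adoption panel.** ~1,940 households x 3 waves (~5,820 observations) in
  ~194 enumeration-area clusters nested in regions. Adoption probability is
  linear with known coefficients (+0.10 on log net revenue, -0.0007 on its
  SD), small covariate effects, region and year effects, and a household
  effect correlated with the time-average of log assets — so pooled OLS
  *needs* the Mundlak terms. The intercept is solved so the average
  adoption rate hits a target (default 0.22), keeping probabilities inside
  the unit interval with negligible clipping. Reported head age carries
  ±2 years of noise, as in real surveys; without it age would be spanned
  exactly by the year indicators.
* **Seeding.** One root seed; every stage draws from a named substream, so
  stages are individually reproducible and a change in one stage does not
  shift another's draws.

## Numerical choices and degenerate inputs

* Rate search is exhaustive on the shared grid — no derivative-based
  optimisation, so dominance comparisons are exact by construction.
* Nonpositive farm-gate maize prices, unreachable cells and empty masks are
  nodata/errors, never silent zeros.
* The logistic calibration is closed-form; the acceptance script still
  *solves* `m(t) = 3` by bisection to 1e-6 as an independent numerical
  check.
* Forests run single-threaded with fixed seeds; identical calls are
  bitwise reproducible.
* ASCII-grid raster files store full double precision; round-trips are
  exact to within text formatting (~1e-15).

## Problem sizes used in the tests

The suite runs on a 24 x 24 km landscape with 5 seasons for unit tests and
on the default 60 x 60 km landscape with 40 seasons (601 survey
observations, ~5,820 panel rows) for the study-condition checks; the
estimator-recovery study uses 200 replicated panels on one landscape. These
sizes were chosen so the whole chain, including brute-force oracles, runs
comfortably on a single CPU.

## Known limitations

* The generator's world is smooth and low-dimensional; real covariate maps
  have sharp discontinuities, measurement error and missingness the package
  never sees.
* Net revenue ignores seed, labour and application costs; only nitrogen is
  priced.
* No price volatility, no intra-seasonal rainfall timing, no residual-noise
  resampling in the uncertainty module (a config hook exists but is off).
* The linear probability model is used for interpretability; predicted
  probabilities are not constrained to the unit interval and no logit
  alternative is provided.
* One-way roads, congestion and seasonal road quality are out of scope for
  market access.
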
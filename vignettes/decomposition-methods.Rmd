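---
title: "Decomposing global NEE-climate correlations into regional and seasonal contributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing global NEE-climate correlations into regional and seasonal contributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neeiav)
```

## The problem

The land carbon sink varies strongly from year to year, and that variability
(the interannual variability of net ecosystem exchange, NEE~IAV~) is what
makes the atmospheric CO~2~ growth rate fluctuate. Two climate drivers compete
as explanations: terrestrial water storage (TWS, a proxy for the water
available to vegetation) and air temperature (T). At the global, annual scale
the two hypotheses are summarized by two Pearson correlations,
$r_\mathrm{TWS} = \mathrm{corr}(X_G, \mathrm{TWS}_G)$ and
$r_T = \mathrm{corr}(X_G, T_G)$, where $X_G$ is the global annual NEE anomaly
(PgC yr^-1^, positive = net release to the atmosphere) and
$\mathrm{TWS}_G$, $T_G$ are area-weighted global land means. Typically
$r_\mathrm{TWS} < 0$ (wet years take up more carbon) and $r_T > 0$ (warm
years release more).

Those two numbers hide where and when the relationship is generated. This
package implements an exact disaggregation of each global correlation into
per-grid-cell, per-calendar-month contributions, so that questions such as
"how much of the global water dependence comes from the tropical dry season"
or "do spring and summer temperature effects cancel in the north" become sums
over a table.

## The decomposition

The key is to treat NEE as an *extensive* quantity. Writing $x_{i,m}(y)$ for
the detrended NEE anomaly of cell $i$ in calendar month $m$ of year $y$
(PgC month^-1^), the global annual anomaly is exactly
$X_G(y) = \sum_i \sum_{m=1}^{12} x_{i,m}(y)$. Because covariance is linear in
its first argument,

$$ r_T = \frac{\mathrm{cov}(X_G, T_G)}{\sigma_{X_G}\sigma_{T_G}}
   = \sum_i \sum_m \frac{\mathrm{cov}(x_{i,m}, T_G)}{\sigma_{X_G}\sigma_{T_G}}
   = \sum_i \sum_m \underbrace{\mathrm{corr}(x_{i,m}, T_G)\,
       \frac{\sigma_{x_{i,m}}}{\sigma_{X_G}}}_{C^T_{i,m}} $$

and likewise for TWS with an extra minus sign,
$C^\mathrm{TWS}_{i,m} = -\mathrm{corr}(x_{i,m},\mathrm{TWS}_G)\,
\sigma_{x_{i,m}}/\sigma_{X_G}$, chosen so that a positive contribution of
either kind means "removing this cell-month's variability would shrink the
absolute global correlation". The identity
$\sum C^T_{i,m} = r_T$ (and $\sum C^\mathrm{TWS}_{i,m} = -r_\mathrm{TWS}$) is
exact, not approximate; the test suite enforces it at $10^{-10}$ relative
tolerance on random inputs, and `nee_decompose()` reports the residual.
Regional or seasonal contributions are then *plain sums* of $C_{i,m}$ over the
cells of a region and the months of a season, which is what
`aggregate_contributions()` tabulates.

Two bookkeeping rules make the sums close exactly:

* **Winter within the calendar year.** Boreal winter (DJF) is January,
  February and December *of the same year*. A year-straddling winter would
  break the additivity between the four season sums and the annual sum; the
  within-year convention keeps season sums a partition of the 12 months. The
  convention is configurable via the `seasons` argument.
* **Zero-variance cell-months contribute exactly zero.** Ocean cells, and
  land cell-months with no variability, have undefined correlations; they are
  assigned contribution 0 and flagged in a quality layer (`undefined`) rather
  than allowed to poison the global sum. The scalar `pearson_r()` by contrast
  treats zero variance as an error: at the global level an undefined
  correlation is a symptom, not a value.

Sample ($n-1$) standard deviations are used everywhere. The ratio
$\sigma_{x_{i,m}}/\sigma_{X_G}$ is convention-invariant only if numerator and
denominator use the same convention, so this is pinned and tested.

## Anomalies, trends and excluded years

Anomalies are residuals from an ordinary least squares line fit to the
monthly series of each cell (`detrend_whole_series()`). Years strongly
perturbed by volcanic eruptions — by default 1982, 1991 and 1992, after
El Chichón and Pinatubo — are excluded *after* detrending and before any
correlation. Detrending first uses the full record's information and keeps
the anomaly definition independent of the exclusion list; the order is pinned
by a test because doing it the other way round gives measurably different
results. Whether the global means should be area-weighted is equally not
derivable from the correlation definition; we weight by cell area over the
land mask, since the drivers are land variables.

A second, separate detrending mode (`detrend_by_month_group()`) removes a
linear trend from each calendar month's across-year series independently.
It exists because month-dependent trends (e.g. winters warming faster than
summers) leak residual trends into seasonal sums under whole-series
detrending. The sensitivity analysis uses this mode; the correlation
decomposition uses whole-series detrending. They are deliberately separate
code paths sharing tests.

## Seasonal sensitivities and dry/wet seasons

Per-cell seasonal sensitivities come from the multiple regression
$\mathrm{NEE}_{i,s} = a^\mathrm{TWS}_{i,s}\mathrm{TWS}_{i,s} +
a^T_{i,s} T_{i,s} + \varepsilon$, where the seasonal vectors are sums of the
per-month-group detrended monthly anomalies over the months of season $s$,
one value per year. An intercept is included even though anomalies are
near-zero-mean: it costs one degree of freedom and guards against numerical
mean drift without biasing the slopes. Cells whose two predictors are
collinear to machine precision (squared correlation within $10^{-10}$ of 1)
are flagged undefined rather than fitted. Standard errors come from the usual
OLS formulas; the suite checks both against an independent normal-equation
fit and, in Monte-Carlo, that $\pm 3$ SE intervals cover planted coefficients
at better than 95%.

Tropical seasons are defined per cell from the climatological mean seasonal
cycle: a month is *dry* when long-term mean potential evapotranspiration
strictly exceeds long-term mean precipitation (ties are wet, following the
strict "larger than" rule), and cells with 0 or 12 dry months are excluded
from dry/wet analyses. Classification from the climatology, rather than
year-by-year, gives each cell one fixed dry/wet partition, which is what a
per-pixel map of dry-season contributions requires; this was a genuinely open
choice and is recorded here as the package's convention.

## The synthetic-data generator

Real multi-decadal gridded NEE/TWS/T products are large external datasets;
the package instead validates itself end-to-end on synthetic fields with
*planted* structure (`simulate_fieldset()`). The generative model is:

* a small number of latent annual climate modes, stationary AR(1) series,
  expanded to months by linear interpolation between mid-year knots (or held
  constant within the year, `mode_interp = "step"`);
* temperature and TWS anomalies as fixed loadings on those modes plus white
  noise — shared loadings make droughts and heat co-occur, giving the
  TWS-T covariation that motivates the partial-correlation analysis;
* NEE anomalies as planted, region- and calendar-month-dependent linear
  responses $a^\mathrm{TWS}\cdot\mathrm{TWS}' + a^T\cdot T'$ plus noise, plus
  an independent AR(1) NEE-only mode representing globally coherent non-climatic
  variability (fire, radiation), which keeps the global correlations away
  from $\pm 1$ without changing expected contribution shares;
* linear trends, hemispheric seasonal climatologies, volcanic-year uptake
  pulses (so the exclusion logic has something to exclude), and a tropical
  precipitation/PET cycle with a configurable dry-month window.

All randomness flows from one root seed through named per-component
substreams, so any component can be regenerated independently and runs are
bit-reproducible. Default conditions mirror the reference study design:
1979-2016 (38 years), volcanic years 1982/1991/1992, water-dominated tropics
contributing roughly two thirds of both global correlations, a partially
compensating NH spring/summer temperature response, and a 5-month tropical
dry season. Tests use coarser grids (10-30 degrees) and shorter records
(10-25 years) — the statistics under test are grid-size invariant, and these
sizes keep the full suite under a minute.

The planted *expected* regional shares reported in `sim_truth` are computed
from the sensitivity maps and the stationary mode covariances
($c_{TT} = \sum_k L_{T,k}^2 v_k$ etc.), under the generator's default
assumption that mode loadings are spatially uniform. They are population
values; the suite checks recovery within $3/\sqrt{n_\mathrm{years}}$.

What the generator does *not* emulate: spatially correlated noise, regime
shifts, non-linear (saturating or threshold) climate responses, lagged
responses, observational error structure of real inversions or upscaling
products. Passing tests therefore demonstrate correctness of the estimators
under the stated linear-Gaussian conditions, not robustness of the scientific
conclusions to real-data pathologies.

### The compensation scenario

`make_compensation_scenario(strength)` plants $a^T_\mathrm{MAM} =
-\mathrm{strength}\cdot a^T_\mathrm{JJA}$ in NH cells and water-dominated
tropics. It holds latent modes constant within each year (`step` expansion)
and is noiseless by default: with every month of a year seeing the same mode
value, spring and summer contributions are exactly antisymmetric at
`strength = 1` and the annual NH temperature contribution cancels by
construction (up to the small interaction with whole-series detrending).
The linear default expansion is kept for all other configurations, where
smooth within-year variation is the more realistic choice.

## Worked example

```{r}
sim <- simulate_fieldset(sim_config(seed = 1))
fit <- nee_decompose(sim$fieldset)
fit
subset(aggregate_contributions(fit), season == "annual")
```

The summary table gives, per latitudinal band and season, the summed
contributions and their shares of $|r|$. A compensation sweep:

```{r}
sapply(c(0, 0.5, 1), function(s) {
  f <- nee_decompose(simulate_fieldset(
    make_compensation_scenario(s, seed = 2, n_years = 20, grid_deg = 15,
                               land_frac = 1))$fieldset,
    excluded_years = integer(0))
  tab <- aggregate_contributions(f, regions = default_bands(f$geometry)["NH"])
  tab$C_T[tab$season == "annual"]
})
```

The annual NH temperature contribution declines linearly to ~0 as the planted
spring/summer antisymmetry approaches 1.

## Numerical choices and limitations

* Cell areas use spherical geometry with Earth radius 6,371,000 m; only
  relative weights matter for the area-weighted means. The land mask is
  binary; fractional coastal cells are not represented.
* The 25°N/25°S band boundaries assign a cell by its center latitude, with
  strict `>` for the northern band.
* Detrending solves the centered normal equations directly (one matrix
  product per field); residuals of an already-detrended series are returned
  unchanged to ~1e-15, and the suite pins idempotence.
* The contribution field is computed as
  $\mathrm{cov}(x_{i,m}, T_G)/(\sigma_{T_G}\sigma_{X_G})$, which is
  algebraically identical to the corr-times-sigma-ratio form but needs no
  special-casing of zero-variance cells and makes the additivity identity
  hold to machine precision by construction.
* Significance testing of correlations, lagged driver-response analysis, and
  regridding between resolutions are out of scope.
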
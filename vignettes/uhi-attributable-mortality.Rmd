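---
title: "Attributing heatwave mortality to the urban heat island: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing heatwave mortality to the urban heat island: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uhimort)
```

## The question and the counterfactual design

Heatwaves raise mortality, and cities are warmer than their
surroundings — mostly at night. This package estimates how much of a
heatwave's mortality burden is attributable to heat, and how much of
*that* to the urban heat island (UHI), by comparing two gridded
temperature scenarios for the same period: an **urban** run and a
**non-urban counterfactual** in which urban surfaces behave like
vegetated land. UHI intensity (UHII) is therefore defined at every
location as the urban-minus-counterfactual difference, not as an
urban-minus-rural station difference; this avoids the classic problem
of "rural" reference stations being themselves influenced by nearby
urban areas.

The full chain is: gridded fields → regional population-weighted
exposure → threshold log-linear exposure–response → attributable deaths
per scenario → UHI attribution as the paired scenario difference — with
a parallel chain for pollutant burdens and a station-validation module.

## Exposure construction

**Population weighting.** The regional exposure at time *t* is
Σ wᵢ Tᵢ(t) / Σ wᵢ over the cells of a regular grid whose centres fall
inside the region boundary. Cell membership is binary
(centre-in-polygon): at kilometre-scale resolution the partial-cell
correction is negligible and a binary mask keeps every downstream
quantity exactly recomputable. Population is transferred to the model
grid by **conservative area weighting** — counts are extensive, so each
source count is split in proportion to geometric overlap and totals are
conserved to 1e−9 relative whenever the target covers the sources.
Because no suitable geometry library fits this package's footprint, the
two primitives involved (ray-casting point-in-polygon and
Sutherland–Hodgman rectangle clipping) are implemented here and
cross-checked in the tests against an independent implementation.

**Temporal metrics.** Daily aggregation uses a configurable local civil
day (UTC offset, default 0) and keeps a day only if ≥75% of its hours
are present. The heat metric is the **0–2 day lag mean**; the first two
days of a record are excluded rather than filled, so edge effects can
never dilute exposure. The pollutant metric is the **daily maximum
8-hour running mean**: windows are labelled by their ending hour,
a window is valid with ≥6 of its 8 hours, and a day with ≥18 valid
windows — standard air-quality completeness practice, stated here
because the choice is otherwise invisible in results. Whether one
population-weights hourly fields and then averages days, or the
reverse, is immaterial for the mean (the operations commute; asserted
by test), so the hourly-first order is used throughout.

## Exposure–response and attribution

Relative risk is `RR = exp(β max(0, X − T₀))` per age stratum
(defaults 0–64, 65–74, 75+), with threshold T₀ = 18.9 °C by default.
The attributable fraction is the standard `(RR − 1)/RR`, and
attributable deaths are `AF × M` per day and stratum, summed per
coefficient quantile (central, low95, high95). Two report-layer
properties are maintained exactly before any rounding: totals are
additive over days and strata, and the UHI row equals urban minus
non-urban. Rounding to whole deaths happens only when formatting.

**UHI intervals.** The same coefficient quantile is paired across
scenarios before differencing. The coefficient uncertainty is common to
both scenarios, so independent differencing would overstate the UHI
interval; pairing is the only covariance treatment applied.

**Pollutants.** A coefficient quoted as *p*% per 10 µg m⁻³ is read
log-linearly, `RR = (1 + p/100)^(C/10)`, with a linear option
(`1 + p/100 · C/10`) behind a flag — at urban concentrations the two
differ by well under 0.1%, but the log-linear form composes correctly
across concentration increments. Pollution is assumed to affect all
ages equally, so all-ages daily deaths are used and intervals come from
the coefficient interval only.

**Fitting.** `fit_erf()` is the ecological time-series design:
per-stratum Poisson regression of daily deaths on
`max(0, X_d − T₀)` with intercept, threshold held fixed, Wald 95%
intervals. It exists for parameter recovery against the generator's
planted coefficients, not to re-derive published coefficients.

## The synthetic generator

The generator emulates the statistical structure of a mid-July,
16-day, city-scale heatwave so that every stage is testable with known
ground truth:

* **Non-urban field**: spatially uniform base climate — daily mean
  21 °C, a diurnal cycle of ±5.5 °C with minimum at 05:00 and maximum
  at 15:00 (a piecewise-phase cosine: a single sinusoid cannot place
  extrema 10 h apart), a Gaussian heatwave pulse of +10 °C peaking on
  day 10 with 2.5-day width, and an AR(1) day-to-day synoptic anomaly
  (SD 1.2 °C, ρ = 0.6) that gives regressions day-to-day contrast.
* **Urban field**: non-urban plus a UHII surface — Gaussian radial
  decay from the grid centre (length scale 8 cells) whose amplitude
  interpolates between a nighttime peak of +7 °C and a daytime value of
  −0.5 °C (night defined as 20:00–08:00, with 2-hour ramps), plus
  independent cell-hour noise (SD 0.4 °C). The negative daytime value
  lets the counterfactual run warmer by day, as urban canopies can.
* **Population**: 8.8 million with a Gaussian radial profile
  (length scale 5 cells), so population weighting genuinely differs
  from the plain spatial mean; uniform and point-mass profiles exist
  for tests.
* **Mortality**: Poisson daily counts per stratum with baselines
  31/24/93 deaths/day and planted coefficients 0.025/0.030/0.040 per °C
  above 18.9 °C. Literature per-stratum heat coefficients for this
  design are not publicly tabulated, so the planted values are
  configuration — chosen to rise with age, as every temperature–
  mortality study finds — and the pipeline's default ERF takes the
  planted values as central estimates with ±15% standing in for
  literature-derived coefficient uncertainty.
* **Pollutants**: hourly concentration = intercept + slope × regional
  temperature + noise, floored at zero (ozone 20 + 2.2/°C, PM2.5
  4 + 0.45/°C), giving the positive hot-day correlation seen in
  monitoring data.
* **Stations**: officials (6) sample grid-edge cells — where the UHII
  surface is near zero, i.e. a non-urban-like environment — with
  0.5 °C noise; personal weather stations (24) sample central cells
  with 2 °C noise plus a fixed per-station bias (SD 1 °C). All
  stations observe the urban run (the "real" atmosphere); every
  injected perturbation is stored, so validation statistics can be
  checked against exact bookkeeping.

One global seed fans out to named substreams
(`substream_seed()`), so adding a generator never shifts existing
draws, and each component can be regenerated independently.

**Ground truth.** Alongside the sampled counts the generator returns
the analytic expectation Σ baseline × (RR − 1) and the exact sampling
variance Σ AF² λ of the attributable total. The end-to-end check asks
that the pipeline's urban total falls within ±3 of these standard
deviations of the expectation, seed by seed.

**What the generator does not emulate.** No physics: no energy
balance, advection, humidity, land-cover classes or spatial
autocorrelation in the noise; the non-urban field is spatially uniform,
and intra-urban temperature variance is narrower than real PWS
networks observe. Passing tests therefore certify the *statistical
machinery* — exposure arithmetic, attribution algebra, interval
propagation, metric identities — not the realism of any particular
city's fields. Conclusions about a real city require real model output
and observations.

## Numerical and degenerate-input choices

* Days below 75% completeness, windows below 6/8 hours, days below 18
  valid windows, and stations below 24 paired hours are dropped with a
  reported reason, never silently imputed.
* A constant observation series leaves Pearson R undefined; it is
  returned as a flagged `NA`, never 0.
* Station-to-cell matching is nearest centre by great-circle distance
  with deterministic (y, x) tie-breaking; no interpolation, so the
  matched series is exactly a stored cell series.
* Gap-containing daily series are rejected by the lag operator
  (series shorter than 3 days are an error).
* Attribution refuses missing exposure or mortality days inside the
  analysis period rather than imputing.
* All internal temperatures are °C; the gridded text format stores K
  by default (CF-style) and declares units in its header, and reading
  a file without a units attribute is an error.

## Problem sizes

The default study is 16 days × 20×20 cells, which makes a full
pipeline run take well under a second; the test suite's recovery study
uses 90 days × 8×8 cells with 150 baseline deaths/day/stratum and
β = 0.03 °C⁻¹ (20 seeds for relative error, 100 for Wald coverage),
and the Monte-Carlo envelope check uses 20 full pipeline runs. These
sizes give stable statistics while keeping the whole suite in the
tens of seconds.

## Known limitations

No distributed-lag non-linear models or spline ERFs; no acclimatisation
or harvesting adjustment; no humidity or apparent-temperature metrics;
no bias adjustment of fields; sex is not modelled. The UHI interval
pairing captures coefficient covariance only. These mirror the
boundaries of the attribution design itself: what the package adds is a
fully testable, ground-truthed implementation of that design.
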
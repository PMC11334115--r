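# uhimort

Counterfactual health impact assessment of urban heat: how many deaths
during a heatwave are attributable to heat, and how many of those to the
urban heat island (UHI)?

The package is aimed at environmental epidemiologists and urban-climate
researchers who have (or can simulate) two gridded temperature scenarios
for the same period — an *urban* run and a *non-urban* counterfactual in
which urban land surfaces are replaced by vegetated cover — together
with gridded population, daily age-stratified mortality counts, and
monitored pollutant concentrations. Everything needed to exercise the
pipeline without external data is produced by a built-in synthetic
generator with known ground truth.

## Model

Exposure is the regional population-weighted temperature restricted to
a boundary polygon,

&nbsp;&nbsp;X(t) = Σᵢ wᵢ Tᵢ(t) / Σᵢ wᵢ,

aggregated to daily means and then to the 0–2 day lag mean
X_d = (X_d + X_{d−1} + X_{d−2})/3 that drives the heat
exposure–response function (ERF). Risk is threshold log-linear: for age
stratum *a*,

&nbsp;&nbsp;RR_{d,a} = exp(β_a · max(0, X_d − T₀)),&nbsp;&nbsp;T₀ = 18.9 °C by default,

with the attributable fraction AF = (RR − 1)/RR and attributable deaths
AD_{d,a} = AF_{d,a} · M_{d,a} summed over days and strata. Each
scenario is attributed with the same ERF; **UHI-attributable mortality
is the paired difference** AD_urban − AD_non-urban per day, stratum and
coefficient quantile, so the 95% interval reflects the shared
coefficient uncertainty. Pollutant burdens use the daily maximum 8-hour
running mean C_d with RR_d = (1 + p/100)^(C_d/10) for a coefficient of
p% per 10 µg m⁻³ (defaults: ozone 0.34% [0.12–0.56], PM2.5 1.04%
[0.52–1.56]), applied to all-ages mortality. A Poisson regression
(`fit_erf()`) recovers β from daily counts for parameter-recovery
studies, and station-versus-model validation statistics (mean bias,
MAE, RMSE, temporal and spatial Pearson R per network) mirror the
standard evaluation against official and personal weather station
(PWS) networks.

## Worked example

```r
library(uhimort)
res <- run_pipeline(pipeline_config(synthetic_config(seed = 1)))
```

The default configuration simulates a 16-day July heatwave on a 20×20
grid with a night-dominant UHI and a planted heat effect. Stage scripts
under `analysis/` narrate each step; `analysis/03_attribute.R` prints:

```
Analysis period: 2022-07-12 to 2022-07-25
Heat-attributable deaths, urban scenario:     873 (95% CI 763-976)
Heat-attributable deaths, non-urban scenario: 680 (95% CI 592-764)
UHI-attributable deaths (paired difference):  192 (95% CI 171-211)
Ozone-attributable deaths: 89 (95% CI 32-145)
PM2.5-attributable deaths: 56 (95% CI 28-83)
Generator ground truth (analytic expectation): 890.7 urban heat deaths
```

Reading: of the 2933 recorded deaths in the 14-day analysis period, 873
are attributed to heat in the urban scenario versus 680 under the
non-urban counterfactual, so 192 deaths (22% of heat deaths) are
attributed to the UHI. The urban total sits about one Monte-Carlo
standard deviation from the generator's analytic expectation (890.7),
which is exactly the check the acceptance suite performs across seeds.
Pollutant burdens are far smaller than the heat burden. Validation
(`analysis/04_validate.R`) gives official-station MAE of 1.69 °C
against the non-urban run and PWS RMSE of 2.16 °C against the urban
run, with temporal correlations of 0.96 and 0.91 — the noisier PWS
network shows larger errors by construction.

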
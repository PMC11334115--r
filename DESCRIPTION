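Package: uhimort
Title: Urban Heat Island Attributable Mortality Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Counterfactual health impact assessment of urban heat:
    population-weighted exposure series from gridded two-scenario
    (urban and non-urban) temperature fields, threshold log-linear
    exposure-response attribution of daily mortality by age group,
    urban-heat-island attributable deaths as the paired scenario
    difference, air-pollutant attribution from the daily maximum 8-hour
    running mean, model-versus-station validation statistics, and a
    synthetic-data generator with known ground truth for end-to-end
    testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    zoo,
    geosphere,
    jsonlite
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
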
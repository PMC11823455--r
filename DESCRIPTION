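Package: nh3ineq
Title: Satellite Ammonia Column Oversampling and Exposure-Inequality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying demographic inequalities in exposure to
    atmospheric ammonia from satellite trace-gas retrievals. Implements
    uncertainty-weighted oversampling of elliptical Level-2 footprints onto a
    fine regular grid with a generalized-Gaussian (Gaussian or super-Gaussian)
    spatial response, percentile-background column enhancements with an
    empirical decile-selection procedure, area-weighted aggregation of
    enhancements to census block-group polygons, population-weighted
    inequality metrics with standard-mean-error uncertainties,
    meteorological (wind/temperature median-split) stratification, and
    source-distance decay profiles with a signal-to-noise spatial extent.
    A synthetic-scene generator produces fully self-contained test scenes
    (clustered point sources with exponential decay, demographic proximity
    bias, elliptical overlapping footprints, heteroscedastic retrieval noise)
    so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    geosphere
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
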
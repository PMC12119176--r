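Package: kelpniche
Title: Realized Environmental Niche Envelopes and Suitability Mapping for Kelp
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns species occurrence records, gridded environmental layers and
    marine ecoregion polygons into per-species, per-ecoregion realized-niche
    envelope tables (minimum, 25th percentile, mean, 75th percentile, maximum),
    and maps habitat suitability by reclassifying environmental layers against
    those envelopes, summing them with optional weights, and ranking areas with
    zonal statistics. Includes a seeded synthetic-data generator (gridded
    fields, strip ecoregions, Gaussian-niche occurrences) so the whole pipeline
    is testable without downloads, and a command-line driver for running the
    stages on files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
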
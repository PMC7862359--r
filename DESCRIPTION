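Package: herdtyper
Title: Herd-Type Classification for Cattle Registers with Self-Organising Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies cattle herds into management types from a national
    animal identification and movement register. Derives nine herd-level
    demographic and transport variables from animal and movement tables,
    trains self-organising maps (plain and supervised bi-directional Kohonen
    maps) for visual rule extraction via component planes and region
    histograms, and assigns each herd to one of 17 herd types with a
    13-decision classification tree, including threshold-sensitivity bands.
    Ships a synthetic register generator emulating the management signatures
    of all 17 herd types, so the full pipeline is testable without access to
    confidential register data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
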
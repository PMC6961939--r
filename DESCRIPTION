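Package: windconflict
Title: Mapping Conflicts Between Wind Energy Development and Wildlife Conservation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for screening onshore wind-energy development against bird and
    bat conservation at the municipal scale. Estimates wind resources from measured
    speed series (log-law height extrapolation, Weibull maximum-likelihood fitting,
    mean power density), scores municipalities with a five-criterion weighted
    multi-criteria index and classifies them into development-priority classes,
    builds a 1-km wildlife sensitivity raster from species observations using a
    packaged species score catalog (conservation status, effect sensitivity,
    abundance rules, species-specific buffer zones, protected-area and dump-site
    rules), combines priority and sensitivity through a conflict matrix, and
    summarises conflict shares per administrative unit. Includes a seeded synthetic
    landscape generator so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), fitdistrplus, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
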
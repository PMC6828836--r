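Package: peathaze
Title: Village-Level Health Impact Assessment of Peatland-Fire Smoke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible assessment of the long-term human
    health burden of fine particulate matter (PM2.5) from tropical peatland
    fires. Satellite fire-hotspot records are confidence-filtered, classified
    by peat depth, and sampled per class; a Gaussian-puff dispersion surrogate
    with first-order dry-deposition and wet-scavenging losses turns each
    hotspot into a 24-hour mean PM2.5 plume on a 1-km grid; class-mean plumes
    are scaled up by annual hotspot counts, placed by hotspot spatial density,
    and calibrated to a single ground monitoring station. Village-level annual
    exposures feed log-linear and linear-exponential concentration-response
    functions to produce relative risks, attributable fractions, attributable
    mortality by disease category and age group, rates per 100,000, and a
    sensitivity analysis. A synthetic-data generator emulates the hotspot,
    peat-map, meteorology, village and station inputs so the whole chain is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
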
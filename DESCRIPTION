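Package: bpfrac
Title: Hydrogen Isotope Fractionation Between Archaeal Biphytane Lipids
    and Growth Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Data reduction and statistics for compound-specific hydrogen
    isotope (delta-2H) measurements of biphytanes, the C40 isoprenoid
    hydrocarbons released from archaeal tetraether (iGDGT) membrane
    lipids.  Calibrates raw GC-pyrolysis-IRMS peak measurements to the
    VSMOW scale with co-run n-alkane standards (offset, scale
    compression, and peak-size effects), applies the hydrogenation
    isotope-dilution correction, computes lipid/water fractionation
    (epsilon notation) with inverse-variance weighted means and full
    error propagation, derives biphytane and iGDGT ring indices and
    per-ring fractionation differences, and provides study-level
    statistics (condition regressions, correlation matrices, Bartlett
    variance tests, two-endmember water/substrate H mass balance).  A
    seeded synthetic-data generator emulates standards ladders,
    instrument artifacts, and multi-treatment culture designs so the
    whole pipeline is testable without instrument output, and a
    compiled set of published culture-study tables for Sulfolobus
    acidocaldarius is included as example data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
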
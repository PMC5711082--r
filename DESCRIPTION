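Package: ctdose
Title: CT Patient Dosimetry with Slab-Phantom Dose Coefficients and
    Reference-Phantom Conversion Factors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes CT patient organ doses and effective dose from
    measured CT dose index (CTDI) data and a scan protocol. Implements
    the CTDI100 integral with the wide-beam min(NT, 100) clamp, weighted
    CTDI and dose-length product, scanner characterization by head/body
    ImPACT factors with matching against a reference scanner library,
    organ-dose accumulation over a 208-slab stylized adult phantom from
    per-slab dose coefficients for helical, contiguous-axial and
    wide-cone volume scan modes, conversion of stylized-phantom organ
    doses to reference adult male/female phantom doses via per-organ
    examination-category conversion factors, and aggregation to
    equivalent and effective dose under ICRP Publication 103 tissue
    weighting (per sex and sex-averaged). Includes seeded synthetic
    generators for every input format, with independently computed
    oracle manifests, so the full pipeline is testable without
    proprietary Monte Carlo datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
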
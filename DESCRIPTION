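Package: srmforge
Title: Develop Scheduled SRM Assays from DIA Chromatogram Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning replicate transition-level quantification
    reports from data-independent acquisition (DIA) experiments into
    instrument-ready selected reaction monitoring (SRM) methods. The
    workflow flags co-elution interference from transition apex retention
    times, scores peptide stability as the percent coefficient of
    variation of summed transition areas across replicates, selects proxy
    peptides and transitions per protein by ranked intensity and
    stability criteria, calibrates indexed retention time (iRT) against
    spiked standards, and partitions scheduled targets into
    triple-quadrupole methods under a concurrent-transition capacity.
    Includes a seeded synthetic-data generator with planted ground truth
    so every stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
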
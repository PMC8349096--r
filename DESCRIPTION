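Package: MareyHCB
Title: Heterochromatin Boundaries and Local Recombination Rates from Marey Maps
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies euchromatin-heterochromatin boundaries (centromeric
    and telomeric) and estimates local recombination rates along chromosomes
    from Marey maps, i.e. paired genetic (cM) and physical (Mb) marker
    positions. Provides data quality control (marker density and
    distribution-homogeneity tests) and outlier cleaning, cubic-polynomial
    and Loess regression of the Marey curve with derivative-based
    recombination rates, cumulative forward/backward goodness-of-fit curves,
    sliding-window detection of centromeric boundaries (with and without a
    centromeric assembly gap), telomeric boundary detection from
    goodness-of-fit depletion, chromosome-type classification (telocentric,
    metacentric, not metacentric), and zeroing of recombination rates across
    heterochromatin. A simulation module generates synthetic Marey maps with
    known boundaries for validation and robustness experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ggplot2,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
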
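Package: halonet
Title: Halogenated Metabolite Dereplication and Substitution-Series
    Detection for LC-MS/MS Metabolomics
Version: 0.1.0
Authors@R:
    person("ICSN", "Metabolomics", email = "devnull@example.org",
           role = c("aut", "cre"))
Description: Tools for dereplicating halogenated fungal natural products
    (azaphilones, ilicicolins) from LC-ESI(+)-MS/MS data: molecular formula
    parsing and exact-mass arithmetic with ppm errors, isotopologue pattern
    simulation by convolution, chlorine/bromine inference from MS1 isotope
    envelopes, modified-cosine molecular networking with GNPS-style spectral
    preprocessing, detection of OSMAC halogen substitution series (H/Cl/Br/I
    analogs linked by fixed mass shifts, isotopic evidence and retention-time
    ordering), annotation against a packaged reference-compound library, and
    a seeded synthetic data generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
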
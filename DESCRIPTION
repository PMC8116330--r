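Package: parthenotrace
Title: Microsatellite Parentage and Facultative Parthenogenesis Inference
Version: 1.0.0
Authors@R:
    person("Parthenotrace", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting facultative parthenogenesis in captive
    elasmobranch breeding programmes from multilocus microsatellite data.
    Classifies offspring against putative dams and sires (sexual,
    parthenogenetic, consistent-but-unconfirmed, or mismatched), reconstructs
    maternal genotypes from parthenote offspring and computes the minimum
    number of dams compatible with a set of parthenotes by exact set-partition
    search, and summarises oviposition event logs into per-female and cohort
    reproductive metrics (fertility, hatchability, fertility duration,
    parthenogenesis incidence). A seeded synthetic-data generator produces
    Hardy-Weinberg populations, Mendelian and terminal-fusion automictic
    offspring, genotyping noise, and egg-laying event logs so that every
    pipeline stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
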
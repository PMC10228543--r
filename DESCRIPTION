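Package: tailspin
Title: Residue-Resolved NMR Spin-Relaxation Analysis of the Nucleosomal H3 Tail
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates per-residue 15N relaxation observables (R1, R2,
    heteronuclear NOE, R2/R1) with propagated errors from peak-intensity
    tables, computes amide chemical shift perturbations between histone H3
    constructs, builds wild-type-versus-mutant difference profiles, ranks
    arginine-neutralizing mutants by summed differences, detects affected
    tail regions with a consecutive-run error-bar rule, and tests
    additivity of single-mutant effects. Ships a synthetic-data generator
    built on an arginine "anchor point" site-binding model of H3 tail
    dynamics within the nucleosome core particle, so the full pipeline is
    testable without experimental downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
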
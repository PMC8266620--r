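Package: lithoseq
Title: Error-Rate Profiling for Light-Directed DNA Microarray Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for characterising chemical and photochemical error rates in
    maskless array synthesis (MAS) of DNA oligonucleotide libraries. Designs
    k-mer-covering oligo panels, places features on a digital micromirror
    device (DMD) grid and generates per-cycle photomasks under the fixed
    A-C-G-T coupling order, simulates synthesis per molecule (first-order
    photodeprotection kinetics, base-specific coupling efficiencies, stray
    light, optional capping), and profiles deletion, insertion and
    substitution errors from aligned reads: per-bp rates, substitution and
    match matrices, deletion run lengths, per-cycle and per-position profiles,
    insertion wait-number histograms, stepwise coupling-efficiency estimation,
    and spatial error maps over array coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    stats,
    graphics,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
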
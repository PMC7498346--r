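Package: srnapaint
Title: Probe Design and Quantitative Analysis for Small RNA DNA-PAINT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design of locked-nucleic-acid (LNA) hybridization probes for
    DNA-PAINT imaging of 21-24 nt small RNAs, and quantitative analysis of
    the resulting single-molecule localization data. Includes an in-package
    nearest-neighbor thermodynamics engine (duplex melting temperature with
    salt correction, LNA-adjusted Tm, self-dimer and hairpin screening), an
    exhaustive LNA-placement probe designer with docking-strand assembly,
    qPAINT binding-site quantification from dark-time kinetics (photon
    filtering, fiducial drift correction, circular region picks, event
    linking, background subtraction), DBSCAN clustering with per-point
    degree-of-colocalization scoring for two-channel data, and a
    blink-kinetics simulator that generates localization tables with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, yaml, stats, utils, Biostrings
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
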
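Package: deltacall
Title: Detection of rRNA Modifications from Nanopore Direct RNA Sequencing
    Basecalling Errors
Version: 0.1.0
Authors@R:
    person("deltacall", "developers", email = "deltacall@example.org",
           role = c("aut", "cre"))
Description: Maps ribosomal RNA modifications from Oxford Nanopore direct RNA
    sequencing (DRS) by comparing per-position basecalling error between a
    native sample and an unmodified in vitro transcript (IVT) of the same
    rRNA.  The per-position difference of the highest non-reference base-call
    percentage (delta call error) is thresholded against the background
    miscall level to nominate candidate modified residues; candidate
    pseudouridines are recognised by their characteristic U-to-C miscall
    signature, and sub-threshold positions flanking supported sites are
    flagged as neighbour effects.  Nanopore candidates are integrated with
    cryo-EM and mass-spectrometry evidence tables into consensus modification
    calls with type assignment by E. coli homology.  Includes a synthetic DRS
    read and pileup generator with planted modification truth sets for
    end-to-end validation, a pileup engine with read-level filters, and a
    command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    jsonlite,
    ggplot2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
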
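Package: kirhla
Title: Population Immunogenetics of KIR and HLA Class I Co-Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-resolution population analysis of killer-cell
    immunoglobulin-like receptor (KIR) and HLA class I variation: pedigree-based
    haplotype deduction with an EM phaser for unrelated individuals, epitope
    assignment and functional receptor-ligand pair counting, frequency-spectrum
    selection statistics (Tajima's D with coalescent-simulation significance,
    Ewens-Watterson homozygosity with the Slatkin exact test and its normalized
    deviate) restricted to receptor-binding motifs, haplotype-structure
    diagnostics (Hamming networks, mismatch distributions, sliding-window MAF),
    and an iterative Mantel-test scan for co-evolving receptor and ligand
    residue groups. Includes a synthetic-cohort generator with Mendelian
    mother-child transmission and plantable receptor-ligand coupling for
    end-to-end validation against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    graphics,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    vegan,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
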
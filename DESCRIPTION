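Package: uniparental
Title: Uniparental Lineage Analysis for Founder Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying sex-biased admixture in founder isolates from
    uniparentally inherited markers. Classifies mitochondrial and Y-chromosome
    variant profiles against annotated haplogroup reference phylogenies
    (Phylotree-style mtDNA trees and minimal skeleton Y trees), performs an
    in-silico PCR fragment-length screen for the Polynesian-motif 9-bp
    COII/tRNA-Lys deletion, propagates matrilineal and patrilineal founder
    lineages through pedigrees, and estimates maternal and paternal ancestry
    fractions with bootstrap confidence intervals. Includes a forward-time
    founder-pedigree simulator emulating the Pitcairn/Norfolk Island founding
    event so that every pipeline stage can be exercised end to end without
    external data, plus distance-based phylogeny reconstruction of sample
    variant profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
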
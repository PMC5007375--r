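Package: convrates
Title: Lineage-Paired Rates of Molecular Evolution in Convergent Mutualists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparing rates of molecular evolution
    between independently evolved lineage pairs in a multi-species whole-genome
    alignment. Implements Nei-Gojobori (1986) counting estimates of dN/dS with
    pathway averaging and Jukes-Cantor correction, sliding-window genetic
    distances with window validity rules, neighbor-joining window trees and a
    topology census, scanning for convergent amino-acid substitutions among a
    foreground lineage set, codon usage statistics (effective number of codons,
    GC3), paired foreground/background testing with consistency classification
    and FDR control, depth-based copy-number screens, nuclear-mitochondrial
    insertion counting, transposable-element candidate filtering, and
    mapping-population marker QC with a simple linkage grouping. A
    synthetic-data module simulates codon and nucleotide evolution along a
    fixed species tree with branch-specific rate multipliers, planted
    convergent sites, read-depth tracks with copy-number gains, a
    single-family mapping population, and a multi-tissue expression matrix,
    each with truth tables so that every stage is verifiable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
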
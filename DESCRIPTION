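Package: orf15asm
Title: De Novo Assembly-Based Variant Calling for Low-Complexity Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Secondary analysis of deep targeted sequencing of a single
    long-range PCR amplicon over a low-complexity, purine-rich locus
    (the RPGR ORF15 model system). Reads are assembled de novo with a
    multi-k de Bruijn graph assembler supporting trusted and untrusted
    seed contigs, a satisfactory contig is chosen by a three-round
    G-content / size / coverage selection cascade, and variants (SNVs and
    indels, including large in-repeat duplications) are called from a
    global affine-gap contig-to-reference alignment with 3'-shifted HGVS
    c. nomenclature and left-aligned VCF output. A naive mapping/pileup
    baseline caller, a cross-pipeline concordance comparator with
    high/low call-quality classes, and a paired-end amplicon read
    simulator with truth variant sets make the whole pipeline testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
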
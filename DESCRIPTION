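Package: igasm
Title: Targeted De Bruijn Graph Assembly of B-Cell Receptor Repertoires
    from Short-Read RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs expressed immunoglobulin heavy- and light-chain
    (IGH/IGK/IGL) sequences from standard short-read mRNA-seq alignments.
    Candidate B-cell receptor reads are extracted from a SAM/BAM file by
    locus, germline k-mer homology and mapping status, assembled on a
    base-quality-aware de Bruijn graph, and traversed from germline-V
    homologous source vertices with an edge-ratio path score. Candidate
    contigs are confirmed by germline V/J anchor matching, conserved
    Cys...Trp/Phe CDR3 detection in reading frame, and perfect-match
    paired-read coverage. Downstream utilities assign isotypes and V/J
    genes, quantify clone abundance with an expectation-maximization
    fragment model, cluster clonotypes, and summarise repertoire diversity
    (richness, Pielou evenness). A seed-deterministic repertoire simulator
    (V(D)J recombination, junctional diversity, somatic hypermutation,
    paired short reads with errors) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    Rsamtools,
    igraph,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
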
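Package: teshot
Title: Transposable-Element Profiling from Low-Coverage Shotgun Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates transposable-element (TE) composition of plant genomes
    from low-coverage whole-genome shotgun reads. Reads are quality-trimmed,
    mapped to TE reference contigs with a built-in seed-and-extend aligner,
    and per-family coverage is normalized by the mean coverage of
    ultra-conserved orthologous sequences (UCOS) to give relative copy
    numbers, superfamily abundances and genome fractions. Further stages call
    variable sites on TE contigs, partition LTR-retrotransposon variability
    across element features, fingerprint accessions by PCA of superfamily
    abundances with subsample replication, build UCOS-based species trees via
    average ranks of coalescences (STAR) with multilocus bootstrap support,
    and cluster reads de novo into repeat families with a k-mer overlap graph
    and Louvain community detection. A synthetic genome and read simulator
    with full ground truth supports calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    igraph,
    stats,
    utils,
    tools,
    yaml,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
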
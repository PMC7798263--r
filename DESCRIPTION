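Package: synmotif
Title: Discovery of Ordered Conserved Short Motifs in Homologous Noncoding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers combinations of short motifs (k-mers) conserved in the
    same linear order across an ordered set of putatively homologous nucleotide
    sequences, such as lncRNA orthologs or 3'UTRs from multiple species. Each
    sequence becomes a layer of k-mer nodes in a layered graph; identical k-mers
    in consecutive layers are joined by edges, and a maximal set of
    non-intersecting paths anchored in the query sequence is selected with an
    exact branch-and-bound solver for the underlying integer linear program.
    Includes empirical significance testing under multiple-sequence-alignment
    column-shuffle and dinucleotide-preserving nulls, microRNA seed-site typing,
    transcript-to-genome coordinate lifting against interval annotations, motif
    module and neighborhood summaries, and a synthetic benchmark generator with
    known planted ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    optparse,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
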
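Package: urscan
Title: Detection and Annotation of Unique Genomic Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies unique (repeat-free) regions in genomes with the
    match-complexity statistic, a sliding-window measure based on maximal
    exact matches computed from a suffix array over both strands. Windows
    whose complexity is indistinguishable from random sequence are merged
    into unique regions, annotated against gene models (strand-aware
    promoters and transcripts), and their gene content is tested for Gene
    Ontology term enrichment with an interval-shuffling Monte Carlo test
    and Bonferroni correction. Includes a point-mutation simulator for
    characterizing the detection of diverged repeat copies, and a synthetic
    fixture generator (genome, GFF3, GO ontology, protein-to-GO mapping)
    so the whole pipeline can be exercised without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
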
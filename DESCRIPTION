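Package: trnacycle
Title: tRNA Repertoire, Decoding Potential and Expression Across the
    Dictyostelium Social Cycle
Version: 0.1.0
Authors@R:
    person("Repertoire", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing transfer-RNA gene repertoires and their
    regulation across the starvation-induced social cycle of Dictyostelium
    discoideum. Builds the decoding potential graph that reconciles a
    restricted anticodon repertoire with genomic codon usage through wobble
    pairings (G:U, U:G and inosine-mediated I:C/I:A), clusters tRNA genes
    into isodecoders and tests chromosomal isotype localization with a
    Monte-Carlo multivariate hypergeometric test, classifies genes as
    transcriptionally available by full embedding in nucleosome-free-region
    peaks, validates and counts mature-tRNA sequencing reads selected by
    their 3' CCA tail, and runs a lightweight negative-binomial
    differential-expression stage at isodecoder, isoacceptor and isotype
    levels. A synthetic-data module generates every input with planted
    ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    igraph,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
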
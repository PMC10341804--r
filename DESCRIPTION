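Package: allostate
Title: Chromatin-State Segmentation and Subgenome Bias Analysis for
    Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide chromatin-state analysis in allopolyploid
    plant genomes from binned histone-modification and chromatin-accessibility
    tracks. Implements Poisson binarization of multi-mark signal, a
    multivariate hidden Markov model with independent Bernoulli emissions
    (Baum-Welch learning, Viterbi and posterior decoding), broad-peak calling
    with replicate consensus, chromatin-state enrichment over genomic elements
    and transposable-element classes, promoter-based gene-state assignment
    with cross-condition transition analysis, a negative-binomial
    differential-expression test, reciprocal-best-hit homoeolog pairing with
    subgenome expression-bias categorisation, and a fully seeded synthetic
    data generator that plants known chromatin and expression structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
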
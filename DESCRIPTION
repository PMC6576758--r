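Package: mpracnn
Title: Convolutional Modelling and Interpretation of Massively Parallel
    Reporter Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits multi-task convolutional regression models that map 145 bp
    DNA fragments to their regulatory activity as measured by massively
    parallel reporter assays (MPRAs), following the Sharpr-MPRA tiling
    design (295 bp regions tiled at 5 bp steps, four cell-type x promoter
    tasks).  Provides nucleotide-resolution feature attribution via a
    backpropagation contribution rule against dinucleotide-shuffled
    references and via in-silico saturation mutagenesis; motif-level
    analytics (match significance against shuffled controls, positional
    profiles, PWM usage scores, promoter/enhancer specificity); and
    variant prioritization combining allelic-effect predictions with
    linkage-disequilibrium expansion and GWAS summary statistics.  A
    fully seeded synthetic MPRA simulator with planted motif effects and
    tunable replicate concordance supports end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    GenomicRanges,
    Rcpp,
    rtracklayer,
    vcfR,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
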
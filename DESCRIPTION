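Package: hapdose
Title: Noninvasive Prenatal Testing of Recessive Variants by Relative
    Haplotype Dosage with Population-Based Parental Haplotyping
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers fetal inheritance of recessive pathogenic variants
    (alpha- and beta-thalassemia as prototypes) from maternal plasma
    cell-free DNA. Parental haplotypes are deduced against a phased
    reference panel built from carrier-screening cohorts (a diploid
    haplotype-copying model decoded by the Viterbi algorithm), copy-number
    deletions are carried through phasing as pseudo-SNPs, informative SNPs
    are selected in a two-step paternal-then-maternal order, fetal fraction
    is estimated from paternal-specific alleles, and relative haplotype
    dosage is decoded with a two-state hidden Markov model with
    forward-backward confidence scores and no-call rules. A simulator
    generates reference panels, at-risk families and plasma read counts so
    the whole pipeline can be exercised without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
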
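Package: devilclones
Title: Clonal Evolution Analysis of Transmissible Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing the clonal evolution of naturally
    transmissible cancers from time-stamped whole-genome variant calls, motivated
    by the two Tasmanian devil facial tumour lineages (DFT1 and DFT2). The package
    separates somatic from germline variants with a panel of normals, builds clone
    phylogenies by greedy perfect-phylogeny construction, dates clone origins with
    a strict-clock Poisson MCMC over branch mutation counts and tumour sampling
    dates, deconvolves subclonal cell populations from allele fractions by
    binomial-mixture EM, fits mutational-signature exposures by non-negative least
    squares, regresses per-class mutation burdens against sampling date to obtain
    per-year mutation rates and rate ratios, detects clade-level rate shifts and
    hypermutator outliers, calls copy-number segments and dates whole-genome
    duplications, scans for selection with a context-aware dN/dS test, and
    attributes LINE-1 insertions to source elements via 3' transductions. A
    synthetic transmissible-cancer cohort generator with a full truth table allows
    every analysis to be exercised end-to-end without access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    ape,
    jsonlite,
    pracma,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    vcfR,
    rtracklayer
Config/testthat/edition: 3
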
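Package: scExome
Title: Single-Cell Whole-Exome SNV, CNV and Clonality Analysis with a
    Clone-Structured Simulator
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for single-cell whole-exome sequencing (scWES) analysis of
    tumor evolution: somatic SNV detection in bulk and single cells via a
    one-sided Fisher exact somatic test and a multi-stage filter cascade
    ending in a ternary per-cell mutation matrix; per-cell copy-number
    inference from exonic coverage using a 100-gene moving average with
    central scaling and a mean(a) > mean(t) amplification call; clonality
    analysis (neighbor joining, Fitch parsimony with acctran branch
    mutation counts, parsimony-ratchet search, subclone identification,
    mutation saturation curves); 96-channel mutational-signature exposure
    fitting by non-negative least squares; and driver-gene classification
    and oncoplot matrix exports. A clone-structured scWES simulator with
    whole-genome-amplification noise, allelic dropout and purity-weighted
    bulk mixtures provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ape,
    phangorn,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SingleCell, ExomeSeq, SomaticMutation, CopyNumberVariation,
    Phylogenetics, Software
RoxygenNote: 7.3.3
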
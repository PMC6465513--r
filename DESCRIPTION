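Package: sseqtl
Title: Two-Stage Discovery of Sex-Interacting Expression QTLs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery of sex-interacting cis expression quantitative trait
    loci (ss-eQTLs) by a two-stage regression procedure: a genome-wide ordinary
    least squares scan testing the genotype-by-sex interaction with
    Benjamini-Hochberg false-discovery-rate screening, followed by
    sex-stratified robust (Huber M-estimation, iterated reweighted least
    squares) regression with robust Wald tests and genotype-block quality
    control. Includes X-chromosome hemizygous dosage coding, cis-window
    pairing of variants with transcription start sites, analytic power
    calculations (noncentral F for the interaction stage, noncentral t for
    single-eQTL detection), linkage-disequilibrium-based annotation of calls
    against a trait-association catalog, and a synthetic-data generator that
    emulates the statistical structure of a population eQTL cohort so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    yaml
Suggests:
    MASS,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
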
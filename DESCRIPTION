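Package: pollensel
Title: Selection on Pollen-Specific Versus Sporophyte-Specific Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for comparing the strength of selection on
    pollen-specific (gametophytic) and sporophyte-specific genes in a selfing
    plant: expression-based life-stage classification with presence scores,
    per-strain reconstruction of coding sequences and scoring of putatively
    deleterious alleles (premature stop codons, frameshifts), 0-fold/4-fold
    site diversity statistics (Watterson's theta, pi) and site-frequency
    spectra, counting-method dN/dS over reciprocal-best-hit ortholog pairs,
    gamma distribution-of-fitness-effects estimation from paired spectra with
    gene bootstrap, and covariate-controlled group comparisons (partial
    Spearman correlations, principal-component regression with jackknife
    pruning, ANCOVA with quantile binning). Includes a seeded synthetic-genome
    generator emulating class-specific selection regimes so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    vcfR,
    pracma,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
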
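Package: mirvar
Title: SNP Effects on Plant miRNA Precursors, Hairpin Stability and Target Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome-wide analysis of single nucleotide polymorphisms (SNPs)
    located in microRNA precursors. Assigns variants to mature, precursor and
    flanking regions with strand-aware offsets, computes per-region and
    per-site SNP densities with one-way ANOVA letter groups, derives the
    ancestral-polarized substitution spectrum and transition:transversion
    ratio, folds wild-type and SNP-type precursor hairpins under a simplified
    nearest-neighbor energy model to classify free-energy changes, predicts
    target gain and loss between wild-type and SNP-type mature miRNAs under a
    two-scheme consensus, and tests candidate (e.g. domestication-related)
    miRNA sets for reduced SNP density by permutation. Includes a synthetic
    study generator (genome, hairpin loci, VCF, transcriptome with planted
    target sites) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
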
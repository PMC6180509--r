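Package: holostrain
Title: Strain-Level Metagenomics of Host-Symbiont Holobionts
Version: 0.1.0
Authors@R:
    person("Holostrain", "Developers", email = "holostrain@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize symbiont strain diversity in host-symbiont
    systems ("holobionts") from multi-sample metagenomic variant data.
    Starting from per-sample allele depths (VCF) and per-position coverage
    tracks, the package calls symbiont presence per sample, filters variants
    with a multi-rule coverage cascade, builds per-sample variant profiles
    (most-abundant-allele haplotypes), computes profile distances and
    neighbor-joining phylogenies with site bootstrap, detects intra-host
    strain coinfection from bimodal allele-depth distributions via Poisson
    mixture models, and tests host-symbiont cospeciation by exact event-cost
    reconciliation with a permutation null. A holobiont simulator generates
    ground-truthed datasets so every stage is verifiable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape (>= 5.0),
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
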
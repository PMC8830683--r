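Package: sipscape
Title: Super-Interactive Promoter Analysis for Promoter-Capture Hi-C
    Interactomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies super-interactive promoters (SIPs) from
    promoter-capture Hi-C significance-score matrices by ranking promoter
    baits on their cumulative significant-interaction scores and locating
    the tangent-slope inflection point of the ranked curve, in the style
    of the ROSE super-enhancer procedure.  Profiles promoter-interacting
    regions (PIRs), flags super PIRs, annotates PIRs with open-chromatin
    peaks, GWAS variants and motif disruptions, fits bait-length-adjusted
    logistic enrichment models, assembles SIP regulatory subnetworks, and
    relates SIP status to gene expression through quintile fold
    enrichment and trend tests.  A seeded synthetic-interactome generator
    with planted SIP structure makes every stage testable without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: HiC, Epigenetics, GeneRegulation, FunctionalGenomics
RoxygenNote: 7.3.3
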
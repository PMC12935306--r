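Package: quorumcomp
Title: Quorum-Sensing Gene Screens and Colony-Biofilm Competition Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying intraspecies competition in Bacillus subtilis
    colony biofilms. Implements a two-strain reaction-diffusion biofilm
    simulator (logistic growth with negative density-dependent diffusion),
    quantification of competitive outcomes from two-channel fluorescence
    images and from OD600 growth curves, comparative-genomics screens that
    classify comP quorum-sensing alleles as intact or disrupted (nonsense,
    frameshift, in-frame 3' deletion, insertion element), detect the comP
    poly-thymidine mutation hotspot, assign ComQ pherotypes, census
    rapP-phrP modules (completeness, residue-236 state, replicon context),
    and summarise LXG/T7SS toxin repertoires and differential-expression
    toxin panels. A synthetic-data module generates annotated genomes,
    images and expression tables with known ground truth for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
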
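Package: crossguide
Title: Cross-Species CRISPR-Cas9 Guide Design from Conserved Coding Regions
Version: 0.1.0
Authors@R:
    person("Morgan", "Reyes", email = "morgan.reyes@example.org",
           role = c("aut", "cre"))
Description: Toolkit for designing single guide RNAs that function across many
    species at once. Aligns orthologous coding sequences with a ClustalW-style
    progressive aligner, detects perfectly conserved windows long enough for a
    20-nt protospacer, enumerates PAM (NGG) adjacent guide candidates on both
    strands, predicts per-species functionality by exact protospacer-plus-PAM
    matching, ranks off-target risk against paralogs by minimal Hamming
    mismatch, and designs T7 endonuclease I genotyping assays in silico
    (amplicon extraction, Cas9 cut placement, fragment sizes, frameshift
    fraction). Ships seeded generators for ortholog families and paralogs so
    every stage is testable without downloads, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
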
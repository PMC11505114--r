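Package: zeinpep
Title: In Silico Proteolysis and Bioactive Peptide Profiling of Corn Alpha-Zeins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting bioactive peptides in corn (Zea mays) alpha-zein
    storage proteins. Implements simulated proteolysis with composable protease
    cleavage rules (pepsin, trypsin, chymotrypsin, subtilisin), bioactive-motif
    profiling with the occurrence-frequency statistic A = a/N in both intact-protein
    and digest modes, identity-based sequence grouping of zein paralogs,
    score-threshold filtering of candidate peptides, and a seeded synthetic-data
    generator with planted motifs and known cleavage sites for end-to-end testing.
    Ships a motif database, golden reference tables and a calibration harness for
    protease rule variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
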
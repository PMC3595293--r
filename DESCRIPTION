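Package: limnodiv
Title: Probe-Based Microdiversity Profiling of Freshwater Limnohabitans
    Along Environmental Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for reverse line blot hybridization (RLBH) style
    microdiversity surveys of the freshwater bacterial genus Limnohabitans.
    Implements in-silico hybridization of IUPAC-degenerate oligonucleotide
    probes and primers against 16S-23S rRNA ITS sequences (including nested
    in-silico PCR and probe-panel coverage statistics), the ordinal 0-3
    detection-score data model, per-probe normalized relative-intensity
    profiles along a pH gradient with distribution-shape classification,
    richness and niche-overlap statistics, distance-matrix analyses
    (permutation Mantel tests, PCA on detection/no-detection data,
    occurrence-similarity clustering of probes), and a fully seeded
    synthetic-data generator with exported ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
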
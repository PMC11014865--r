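Package: plastosort
Title: Sorting Single-Gene Trees and Predicting Bipartite Plastid-Targeting
    Presequences in Fucoxanthin Dinoflagellates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies the evolutionary origin of nucleus-encoded plastid
    proteins from their single-gene phylogenies. A tree-sorting engine finds,
    for a seed sequence, the highest-supported bipartition whose seed-side
    clade satisfies configurable taxon-set criteria, and assigns each tree to
    origin categories such as plastid-late (haptophyte endosymbiont),
    plastid-early (dinoflagellate host) or lateral acquisitions from green,
    brown or prokaryotic sources. Companion modules implement the
    homology-search and alignment filters that gate which proteins receive
    trees, a modified ASAFind-style bipartite targeting-signal predictor built
    on a custom cleavage-site position-specific scoring matrix, signal-peptide
    motif and composition statistics, and deterministic synthetic-data
    generators with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
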
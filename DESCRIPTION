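Package: phipflag
Title: PhIP-Seq Enrichment Calling and Anti-Flagellin Repertoire Analysis
Version: 0.1.0
Authors@R: person("phipflag", "maintainers", email = "maintainers@phipflag.org",
    role = c("aut", "cre"))
Description: Tools for phage-display immunoprecipitation sequencing (PhIP-Seq)
    antibody-repertoire studies of bacterial flagellins. Implements enrichment
    calling from peptide-by-sample count matrices under a generalized Poisson
    null with per-input-level parameter interpolation, Bonferroni
    seropositivity and fold-change rules; peptide library design (tiling,
    reverse translation with restriction-site avoidance, Hamming
    error-correcting barcodes); pairwise protein alignment, flagellin N-/C-
    terminal domain annotation and relative epitope-position profiling;
    stimulator/silent/evader flagellin classification and class-similarity
    statistics; and a synthetic-data generator that plants disease-like
    anti-flagellin binding signatures into matched case/control cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
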
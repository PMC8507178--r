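Package: molsearch
Title: Analysis of Individual and Collective Human Chemical-Space Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse goal-directed chemical-space search experiments in
    which human participants (individually or collectively) edit molecules to
    maximise a similarity score towards a hidden target. Provides an ECFC4-style
    1024-bucket count-fingerprint engine with count-Tanimoto scoring normalised
    to the 0-1000 range, molecule canonicalisation and InChIKey-based
    uniqueness, Murcko scaffold extraction and complexity profiling, a
    provenance-aware experiment-log model (design sessions, evolution steps,
    leader changes, collaboration degree, time played), GuacaMol-style
    goal-directed benchmark scoring with embedded published baselines, a
    score-guided agent-based simulator generating experiment logs in individual
    and collective modes, and a fixed-seed t-SNE map of the explored chemical
    space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    dplyr,
    jsonlite,
    parallel,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
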
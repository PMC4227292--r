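Package: covarnet
Title: Covariation Dependency Networks and CRF Scoring for Categorical
    Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts conditionally-weighted dependency networks
    (metagraphs) from fixed-length categorical sequence alignments:
    per-position marginal profiles, pairwise joint distributions,
    signed residuals against the independence expectation, and Fisher
    exact significance for every category pair. Networks are refined by
    threshold and statistical filters with pinning and replayable manual
    edits, converted into pairwise conditional-random-field scoring
    models for candidate sequences, and mined for shifted "echo"
    dependency runs that fingerprint misaligned families, which are
    corrected by aligning the dependencies rather than the symbols.
    Includes a deterministic cylinder layout of categorical parallel
    axes with an occlusion certificate, scene export, and synthetic
    family generators (independent nulls, Watson-Crick stem-loops,
    shifted-motif families) with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
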
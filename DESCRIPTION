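Package: pathfigr
Title: Gene Recognition and Gene-Set Analytics for Pathway Figure OCR
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts human gene content from the OCR text of published
    pathway figures and analyses the resulting per-figure gene sets. Words
    from OCR output are normalized (case, Greek letters, punctuation),
    corrected for common OCR character confusions, stripped of author
    decorations (e.g. p-AKT, CDK1-FLAG), and expanded from range and slash
    shorthand (e.g. WNT1-5, LATS1/2), with a lexicon match attempted after
    each transform round against a layered lexicon of HGNC current, alias
    and previous symbols plus conventional bioentity names. Downstream
    tools build per-figure gene sets, filter by size, detect duplicate and
    contained sets, compute Jaccard and directional overlap matrices with
    hierarchical clustering, annotate sets by hypergeometric
    overrepresentation against GMT collections, and summarise corpora
    (figure-versus-text comparison, database novelty, classifier metrics,
    binomial proportion intervals, first-appearance year spans). A
    synthetic-figure generator plants decorated symbols with ground-truth
    manifests so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    ape,
    optparse
Suggests:
    testthat (>= 3.0.0),
    png,
    withr
Config/testthat/edition: 3
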
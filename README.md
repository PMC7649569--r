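# pathfigr

Published pathway diagrams are one of the densest records of molecular
biology in the literature, yet their gene content is locked inside raster
images. Running OCR on a figure yields a noisy word list: symbols decorated
with experimental tags (`p-AKT`, `CDK1-FLAG`), Greek spellings (`NF-κB`,
`TNFα`), family shorthand (`WNT1-5`, `LATS1/2`), and character-level OCR
confusions (`AKTI` for `AKT1`). **pathfigr** turns such word lists into
per-figure sets of human NCBI Gene identifiers and provides the analytics
layer for the resulting gene-set corpus. It is aimed at pathway curators,
text-mining researchers, and anyone building gene-set resources from figure
OCR output.

## Method

For each OCR word `w`, a transform chain generates candidate symbols in
rounds:

1. **normalize** — uppercase, Greek→Latin mapping, Unicode-dash
   unification, surrounding punctuation stripped;
2. **substitute** — OCR confusion edits (`0↔O`, `1↔I`, `1↔L`, `5↔S`,
   `8↔B`), at most one position by default;
3. **strip** — curated decoration prefixes/suffixes removed (`P-`,
   `PHOSPHO-`, `-FLAG`, `-GFP`, ...);
4. **expand** — numeric ranges `STEMa-b → {STEMa … STEMb}` and slash lists
   `STEMa/b → {STEMa, STEMb}`.

After every round the candidates are looked up in a layered lexicon —
current HGNC symbols, then HGNC aliases, then previous symbols, then
conventional bioentity names (complex/family names mapped to member genes).
The first round with a match wins; within a candidate only the best tier is
kept, and an alias that maps to several genes at its best tier is dropped
rather than guessed. Family bioentity names (e.g. `AMPK`) emit one hit per
member gene by design. An optional stoplist removes the 20 three-letter
amino-acid codes, whose residue labels otherwise collide with gene aliases.

Downstream, per-figure gene sets support: size filtering; duplicate and
strict-containment detection; pairwise Jaccard `|A∩B|/|A∪B|` and
directional overlap `|A∩B|/|A|` matrices with average-linkage hierarchical
clustering; overrepresentation annotation via the one-sided hypergeometric
test `P(X ≥ k)` for `X ~ Hypergeom(N, K, n)` with Benjamini–Hochberg
adjustment within each set; and corpus statistics (figure-vs-text gene
comparison, database novelty, precision/recall/MCC, Wald binomial
proportion intervals, first-appearance year spans).

A synthetic-corpus generator (`make_corpus()`) plants decorated, ranged and
Greek-spelled symbols with exact ground-truth manifests, so the entire
pipeline is testable offline against a closed toy lexicon.

## Worked example

```r
library(pathfigr)

corp  <- make_corpus(n_figures = 6, decoration_rate = 0.5,
                     range_rate = 0.4, seed = 42)
lex   <- build_lexicon(corp$lexicon$hgnc, corp$lexicon$bioentities,
                       stoplist = default_stoplist())
chain <- pf_chain()

doc <- words_from_text("demo", "p-AKT  WNT1-5\nLATS1/2 NF-κB Met HELLOWORLD")
recognize_document(doc, chain, lex)$hits
#>   raw_word matched_variant official_symbol gene_id       source
#> 1    p-AKT             AKT            AKT1     207   hgnc_alias
#> 2   WNT1-5            WNT1            WNT1    7471 hgnc_current
#> 3   WNT1-5            WNT2            WNT2    7472 hgnc_current
#> 4   WNT1-5            WNT3            WNT3    7473 hgnc_current
#> 5   WNT1-5            WNT4            WNT4    7474 hgnc_current
#> 6   WNT1-5            WNT5            WNT5    7475 hgnc_current
#> 7  LATS1/2           LATS1           LATS1    9113 hgnc_current
#> 8  LATS1/2           LATS2           LATS2   26524 hgnc_current
#> 9    NF-κB           NF-KB           NFKB1    4790  bioentities
```

`p-AKT` resolves through the strip round to the alias `AKT`; the range and
slash words expand to every family member; the Greek-spelled complex name
matches the bioentities tier; `Met` is silenced by the amino-acid stoplist
and `HELLOWORLD` is simply unmatched.

```r
hits <- recognize_corpus(corp$docs, chain, lex, progress_every = 0)
sets <- build_sets(hits, metadata = corp$metadata)
summarize_corpus(sets, hits)
#> figures: 6 with genes / 6 total
#> instances: 80 | unique genes: 36 | mean genes/figure: 13.3
```

The hit table keeps one row per recognized *instance* (a symbol repeated in
a figure counts twice); `build_sets()` deduplicates to unique genes per
figure. From there, `filter_by_size()`, `overlap_matrix()`,
`cluster_sets()`, `annotate_sets()` and `write_gmt()` cover the analysis
layer.

A command-line front-end is installed at
`system.file("exec", "pathfigr.R", package = "pathfigr")` with
`recognize`, `analyze` and `fixtures` subcommands.

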
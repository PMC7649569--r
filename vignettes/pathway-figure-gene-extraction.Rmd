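---
title: "Extracting gene content from pathway figure OCR: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting gene content from pathway figure OCR: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathfigr)
```

## The problem and the model

A pathway figure names its molecules as free-form text labels. OCR recovers
those labels as a bag of words, but the words are rarely clean HGNC
symbols: authors decorate symbols with modification and tag affixes
(`p-AKT`, `CDK1-FLAG`), compress families into ranges and slash lists
(`WNT1-5`, `LATS1/2`), and use Greek letters and conventional complex names
(`NF-κB`, `AMPK`); OCR itself confuses visually similar glyphs (`1/I/L`,
`0/O`, `5/S`, `8/B`). pathfigr models recognition as a *staged rewriting*
of each word followed by lexicon lookup: each transform round proposes
candidate symbols, and a match attempted after every round grounds the word
to NCBI Gene identifiers.

Two assumptions shape the design. First, words are independent: no attempt
is made to reassemble a symbol split across lines by the OCR engine (a
known, accepted loss). Second, position on the page carries no signal the
pipeline uses — recognition is purely lexical.

## The transform chain

Round 0 is character normalization: uppercasing, Greek→Latin mapping from a
bundled editable table, Unicode-dash unification, removal of internal
whitespace and of surrounding punctuation `()[]{}.,:;*`. Normalization is
idempotent, and the normalized word is always the first candidate, so a
clean symbol matches immediately and no speculative edits are attempted for
it.

The subsequent rounds, in order:

* **substitute** applies the OCR confusion table at up to
  `max_substitutions` positions (default **1**: single-character OCR errors
  dominate, and two simultaneous edits sharply increase false-positive
  risk);
* **strip** removes curated decoration prefixes and suffixes (both sides
  allowed), shipped as plain-text config files so the affix inventory can
  grow;
* **expand** rewrites `STEMa-b` into its members when `a < b` and
  `b − a < max_span` (default **20**, chosen so the largest human gene
  families, such as the 19-member WNT family, still expand while absurd
  spans like `IL1-100` are left alone), and splits slash lists.

Round ordering — normalize, substitute, strip, expand — is a package
decision: substitution repairs the raw glyphs before affix matching, and
expansion is last because it is the only rule that multiplies candidates.
The total candidate list per word is capped at `max_candidates = 64`, a
bound no realistic label approaches. Hyphen ambiguity (`CDK1-FLAG` strips,
`WNT1-5` expands) is resolved by the lexicon, not by the rules: strip fires
only on the curated affix sets, expansion only on trailing
digit-dash-digit patterns, and whichever candidate actually matches wins.

## The lexicon and matching semantics

The lexicon layers four tiers in priority order: current HGNC symbols,
HGNC aliases, previous (retired) symbols, and bioentities — conventional
complex/family names mapped to their member official symbols. All variants
are normalized at build time (OCR case is unreliable and HGNC symbols are
conventionally uppercase). Matching stops at the *first* round with at
least one hit; later rounds are increasingly speculative edits of a word
already explained, and collecting across rounds would over-generate.

Within a matched candidate only the best tier is kept. If the best tier
still maps the variant to several genes, the policy splits by tier kind:

* an **HGNC alias collision** (e.g. an alias shared by two kinases) is a
  true ambiguity — the candidate is dropped and logged, preferring
  precision over recall;
* a **bioentities family name** maps to several genes *by construction*
  (that is what a family entry means), so it emits one hit per member.

The package ships a stoplist of the 20 three-letter amino-acid codes
(`Tyr`, `His`, `Met`, ...), the one systematic false-positive class in this
kind of corpus: residue annotations in figures collide with gene aliases.
It is off by default — the codes are legitimate aliases in some contexts —
and enabled by passing `default_stoplist()` to `build_lexicon()`.

The hit table keeps every *instance* (a symbol repeated in a figure counts
each time); `build_sets()` deduplicates to unique gene IDs per figure. All
downstream counting is by NCBI Gene ID, never by symbol string.

## Set analytics

`filter_by_size()` applies inclusive thresholds; the package's working
defaults are **7** distinct genes for annotation (small enough to keep most
of the corpus's unique-gene coverage) and **10** for enrichment use (very
small query sets make overrepresentation unstable). Duplicate detection
groups figures with identical gene sets; containment is *strict* subset,
so the two categories are disjoint by definition.

The overlap matrices follow the set formulas directly: Jaccard
`|A∩B|/|A∪B|` (symmetric) and directional overlap `|A∩B|/|A|`, whose row
hits 1 exactly when the row set is contained in the column set. Clustering
is agglomerative on `1 − similarity`; the default is Jaccard distance with
average linkage — a conventional choice for set similarity, exposed as
options (`linkage`, `distance`) rather than claimed canonical. `hclust` is
deterministic given the matrix, so leaf orders and Newick exports are
byte-reproducible.

## Enrichment

Overrepresentation uses the one-sided hypergeometric upper tail
`P(X ≥ k)` with `X ~ Hypergeom(N, K, n)` — the standard test form for
gene-set overrepresentation. Multiple testing is Benjamini–Hochberg within
each query set across terms, significance at `fdr < 0.05` by default; both
are package conventions, documented rather than hidden. The default gene
universe is the union of the annotation collection's members — the only
universe derivable from the collection itself — and can be overridden with
the recognizer's full gene universe when that is the more honest null.
Annotation terms with fewer than 7 associated genes are dropped before
testing (`filter_collection()`), removing terms too small to test stably.

Per-set top terms take the smallest FDR, with ties broken by larger
overlap and then lexicographic term ID, so results are reproducible. The
corpus-level `dedup_top_terms()` ranking is greedy exclusive coverage:
singular/plural label pairs are merged (trailing-`S` rule, applied only
when both forms are present), then the term covering the most
not-yet-counted items is picked repeatedly (ties alphabetical); after ten
picks the remainder is `Other`.

## Corpus statistics

`summarize_corpus()` defaults to instance mode — total recognized
instances divided by gene-containing figures, matching how a mean of
"genes recognized per figure" is naturally reported for an instance-level
table — with unique-per-figure mode behind a flag. The binomial proportion
interval is the Wald half-width `z·sqrt(p(1−p)/n)` by default, with Wilson
available for small samples or extreme proportions. Classifier metrics
flag undefined denominators as `NA` rather than coercing to zero; MCC is
0 only for the degenerate one-margin case. First-appearance spans exclude
genes missing from the user-supplied event table and keep negative spans
flagged rather than silently dropping them.

## The synthetic corpus generator

`make_corpus()` emulates exactly the phenomena the transform chain
handles: bare symbols and aliases, random case, decoration affixes drawn
from the shipped sets, numeric ranges and slash lists fully covered by the
toy lexicon, Greek-spelled bioentity names, and distractor vocabulary that
includes amino-acid codes to exercise the stoplist path. Each figure's
manifest records the exact gene IDs its plants must yield, enabling
exact-recovery assertions; everything is reproducible from the seed.

What it deliberately does *not* emulate: real OCR noise beyond the
confusion table, multi-word symbols split across lines, composite figures,
non-human gene content, and genuine pathway graphics. Passing the planted
recovery tests therefore demonstrates that the post-OCR machinery is
correct on its declared grammar — not that recognition on arbitrary real
figures reaches any particular recall. The rendered-image path
(`render_figure()` plus an injected OCR engine) exists for engine
round-trip checks; no engine ships with the package, and the text fixtures
are the primary test surface.

Test and acceptance runs use corpora of 200 figures (recovery), 200 random
sets (redundancy oracles), and exhaustive hypergeometric checks up to
universe size 12 — sizes chosen to exercise every code path while keeping
a full test run around two minutes on one core.

## Known limitations

* One word, one symbol: `NF` + `κB` on separate lines is not reassembled.
* The shipped transform tables are a curated core, not an exhaustive
  inventory; all are plain-text config files meant to be extended.
* The lexicon is human-only, though nothing in the design precludes
  loading another species' nomenclature table.
* Interaction edges, compartments and other graphical semantics are out of
  scope; the unit of extraction is the gene mention.
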
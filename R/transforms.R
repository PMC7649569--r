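# Transform chain applied to OCR words before lexicon matching.
#
# Pathway authors rarely write clean HGNC symbols: labels carry modification
# prefixes ("p-AKT"), tag suffixes ("CDK1-FLAG"), Greek letters ("NF-κB"),
# family shorthand ("WNT1-5", "LATS1/2"), and OCR itself confuses visually
# similar glyphs (1/I/L, 0/O, 5/S, 8/B). Each transform turns one word into
# candidate symbol strings; matching is attempted after every round.

#' Read a bundled transform table
#'
#' @param name File name under `inst/extdata`.
#' @return Path to the installed file.
#' @keywords internal
pf_extdata <- function(name) {
  p <- system.file("extdata", name, package = "pathfigr")
  if (!nzchar(p)) stop("bundled table not found: ", name)
  p
}

read_greek_map <- function(file = pf_extdata("greek_map.tsv")) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", quote = "")
  stats::setNames(tab$latin, tab$greek)
}

read_confusions <- function(file = pf_extdata("ocr_confusions.tsv")) {
  utils::read.delim(file, colClasses = "character", quote = "")
}

read_affixes <- function(file) {
  x <- readLines(file, warn = FALSE, encoding = "UTF-8")
  x <- sub("#.*$", "", x)
  x <- toupper(trimws(x))
  x[nzchar(x)]
}

#' Normalize an OCR word
#'
#' Uppercases, maps Greek letters to Latin equivalents via the bundled table,
#' unifies Unicode dash variants to `-`, strips surrounding punctuation
#' (`()[]{}.,:;*`) and removes internal whitespace. Vectorized.
#'
#' @param word Character vector of raw OCR words.
#' @param greek Named character vector mapping Greek letters to Latin.
#' @return Character vector of normalized words; `""` marks a word that
#'   reduced to nothing (callers skip it).
#' @examples
#' normalize_characters(c("NF-κB,", "(p53)", "MAPK1"))
#' @export
normalize_characters <- function(word, greek = read_greek_map()) {
  x <- as.character(word)
  for (g in names(greek)) x <- gsub(g, greek[[g]], x, fixed = TRUE)
  x <- gsub("[‐‑‒–—―−]", "-", x)
  x <- gsub("[[:space:]]+", "", x)
  x <- toupper(x)
  x <- gsub("^[][(){}.,:;*]+|[][(){}.,:;*]+$", "", x)
  x
}

#' Generate OCR-confusion candidates
#'
#' Applies the character confusion table (`0/O`, `1/I`, `1/L`, `5/S`, `8/B`)
#' at up to `max_substitutions` positions. The unmodified word is always the
#' first candidate.
#'
#' @param word A normalized word (scalar).
#' @param confusions Data frame with columns `from`, `to`.
#' @param max_substitutions Maximum positions edited per candidate.
#' @return Character vector of candidates, original first, no duplicates.
#' @export
substitute_ocr_errors <- function(word, confusions = read_confusions(),
                                  max_substitutions = 1L) {
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  alts <- lapply(chars, function(ch) confusions$to[confusions$from == ch])
  pos <- which(lengths(alts) > 0)
  out <- word
  if (length(pos) > 0 && max_substitutions >= 1L) {
    k_max <- min(max_substitutions, length(pos))
    for (k in seq_len(k_max)) {
      for (idx in utils::combn(length(pos), k, simplify = FALSE)) {
        sel <- pos[idx]
        grids <- expand.grid(lapply(alts[sel], identity),
                             stringsAsFactors = FALSE)
        for (r in seq_len(nrow(grids))) {
          v <- chars
          v[sel] <- unlist(grids[r, ], use.names = FALSE)
          out <- c(out, paste(v, collapse = ""))
        }
      }
    }
  }
  unique(out[nzchar(out)])
}

#' Strip decoration prefixes and suffixes
#'
#' Removes curated experimental-tag affixes (e.g. `P-`, `-FLAG`) from a word,
#' emitting the original plus each stripped form (prefix-only, suffix-only,
#' and both sides).
#'
#' @param word A normalized word (scalar).
#' @param prefixes,suffixes Character vectors of affixes (with their dash).
#' @return Character vector of candidates, original first.
#' @export
strip_decorations <- function(word,
                              prefixes = read_affixes(pf_extdata("prefixes.txt")),
                              suffixes = read_affixes(pf_extdata("suffixes.txt"))) {
  cands <- word
  pre_stripped <- character(0)
  for (p in prefixes) {
    if (startsWith(word, p) && nchar(word) > nchar(p)) {
      pre_stripped <- c(pre_stripped, substring(word, nchar(p) + 1L))
    }
  }
  suf_stripped <- character(0)
  for (s in suffixes) {
    if (endsWith(word, s) && nchar(word) > nchar(s)) {
      suf_stripped <- c(suf_stripped, substring(word, 1L, nchar(word) - nchar(s)))
    }
  }
  both <- character(0)
  for (w in pre_stripped) {
    for (s in suffixes) {
      if (endsWith(w, s) && nchar(w) > nchar(s)) {
        both <- c(both, substring(w, 1L, nchar(w) - nchar(s)))
      }
    }
  }
  unique(c(cands, pre_stripped, suf_stripped, both))
}

#' Expand range and slash shorthand into member symbols
#'
#' `STEM<a>-<b>` with `a < b` and `b - a < max_span` expands to
#' `STEMa ... STEMb`; `STEM<a>/<b>[/...]` expands to one symbol per number;
#' `A/B` where both halves look like full symbols (length >= 2, contain a
#' letter) expands to `A` and `B`. Anything else is returned unchanged.
#'
#' @param word A normalized word (scalar).
#' @param max_span Guard on numeric range width; ranges spanning `max_span`
#'   or more members are left unexpanded. Default 20 so that the largest
#'   human gene families (e.g. the 19-member WNT family) still expand.
#' @return Character vector of member symbols, or `word` itself.
#' @examples
#' expand_multi("WNT1-5")
#' expand_multi("LATS1/2")
#' @export
expand_multi <- function(word, max_span = 20L) {
  # numeric range: stem ends in a letter, then digits-dash-digits
  m <- regmatches(word, regexec("^(.*[A-Z])([0-9]+)-([0-9]+)$", word))[[1]]
  if (length(m) == 4) {
    a <- as.integer(m[3]); b <- as.integer(m[4])
    if (!is.na(a) && !is.na(b) && a < b && (b - a) < max_span) {
      return(paste0(m[2], a:b))
    }
    return(word)
  }
  # numeric slash list: STEM1/2[/3...]
  if (grepl("^.*[A-Z][0-9]+(/[0-9]+)+$", word)) {
    stem <- sub("^(.*[A-Z])[0-9]+(/[0-9]+)+$", "\\1", word)
    nums <- strsplit(regmatches(word, regexpr("[0-9]+(/[0-9]+)+$", word)),
                     "/", fixed = TRUE)[[1]]
    return(unique(paste0(stem, nums)))
  }
  # general slash pair: both halves plausible full symbols
  if (grepl("/", word, fixed = TRUE)) {
    halves <- strsplit(word, "/", fixed = TRUE)[[1]]
    if (length(halves) == 2 && all(nchar(halves) >= 2) &&
        all(grepl("[A-Z]", halves))) {
      return(unique(halves))
    }
  }
  word
}

#' Build the default transform chain
#'
#' The chain defines the matching rounds: round 0 is the normalized word
#' itself; subsequent rounds apply OCR-confusion substitution, decoration
#' stripping, and range/slash expansion, in that order. Every table is a
#' plain-text config file so the rule inventory can be extended.
#'
#' @param greek_map,confusions,prefixes,suffixes Paths to rule tables;
#'   defaults are the bundled ones.
#' @param max_substitutions Confusion edits per candidate (default 1).
#' @param max_span Range-expansion guard (default 20).
#' @param max_candidates Hard cap on total candidates per word (default 64).
#' @return A `pf_chain` object.
#' @export
pf_chain <- function(greek_map = pf_extdata("greek_map.tsv"),
                     confusions = pf_extdata("ocr_confusions.tsv"),
                     prefixes = pf_extdata("prefixes.txt"),
                     suffixes = pf_extdata("suffixes.txt"),
                     max_substitutions = 1L,
                     max_span = 20L,
                     max_candidates = 64L) {
  greek <- read_greek_map(greek_map)
  conf <- read_confusions(confusions)
  pre <- read_affixes(prefixes)
  suf <- read_affixes(suffixes)
  rules <- list(
    list(name = "substitute", kind = "substitute",
         apply = function(w) substitute_ocr_errors(w, conf, max_substitutions)),
    list(name = "strip", kind = "strip",
         apply = function(w) strip_decorations(w, pre, suf)),
    list(name = "expand", kind = "expand",
         apply = function(w) expand_multi(w, max_span))
  )
  structure(list(greek = greek, rules = rules,
                 max_candidates = as.integer(max_candidates)),
            class = "pf_chain")
}

#' Candidate rounds for one word
#'
#' @param word Raw OCR word.
#' @param chain A [pf_chain()].
#' @return List of character vectors, one per round; empty list if the word
#'   normalizes to nothing. Candidates never repeat across rounds.
#' @export
candidate_rounds <- function(word, chain = pf_chain()) {
  norm <- normalize_characters(word, chain$greek)
  if (!nzchar(norm)) return(list())
  rounds <- list(norm)
  seen <- norm
  total <- 1L
  for (rule in chain$rules) {
    cands <- rule$apply(norm)
    cands <- setdiff(cands[nzchar(cands)], seen)
    if (total + length(cands) > chain$max_candidates) {
      cands <- utils::head(cands, max(0L, chain$max_candidates - total))
    }
    if (length(cands) > 0) {
      rounds[[length(rounds) + 1L]] <- cands
      seen <- c(seen, cands)
      total <- total + length(cands)
    }
  }
  rounds
}

#' Flat candidate stream for one word
#'
#' @inheritParams candidate_rounds
#' @return Character vector of candidates in round order, normalized word
#'   first, no duplicates; empty if the word normalizes to nothing.
#' @export
candidate_stream <- function(word, chain = pf_chain()) {
  unlist(candidate_rounds(word, chain), use.names = FALSE)
}
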
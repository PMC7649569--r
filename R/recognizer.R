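# Core recognition loop: walk each OCR word through the transform rounds and
# attempt a lexicon match after every round. The first round that matches
# wins — later rounds are increasingly speculative edits of a word that has
# already been explained, so stopping early prevents over-generation
# (e.g. "AKT1" must not also fire the "AKT1 -> AKTI -> ..." edits).

.hit_cols <- function() {
  data.frame(raw_word = character(0), matched_variant = character(0),
             official_symbol = character(0), gene_id = integer(0),
             source = character(0), stringsAsFactors = FALSE)
}

#' Recognize genes in a single OCR word
#'
#' Iterates the candidate rounds; at the first round with at least one
#' lexicon match, emits hits for all matching candidates of that round and
#' stops. Within one candidate, only the best lexicon tier is kept; if the
#' best tier is ambiguous (one variant, several gene IDs) the candidate is
#' dropped and recorded — precision over recall.
#'
#' @param word Raw OCR word.
#' @param chain A [pf_chain()].
#' @param lex A [build_lexicon()] result.
#' @return Data frame with columns `raw_word`, `matched_variant`,
#'   `official_symbol`, `gene_id`, `source` (zero rows if unmatched); the
#'   `"ambiguous"` attribute lists dropped ambiguous variants.
#' @export
recognize_word <- function(word, chain, lex) {
  rounds <- candidate_rounds(word, chain)
  ambiguous <- character(0)
  for (cands in rounds) {
    rows <- list()
    for (cand in cands) {
      ent <- lookup(lex, cand)
      if (nrow(ent) == 0) next
      best <- ent[ent$source == ent$source[1], , drop = FALSE]
      ids <- unique(best$gene_id)
      # multiple genes at the best tier: an HGNC alias collision is a true
      # ambiguity and is dropped; a bioentities family/complex name maps to
      # all member genes by design and emits one hit per member
      if (length(ids) > 1 && best$source[1] != "bioentities") {
        ambiguous <- c(ambiguous, cand)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        raw_word = word, matched_variant = cand,
        official_symbol = best$official_symbol[match(ids, best$gene_id)],
        gene_id = ids,
        source = as.character(best$source[1]), stringsAsFactors = FALSE)
    }
    if (length(rows) > 0) {
      hits <- do.call(rbind, rows)
      hits <- hits[!duplicated(hits$gene_id), , drop = FALSE]
      rownames(hits) <- NULL
      attr(hits, "ambiguous") <- unique(ambiguous)
      return(hits)
    }
  }
  out <- .hit_cols()
  attr(out, "ambiguous") <- unique(ambiguous)
  out
}

#' Recognize genes across one figure's OCR document
#'
#' Every word occurrence can contribute hits: a symbol repeated in a figure
#' yields one hit per occurrence (instance counting); deduplication to
#' unique genes happens when sets are built.
#'
#' @param doc A `pf_ocr_document`.
#' @inheritParams recognize_word
#' @return List with `hits` (data frame: figure_id, pmcid, word_index,
#'   raw_word, matched_variant, official_symbol, gene_id, source),
#'   `unmatched` (figure_id, raw_word), and `stats` (words_seen,
#'   words_matched, hits_emitted).
#' @export
recognize_document <- function(doc, chain, lex) {
  stopifnot(inherits(doc, "pf_ocr_document"))
  per_word <- lapply(seq_along(doc$words),
                     function(i) recognize_word(doc$words[i], chain, lex))
  matched <- vapply(per_word, nrow, integer(1)) > 0
  hits <- if (any(matched)) {
    do.call(rbind, lapply(which(matched), function(i) {
      h <- per_word[[i]]
      cbind(data.frame(figure_id = doc$figure_id,
                       pmcid = if (is.null(doc$pmcid)) NA_character_ else doc$pmcid,
                       word_index = i, stringsAsFactors = FALSE),
            h)
    }))
  } else {
    cbind(data.frame(figure_id = character(0), pmcid = character(0),
                     word_index = integer(0), stringsAsFactors = FALSE),
          .hit_cols())
  }
  rownames(hits) <- NULL
  unmatched <- data.frame(figure_id = rep(doc$figure_id, sum(!matched)),
                          raw_word = doc$words[!matched],
                          stringsAsFactors = FALSE)
  list(hits = hits, unmatched = unmatched,
       stats = c(words_seen = length(doc$words),
                 words_matched = sum(matched),
                 hits_emitted = nrow(hits)))
}

#' Recognize genes across a corpus
#'
#' @param docs List of `pf_ocr_document` with unique figure_ids.
#' @inheritParams recognize_word
#' @param progress_every Log a progress message every this many figures
#'   (0 disables).
#' @return Hit table: one row per recognized gene instance, ordered by
#'   (figure_id, word_index, gene_id).
#' @export
recognize_corpus <- function(docs, chain, lex, progress_every = 1000L) {
  ids <- vapply(docs, function(d) d$figure_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate figure_id in corpus: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  parts <- vector("list", length(docs))
  for (i in seq_along(docs)) {
    parts[[i]] <- recognize_document(docs[[i]], chain, lex)$hits
    if (progress_every > 0 && i %% progress_every == 0) {
      message("recognized ", i, "/", length(docs), " figures")
    }
  }
  hits <- do.call(rbind, parts)
  hits <- hits[order(hits$figure_id, hits$word_index, hits$gene_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write / read the hit table
#'
#' TSV columns mirror the interactive gene table: figure_id, pmcid,
#' word_index, raw_word, matched_variant, official_symbol, ncbi_gene_id,
#' lexicon_source.
#'
#' @param hits Hit table from [recognize_corpus()].
#' @param file Output path.
#' @export
write_hit_table <- function(hits, file) {
  out <- hits
  names(out)[names(out) == "gene_id"] <- "ncbi_gene_id"
  names(out)[names(out) == "source"] <- "lexicon_source"
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(file) {
  tab <- utils::read.delim(file, sep = "\t", quote = "", comment.char = "",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  names(tab)[names(tab) == "ncbi_gene_id"] <- "gene_id"
  names(tab)[names(tab) == "lexicon_source"] <- "source"
  if ("pmcid" %in% names(tab)) tab$pmcid <- as.character(tab$pmcid)
  tab
}

#' Export per-figure gene sets as JSON
#'
#' One object per figure: `{pmcid, figure_id, genes: [ncbi_gene_id, ...]}`.
#'
#' @param hits Hit table.
#' @param file Output path.
#' @export
export_geneset_json <- function(hits, file) {
  figs <- unique(hits$figure_id)
  objs <- lapply(figs, function(f) {
    sub <- hits[hits$figure_id == f, , drop = FALSE]
    list(pmcid = if (all(is.na(sub$pmcid))) NULL else sub$pmcid[1],
         figure_id = f, genes = sort(unique(sub$gene_id)))
  })
  jsonlite::write_json(objs, file, auto_unbox = TRUE, null = "null")
  invisible(file)
}
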
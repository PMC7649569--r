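# Layered human gene-symbol lexicon.
#
# Four tiers, matched in priority order: current HGNC symbols, HGNC aliases,
# previous (retired) HGNC symbols, and conventional bioentity names
# (complexes/families such as "NF-kB" mapped to member official symbols).
# All variants are normalized (see normalize_characters) at build time.

PF_TIERS <- c("hgnc_current", "hgnc_alias", "hgnc_previous", "bioentities")

# accepted header spellings for the HGNC-style table
.hgnc_cols <- list(
  symbol = c("symbol", "approved_symbol", "Approved symbol"),
  alias_symbol = c("alias_symbol", "alias_symbols", "Alias symbols"),
  prev_symbol = c("prev_symbol", "previous_symbols", "Previous symbols"),
  ncbi_gene_id = c("ncbi_gene_id", "entrez_id", "NCBI Gene ID")
)

.pick_col <- function(tab, aliases, what) {
  hit <- intersect(aliases, names(tab))
  if (length(hit) == 0) {
    stop("HGNC table is missing a required column (", what,
         "); accepted names: ", paste(aliases, collapse = ", "))
  }
  tab[[hit[1]]]
}

# split "|"- or ", "-delimited list cells
.split_list_col <- function(x) {
  strsplit(ifelse(is.na(x), "", x), "\\s*\\|\\s*|,\\s+")
}

#' Read a stoplist file
#'
#' One variant per line; `#` starts a comment. Variants are normalized the
#' same way lexicon variants are.
#'
#' @param file Path to the stoplist.
#' @return Character vector of normalized variants.
#' @export
read_stoplist <- function(file) {
  x <- readLines(file, warn = FALSE, encoding = "UTF-8")
  x <- trimws(sub("#.*$", "", x))
  unique(normalize_characters(x[nzchar(x)]))
}

#' The bundled amino-acid stoplist
#'
#' The 20 three-letter amino-acid codes (Tyr, His, Met, ...), which collide
#' with gene aliases when they appear as residue labels in figures. Not
#' applied unless passed to [build_lexicon()].
#'
#' @return Character vector of 20 normalized codes.
#' @export
default_stoplist <- function() {
  read_stoplist(pf_extdata("stoplist_amino_acids.txt"))
}

#' Build the layered gene-symbol lexicon
#'
#' @param hgnc_table Path to an HGNC-style TSV with columns for the approved
#'   symbol, alias symbols, previous symbols and NCBI Gene ID (list columns
#'   delimited by `|` or `, `).
#' @param bioentities_table Optional path to a CSV whose first column is a
#'   conventional name and remaining columns official symbols it maps to
#'   (one entry per member gene for families/complexes).
#' @param stoplist Optional character vector of variants to exclude, e.g.
#'   [default_stoplist()].
#' @return A `pf_lexicon`: entry table plus a hash index, tiers ordered
#'   `hgnc_current > hgnc_alias > hgnc_previous > bioentities`.
#' @examples
#' hgnc <- tempfile(fileext = ".tsv")
#' writeLines(c("symbol\talias_symbol\tprev_symbol\tncbi_gene_id",
#'              "MAPK1\tERK2|p42\tPRKM1\t5594"), hgnc)
#' lex <- build_lexicon(hgnc)
#' lookup(lex, "ERK2")
#' @export
build_lexicon <- function(hgnc_table, bioentities_table = NULL,
                          stoplist = NULL) {
  tab <- utils::read.delim(hgnc_table, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", comment.char = "")
  symbol <- .pick_col(tab, .hgnc_cols$symbol, "approved symbol")
  alias <- .split_list_col(.pick_col(tab, .hgnc_cols$alias_symbol, "alias symbols"))
  prev <- .split_list_col(.pick_col(tab, .hgnc_cols$prev_symbol, "previous symbols"))
  gene_id <- suppressWarnings(as.integer(.pick_col(tab, .hgnc_cols$ncbi_gene_id,
                                                   "NCBI Gene ID")))
  keep <- !is.na(gene_id) & gene_id > 0 & nzchar(symbol)
  symbol <- symbol[keep]; alias <- alias[keep]; prev <- prev[keep]
  gene_id <- gene_id[keep]

  mk <- function(variants, official, ids, source) {
    v <- normalize_characters(variants)
    ok <- nzchar(v)
    data.frame(variant = v[ok], official_symbol = official[ok],
               gene_id = ids[ok], source = rep(source, sum(ok)),
               stringsAsFactors = FALSE)
  }
  cur <- mk(symbol, symbol, gene_id, "hgnc_current")
  ali <- mk(unlist(alias, use.names = FALSE),
            rep(symbol, lengths(alias)), rep(gene_id, lengths(alias)),
            "hgnc_alias")
  prv <- mk(unlist(prev, use.names = FALSE),
            rep(symbol, lengths(prev)), rep(gene_id, lengths(prev)),
            "hgnc_previous")
  entries <- rbind(cur, ali, prv)

  if (!is.null(bioentities_table)) {
    be <- utils::read.csv(bioentities_table, header = FALSE, quote = "\"",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    if (nrow(be) > 0 && ncol(be) >= 2) {
      sym2id <- stats::setNames(gene_id, symbol)
      rows <- lapply(seq_len(nrow(be)), function(i) {
        name <- be[i, 1]
        targets <- unlist(be[i, -1], use.names = FALSE)
        targets <- targets[!is.na(targets) & nzchar(targets)]
        known <- targets %in% names(sym2id)
        if (any(!known)) {
          warning("bioentities name '", name, "' maps to unknown symbol(s): ",
                  paste(targets[!known], collapse = ", "), call. = FALSE)
        }
        targets <- targets[known]
        if (length(targets) == 0) return(NULL)
        mk(rep(name, length(targets)), targets,
           unname(sym2id[targets]), "bioentities")
      })
      entries <- rbind(entries, do.call(rbind, rows))
    }
  }

  if (!is.null(stoplist) && length(stoplist) > 0) {
    stopv <- normalize_characters(stoplist)
    entries <- entries[!(entries$variant %in% stopv), , drop = FALSE]
  }
  entries <- unique(entries)
  entries$source <- factor(entries$source, levels = PF_TIERS)
  entries <- entries[order(entries$variant, entries$source, entries$gene_id), ,
                     drop = FALSE]
  rownames(entries) <- NULL

  index <- new.env(parent = emptyenv(), size = nrow(entries))
  sp <- split(seq_len(nrow(entries)), entries$variant)
  for (v in names(sp)) assign(v, sp[[v]], envir = index)

  structure(list(entries = entries, tier_order = PF_TIERS, index = index),
            class = "pf_lexicon")
}

#' Look up a normalized variant
#'
#' @param lex A [build_lexicon()] result.
#' @param variant A normalized symbol string.
#' @return Data frame of matching entries ordered by tier (current first),
#'   zero rows if no match.
#' @export
lookup <- function(lex, variant) {
  stopifnot(inherits(lex, "pf_lexicon"))
  if (length(variant) != 1 || is.na(variant) || !nzchar(variant)) {
    return(lex$entries[0, , drop = FALSE])
  }
  idx <- get0(variant, envir = lex$index, inherits = FALSE)
  if (is.null(idx)) return(lex$entries[0, , drop = FALSE])
  lex$entries[idx, , drop = FALSE]
}

#' @export
print.pf_lexicon <- function(x, ...) {
  cat("pathfigr lexicon:", nrow(x$entries), "entries,",
      length(ls(x$index)), "distinct variants\n")
  print(table(x$entries$source))
  invisible(x)
}
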
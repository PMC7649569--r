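# Overrepresentation analysis of figure gene sets against annotation
# collections (disease-term channels, GO BP, pathway databases), with the
# term-size filter and the greedy top-term deduplication used for
# corpus-level disease summaries.

#' Build an annotation collection
#'
#' @param terms Named list of gene-ID vectors (term_id -> members).
#' @param labels Optional named character vector of human-readable labels
#'   (defaults to the term_ids).
#' @param universe Optional gene universe; defaults to the union of all
#'   term members.
#' @param name Collection name.
#' @return A `pf_collection` object.
#' @export
annotation_collection <- function(terms, labels = NULL, universe = NULL,
                                  name = "collection") {
  stopifnot(is.list(terms), !is.null(names(terms)))
  terms <- lapply(terms, function(g) sort(unique(g)))
  if (is.null(universe)) universe <- sort(unique(unlist(terms, use.names = FALSE)))
  if (is.null(labels)) labels <- stats::setNames(names(terms), names(terms))
  bad <- names(terms)[!vapply(terms, function(g) all(g %in% universe), logical(1))]
  if (length(bad) > 0) stop("term members outside universe: ", bad[1])
  structure(list(name = name, terms = terms, labels = labels,
                 universe = universe),
            class = "pf_collection")
}

#' Read an annotation collection from GMT or 3-column TSV
#'
#' The TSV form is `term_id`, `term_label`, `gene_id` (one association per
#' row), as disease-annotation channels commonly ship.
#'
#' @param file Path to a `.gmt` file or association TSV.
#' @param name Collection name (defaults to the file stem).
#' @return A `pf_collection`.
#' @export
read_collection <- function(file, name = tools::file_path_sans_ext(basename(file))) {
  if (grepl("\\.gmt$", file, ignore.case = TRUE)) {
    sets <- read_gmt(file)
    return(annotation_collection(sets, labels = attr(sets, "descriptions"),
                                 name = name))
  }
  tab <- utils::read.delim(file, sep = "\t", quote = "", comment.char = "",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(tab) < 3) stop("association TSV needs term_id, term_label, gene_id")
  names(tab)[1:3] <- c("term_id", "term_label", "gene_id")
  terms <- split(tab$gene_id, tab$term_id)
  labels <- vapply(split(tab$term_label, tab$term_id), `[`, character(1), 1)
  annotation_collection(terms, labels = labels, name = name)
}

#' Drop terms with too few gene associations
#'
#' Small terms produce unstable enrichment; a common choice is to require
#' at least 7 associated genes. The universe is left unchanged.
#'
#' @param coll A `pf_collection`.
#' @param min_genes Minimum term size (inclusive).
#' @return Filtered `pf_collection`.
#' @export
filter_collection <- function(coll, min_genes) {
  stopifnot(inherits(coll, "pf_collection"), min_genes >= 1)
  keep <- lengths(coll$terms) >= min_genes
  structure(list(name = coll$name, terms = coll$terms[keep],
                 labels = coll$labels[names(coll$terms)[keep]],
                 universe = coll$universe),
            class = "pf_collection")
}

#' One-sided hypergeometric overrepresentation test
#'
#' Upper-tail probability `P(X >= k)` (k included) for the overlap between a
#' query set and a term within a finite universe — the Fisher exact test's
#' one-sided form.
#'
#' @param query,term Gene-ID vectors, both subsets of `universe`.
#' @param universe Gene universe.
#' @return The p-value.
#' @examples
#' hypergeometric_test(c(1, 2), c(1, 2), universe = 1:4)  # 1/6
#' @export
hypergeometric_test <- function(query, term, universe) {
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query); term <- unique(term); universe <- unique(universe)
  stopifnot(all(query %in% universe), all(term %in% universe))
  k <- length(intersect(query, term))
  K <- length(term)
  n <- length(query)
  N <- length(universe)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Annotate gene sets by overrepresentation
#'
#' Tests every term against every set; p-values are Benjamini-Hochberg
#' adjusted within each set across terms. Query genes outside the universe
#' are ignored (standard ORA behaviour).
#'
#' @param sets A `pf_gene_sets` data frame.
#' @param coll A `pf_collection`.
#' @param alpha FDR significance threshold (default 0.05).
#' @param universe Optional override of the collection universe (e.g. the
#'   full set of genes the recognizer can emit).
#' @return List with `results` (significant tests only: set_id, term_id,
#'   term_label, k, K, n, N, p_value, fdr) and `top_terms` (one row per set
#'   with >= 1 significant term: smallest FDR, ties broken by larger
#'   overlap then term_id).
#' @export
annotate_sets <- function(sets, coll, alpha = 0.05, universe = NULL) {
  stopifnot(inherits(coll, "pf_collection"), alpha > 0, alpha < 1)
  if (is.null(universe)) universe <- coll$universe
  N <- length(universe)
  term_ids <- names(coll$terms)
  term_sizes <- lengths(lapply(coll$terms, function(g) intersect(g, universe)))
  res <- vector("list", nrow(sets))
  for (i in seq_len(nrow(sets))) {
    q <- intersect(sets$genes[[i]], universe)
    if (length(q) == 0) next
    k <- vapply(coll$terms, function(g) length(intersect(q, g)), integer(1))
    p <- stats::phyper(k - 1, term_sizes, N - term_sizes, length(q),
                       lower.tail = FALSE)
    fdr <- stats::p.adjust(p, method = "BH")
    keep <- which(fdr < alpha)
    if (length(keep) == 0) next
    res[[i]] <- data.frame(
      set_id = sets$figure_id[i], term_id = term_ids[keep],
      term_label = unname(coll$labels[term_ids[keep]]),
      k = unname(k[keep]), K = unname(term_sizes[keep]),
      n = length(q), N = N, p_value = unname(p[keep]),
      fdr = unname(fdr[keep]), stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  if (is.null(results)) {
    results <- data.frame(set_id = character(0), term_id = character(0),
                          term_label = character(0), k = integer(0),
                          K = integer(0), n = integer(0), N = integer(0),
                          p_value = numeric(0), fdr = numeric(0),
                          stringsAsFactors = FALSE)
  }
  rownames(results) <- NULL
  top <- do.call(rbind, lapply(split(results, results$set_id), function(r) {
    r <- r[order(r$fdr, -r$k, r$term_id), , drop = FALSE]
    r[1, , drop = FALSE]
  }))
  if (is.null(top)) top <- results[0, , drop = FALSE]
  rownames(top) <- NULL
  list(results = results, top_terms = top)
}

# merge singular/plural term labels: when both "TUMOR" and "TUMORS" occur,
# the plural is relabelled to the singular form
.merge_plurals <- function(labels) {
  u <- unique(labels)
  upper <- toupper(u)
  singular <- sub("S$", "", upper)
  for (i in seq_along(u)) {
    if (endsWith(upper[i], "S") && singular[i] %in% upper) {
      labels[labels == u[i]] <- u[match(singular[i], upper)]
    }
  }
  labels
}

#' Rank top terms with exclusive item counts
#'
#' Greedy deduplication of per-item term assignments: singular and plural
#' forms of a label are merged, then the term covering the most
#' not-yet-counted items is picked repeatedly (ties broken alphabetically);
#' its items are removed before the next pick. After `top_n` picks the
#' remaining items are counted as `"Other"`.
#'
#' @param assignments Data frame with columns `item_id`, `term_label` (one
#'   row per item-term association; items may carry several terms).
#' @param top_n Number of ranked terms to report (default 10).
#' @return Data frame `term_label`, `n_items` in pick order, with an
#'   `"other"` attribute counting leftover items.
#' @export
dedup_top_terms <- function(assignments, top_n = 10L) {
  stopifnot(all(c("item_id", "term_label") %in% names(assignments)))
  a <- assignments
  a$term_label <- .merge_plurals(a$term_label)
  a <- unique(a[, c("item_id", "term_label")])
  remaining <- unique(a$item_id)
  picks <- character(0); counts <- integer(0)
  while (length(picks) < top_n && length(remaining) > 0) {
    live <- a[a$item_id %in% remaining, , drop = FALSE]
    if (nrow(live) == 0) break
    tab <- table(live$term_label)
    best <- sort(names(tab)[tab == max(tab)])[1]
    covered <- unique(live$item_id[live$term_label == best])
    picks <- c(picks, best)
    counts <- c(counts, length(covered))
    remaining <- setdiff(remaining, covered)
  }
  out <- data.frame(term_label = picks, n_items = counts,
                    stringsAsFactors = FALSE)
  attr(out, "other") <- length(intersect(remaining, unique(a$item_id)))
  out
}
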
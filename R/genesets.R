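# Per-figure gene sets and set-level analytics: size filtering, duplicate
# and containment detection, Jaccard / directional-overlap matrices, and
# hierarchical clustering for heatmap-style corpus views.

#' Build per-figure gene sets from a hit table
#'
#' One set per figure with at least one hit; genes are deduplicated NCBI
#' Gene IDs (unique-gene semantics, in contrast to the instance-level hit
#' table).
#'
#' @param hits Hit table from [recognize_corpus()].
#' @param metadata Optional data frame keyed by `figure_id` with columns
#'   such as `pmcid`, `year`, `figure_title`.
#' @return Data frame of class `pf_gene_sets`: figure_id, pmcid, year,
#'   n_genes, and a `genes` list-column of sorted gene ID vectors.
#' @export
build_sets <- function(hits, metadata = NULL) {
  if (nrow(hits) == 0) {
    out <- data.frame(figure_id = character(0), pmcid = character(0),
                      year = integer(0), n_genes = integer(0),
                      stringsAsFactors = FALSE)
    out$genes <- list()
    class(out) <- c("pf_gene_sets", "data.frame")
    return(out)
  }
  genes <- lapply(split(hits$gene_id, hits$figure_id),
                  function(g) sort(unique(g)))
  out <- data.frame(figure_id = names(genes), stringsAsFactors = FALSE)
  pmcid <- if ("pmcid" %in% names(hits)) {
    vapply(split(as.character(hits$pmcid), hits$figure_id),
           function(p) p[1], character(1))
  } else rep(NA_character_, nrow(out))
  out$pmcid <- unname(pmcid[out$figure_id])
  out$year <- NA_integer_
  if (!is.null(metadata)) {
    missing_meta <- setdiff(out$figure_id, metadata$figure_id)
    if (length(missing_meta) > 0) {
      warning("no metadata for ", length(missing_meta), " figure(s): ",
              paste(utils::head(missing_meta, 5), collapse = ", "),
              call. = FALSE)
    }
    m <- match(out$figure_id, metadata$figure_id)
    for (col in setdiff(names(metadata), "figure_id")) {
      vals <- metadata[[col]][m]
      if (col %in% c("pmcid", "year")) {
        out[[col]] <- ifelse(is.na(vals), out[[col]], vals)
      } else {
        out[[col]] <- vals
      }
    }
  }
  out$n_genes <- lengths(genes)[out$figure_id]
  out$genes <- genes[out$figure_id]
  rownames(out) <- NULL
  class(out) <- c("pf_gene_sets", "data.frame")
  out
}

#' Filter gene sets by minimum size
#'
#' The threshold is inclusive ("at least"); typical cutoffs are 7 distinct
#' genes for annotation coverage and 10 for enrichment-analysis use.
#'
#' @param sets A `pf_gene_sets` data frame.
#' @param min_genes Minimum number of distinct genes (>= 1).
#' @return Subset of `sets`, order preserved.
#' @export
filter_by_size <- function(sets, min_genes) {
  stopifnot(min_genes >= 1)
  sets[sets$n_genes >= min_genes, , drop = FALSE]
}

#' Find figures with identical gene content
#'
#' @param sets A `pf_gene_sets` data frame.
#' @return List of character vectors of figure_ids, one per group of size
#'   >= 2 sharing the exact same gene set; empty list if none.
#' @export
find_duplicates <- function(sets) {
  if (nrow(sets) == 0) return(list())
  key <- vapply(sets$genes, function(g) paste(g, collapse = ","), character(1))
  groups <- split(sets$figure_id, key)
  unname(groups[lengths(groups) >= 2])
}

#' Find strictly contained gene sets
#'
#' A figure is contained when its gene set is a strict subset of another
#' figure's set; exact duplicates are reported by [find_duplicates()]
#' instead, keeping the two categories disjoint.
#'
#' @param sets A `pf_gene_sets` data frame.
#' @return Data frame with columns `inner`, `outer` (figure_ids).
#' @export
find_contained <- function(sets) {
  n <- nrow(sets)
  inner <- character(0); outer <- character(0)
  if (n >= 2) {
    gs <- sets$genes
    sizes <- sets$n_genes
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || sizes[i] >= sizes[j]) next
        if (all(gs[[i]] %in% gs[[j]])) {
          inner <- c(inner, sets$figure_id[i])
          outer <- c(outer, sets$figure_id[j])
        }
      }
    }
  }
  data.frame(inner = inner, outer = outer, stringsAsFactors = FALSE)
}

#' Pairwise Jaccard and directional overlap matrices
#'
#' Jaccard is intersection over union (symmetric); overlap is intersection
#' over the row set's size, so `overlap[i, j] == 1` whenever set i is a
#' subset of set j.
#'
#' @param sets A `pf_gene_sets` data frame; all sets must be non-empty.
#' @return A `pf_overlap` object: `ids`, `jaccard`, `overlap`.
#' @export
overlap_matrix <- function(sets) {
  if (any(sets$n_genes == 0)) stop("empty gene set in overlap_matrix input")
  ids <- sets$figure_id
  all_genes <- sort(unique(unlist(sets$genes, use.names = FALSE)))
  inc <- vapply(sets$genes, function(g) all_genes %in% g,
                logical(length(all_genes)))
  inc <- matrix(as.numeric(inc), nrow = length(all_genes),
                dimnames = list(NULL, ids))
  inter <- crossprod(inc)
  sizes <- sets$n_genes
  uni <- outer(sizes, sizes, "+") - inter
  jac <- inter / uni
  ovl <- inter / sizes   # divides each row i by |genes_i|
  dimnames(jac) <- dimnames(ovl) <- list(ids, ids)
  structure(list(ids = ids, jaccard = jac, overlap = ovl),
            class = "pf_overlap")
}

#' Hierarchically cluster gene sets
#'
#' Agglomerative clustering on `1 - similarity`; defaults to Jaccard
#' distance with average linkage. The leaf order is what a heatmap view of
#' the corpus uses.
#'
#' @param m A [overlap_matrix()] result.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @param distance `"jaccard_distance"` (symmetric, default) or
#'   `"overlap_distance"` (symmetrized as 1 - max(overlap_ij, overlap_ji)).
#' @return List with the `hclust` object and `leaf_order` (figure_ids).
#' @export
cluster_sets <- function(m, linkage = "average",
                         distance = c("jaccard_distance", "overlap_distance")) {
  stopifnot(inherits(m, "pf_overlap"))
  distance <- match.arg(distance)
  if (length(m$ids) < 2) stop("need at least 2 sets to cluster")
  sim <- if (distance == "jaccard_distance") m$jaccard else pmax(m$overlap, t(m$overlap))
  h <- stats::hclust(stats::as.dist(1 - sim), method = linkage)
  list(hclust = h, leaf_order = m$ids[h$order])
}

#' Export a dendrogram as Newick
#'
#' @param clust A [cluster_sets()] result.
#' @param file Output path.
#' @export
write_dendrogram_newick <- function(clust, file) {
  ape::write.tree(ape::as.phylo(clust$hclust), file = file)
  invisible(file)
}

#' Write similarity matrices as TSV
#'
#' @param m A [overlap_matrix()] result.
#' @param file Output path.
#' @param which `"jaccard"` or `"overlap"`.
#' @export
write_overlap_tsv <- function(m, file, which = c("jaccard", "overlap")) {
  which <- match.arg(which)
  mat <- m[[which]]
  utils::write.table(cbind(figure_id = rownames(mat), as.data.frame(mat)),
                     file, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}

#' Write gene sets in GMT format
#'
#' Set names are `<pmcid>__<figure_id>` so enrichment tools get unique,
#' traceable identifiers; the description column carries the figure title
#' when available.
#'
#' @param sets A `pf_gene_sets` data frame.
#' @param file Output path.
#' @param symbols Optional named vector `gene_id -> symbol`; if supplied,
#'   members are written as symbols instead of NCBI integers.
#' @export
write_gmt <- function(sets, file, symbols = NULL) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    name <- if (!is.na(sets$pmcid[i])) {
      paste0(sets$pmcid[i], "__", sets$figure_id[i])
    } else sets$figure_id[i]
    desc <- if ("figure_title" %in% names(sets) && !is.na(sets$figure_title[i])) {
      sets$figure_title[i]
    } else sets$figure_id[i]
    members <- sets$genes[[i]]
    if (!is.null(symbols)) members <- unname(symbols[as.character(members)])
    paste(c(name, desc, members), collapse = "\t")
  }, character(1))
  writeLines(lines, file, useBytes = TRUE)
  invisible(file)
}

#' Read a GMT file
#'
#' @param file GMT path (tab-separated: name, description, members...).
#' @return Named list of member vectors; the `"descriptions"` attribute
#'   carries the second column.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad) > 0) {
    stop("malformed GMT line ", bad[1], " in ", file,
         " (need name, description, >=1 member)")
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[`, character(1), 2), names(sets))
  sets
}
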
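# Corpus-level summaries: gene counts per figure, figure-vs-text overlap,
# database novelty, classifier evaluation metrics, binomial proportion
# intervals, and first-appearance year spans.

#' Summarize a recognized corpus
#'
#' @param sets A `pf_gene_sets` data frame (one row per gene-containing
#'   figure).
#' @param hits Hit table (instance level).
#' @param n_figures_total Total figures processed, including those with no
#'   recognized gene; defaults to the number of sets.
#' @param mode `"instances"` (default) averages recognized instances over
#'   gene-containing figures; `"unique"` averages distinct genes per figure.
#' @return A `pf_corpus_summary` list: n_figures_total,
#'   n_figures_with_genes, total_instances, n_unique_genes,
#'   mean_genes_per_figure, per_gene_figure_counts.
#' @export
summarize_corpus <- function(sets, hits, n_figures_total = nrow(sets),
                             mode = c("instances", "unique")) {
  mode <- match.arg(mode)
  n_with <- nrow(sets)
  total_instances <- nrow(hits)
  uniq <- sort(unique(unlist(sets$genes, use.names = FALSE)))
  mean_gpf <- if (n_with == 0) {
    NA_real_
  } else if (mode == "instances") {
    total_instances / n_with
  } else {
    mean(sets$n_genes)
  }
  per_gene <- if (n_with == 0) integer(0) else {
    table(unlist(lapply(sets$genes, unique), use.names = FALSE))
  }
  structure(list(n_figures_total = n_figures_total,
                 n_figures_with_genes = n_with,
                 total_instances = total_instances,
                 n_unique_genes = length(uniq),
                 mean_genes_per_figure = mean_gpf,
                 per_gene_figure_counts = per_gene),
            class = "pf_corpus_summary")
}

#' @export
print.pf_corpus_summary <- function(x, ...) {
  cat("figures:", x$n_figures_with_genes, "with genes /", x$n_figures_total,
      "total\ninstances:", x$total_instances,
      "| unique genes:", x$n_unique_genes,
      "| mean genes/figure:", round(x$mean_genes_per_figure, 1), "\n")
  invisible(x)
}

#' Compare figure-derived and text-derived gene content per paper
#'
#' Assigns each (paper, gene) pair to `figure_only`, `text_only` or `both`,
#' and tallies corpus-level unique genes per category — the comparison a
#' text-mining gene-paper table (e.g. PubTator-style) supports.
#'
#' @param figure_table Data frame `paper_id`, `gene_id` from figure sets.
#' @param text_table Data frame `paper_id`, `gene_id` from text mining.
#' @return List with `per_gene` (gene_id, n_papers_figure_only,
#'   n_papers_text_only, n_papers_both) and `totals` (unique genes per
#'   category across the corpus).
#' @export
compare_figure_vs_text <- function(figure_table, text_table) {
  fig <- unique(figure_table[, c("paper_id", "gene_id")])
  txt <- unique(text_table[, c("paper_id", "gene_id")])
  fig_key <- paste(fig$paper_id, fig$gene_id)
  txt_key <- paste(txt$paper_id, txt$gene_id)
  both_key <- intersect(fig_key, txt_key)
  cat_of <- function(keys, category) {
    if (length(keys) == 0) {
      return(data.frame(gene_id = integer(0), category = character(0)))
    }
    parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
    data.frame(gene_id = as.integer(parts[, 2]), category = category,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(cat_of(setdiff(fig_key, txt_key), "figure_only"),
               cat_of(setdiff(txt_key, fig_key), "text_only"),
               cat_of(both_key, "both"))
  per_gene <- do.call(rbind, lapply(split(tab, tab$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1],
               n_papers_figure_only = sum(g$category == "figure_only"),
               n_papers_text_only = sum(g$category == "text_only"),
               n_papers_both = sum(g$category == "both"))
  }))
  rownames(per_gene) <- NULL
  fig_genes <- unique(fig$gene_id)
  txt_genes <- unique(txt$gene_id)
  totals <- c(figure_only = length(setdiff(fig_genes, txt_genes)),
              text_only = length(setdiff(txt_genes, fig_genes)),
              both = length(intersect(fig_genes, txt_genes)))
  list(per_gene = per_gene, totals = totals)
}

#' Genes absent from reference pathway databases
#'
#' @param unique_genes Vector of gene IDs recognized in the corpus.
#' @param db_collections List of gene-ID vectors (or GMT-style named lists
#'   of sets), e.g. pathway database collections.
#' @return List: `n_covered`, `n_novel`, `novel` (the gene IDs found in no
#'   collection).
#' @export
novel_vs_databases <- function(unique_genes, db_collections) {
  genes <- unique(unique_genes)
  covered_pool <- unique(unlist(db_collections, use.names = FALSE))
  novel <- sort(setdiff(genes, covered_pool))
  list(n_covered = length(genes) - length(novel),
       n_novel = length(novel), novel = novel)
}

#' Binary classifier evaluation metrics
#'
#' Precision, recall and the Matthews correlation coefficient from gold
#' labels and predictions. Metrics with an undefined denominator are
#' returned as `NA` (flagged, never silently zero); MCC with a zero
#' denominator is 0 by the usual convention only when the confusion matrix
#' is degenerate in one margin.
#'
#' @param labels,predictions Equal-length logical (or 0/1) vectors.
#' @return A `pf_classifier_metrics` list: tp, fp, tn, fn, precision,
#'   recall, mcc.
#' @export
classifier_metrics <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions differ in length")
  }
  y <- as.logical(labels); p <- as.logical(predictions)
  stopifnot(!anyNA(y), !anyNA(p))
  tp <- sum(y & p); fp <- sum(!y & p); tn <- sum(!y & !p); fn <- sum(y & !p)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = precision, recall = recall, mcc = mcc),
            class = "pf_classifier_metrics")
}

#' Binomial proportion confidence-interval half-width
#'
#' Wald normal approximation by default (half-width
#' `z * sqrt(p(1-p)/n)`); Wilson is available for small samples or extreme
#' proportions.
#'
#' @param p_hat Observed proportion in `[0, 1]`.
#' @param n Sample size (>= 1).
#' @param confidence Confidence level in (0, 1), e.g. 0.97.
#' @param method `"wald"` (default) or `"wilson"`.
#' @return The half-width of the interval, on the proportion scale.
#' @examples
#' proportion_ci(0.94, 300, 0.97)  # about 0.03
#' @export
proportion_ci <- function(p_hat, n, confidence = 0.95,
                          method = c("wald", "wilson")) {
  method <- match.arg(method)
  stopifnot(p_hat >= 0, p_hat <= 1, n >= 1, confidence > 0, confidence < 1)
  z <- stats::qnorm((1 + confidence) / 2)
  if (method == "wald") {
    z * sqrt(p_hat * (1 - p_hat) / n)
  } else {
    centre_adj <- (p_hat + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    # half-width around the Wilson centre; centre shift is part of the
    # interval, so report (upper - lower) / 2
    (min(1, centre_adj + half) - max(0, centre_adj - half)) / 2
  }
}

#' First-appearance spans between a gene event and its first figure
#'
#' For each gene, the span is the year it first appears in a figure minus
#' a user-supplied event year (e.g. initial cloning). Genes absent from the
#' event table are excluded; negative spans are kept and flagged.
#'
#' @param sets A `pf_gene_sets` data frame with `year` populated.
#' @param event_table Data frame `gene_id`, `year`.
#' @return List with `spans` (gene_id, first_figure_year, event_year, span,
#'   negative flag) and `median_span`.
#' @export
first_appearance_spans <- function(sets, event_table) {
  stopifnot(all(c("gene_id", "year") %in% names(event_table)))
  with_year <- sets[!is.na(sets$year), , drop = FALSE]
  if (nrow(with_year) == 0) {
    return(list(spans = data.frame(gene_id = integer(0),
                                   first_figure_year = integer(0),
                                   event_year = integer(0), span = integer(0),
                                   negative = logical(0)),
                median_span = NA_real_))
  }
  long <- data.frame(
    gene_id = unlist(with_year$genes, use.names = FALSE),
    year = rep(with_year$year, with_year$n_genes))
  first_year <- vapply(split(long$year, long$gene_id), min, numeric(1))
  genes <- as.integer(names(first_year))
  m <- match(genes, event_table$gene_id)
  keep <- !is.na(m)
  spans <- data.frame(gene_id = genes[keep],
                      first_figure_year = as.integer(unname(first_year[keep])),
                      event_year = as.integer(event_table$year[m[keep]]))
  spans$span <- spans$first_figure_year - spans$event_year
  spans$negative <- spans$span < 0
  list(spans = spans, median_span = stats::median(spans$span))
}
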
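test_that("corpus summary means follow the instance and unique modes", {
  hits <- data.frame(figure_id = c(rep("F1", 3), rep("F2", 5)),
                     gene_id = c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 6L),
                     stringsAsFactors = FALSE)
  sets <- build_sets(hits)
  s <- summarize_corpus(sets, hits)
  expect_equal(s$mean_genes_per_figure, 4.0)          # 8 instances / 2 figures
  expect_equal(s$total_instances, 8L)
  expect_equal(s$n_unique_genes, 6L)
  su <- summarize_corpus(sets, hits, mode = "unique")
  expect_equal(su$mean_genes_per_figure, 3.0)         # (2 + 4) / 2
  s0 <- summarize_corpus(build_sets(hits[0, ]), hits[0, ])
  expect_true(is.na(s0$mean_genes_per_figure))
  # 1-decimal display rounding of the instance ratio is half-even
  expect_equal(round(s$mean_genes_per_figure, 1),
               round(8 / 2, 1))
})

test_that("figure-vs-text comparison matches a brute-force join", {
  fig <- data.frame(paper_id = c("p1", "p1", "p2", "p3"),
                    gene_id = c(10L, 20L, 10L, 30L))
  txt <- data.frame(paper_id = c("p1", "p2", "p2"),
                    gene_id = c(10L, 40L, 10L))
  cmp <- compare_figure_vs_text(fig, txt)
  expect_equal(unname(cmp$totals["both"]), 1L)          # gene 10
  expect_equal(unname(cmp$totals["figure_only"]), 2L)   # 20, 30
  expect_equal(unname(cmp$totals["text_only"]), 1L)     # 40
  g10 <- cmp$per_gene[cmp$per_gene$gene_id == 10, ]
  expect_equal(g10$n_papers_both, 2L)                   # p1 and p2
  expect_equal(g10$n_papers_figure_only, 0L)
  g20 <- cmp$per_gene[cmp$per_gene$gene_id == 20, ]
  expect_equal(g20$n_papers_figure_only, 1L)

  # brute-force oracle over random tables
  set.seed(31)
  figr <- unique(data.frame(paper_id = sample(paste0("p", 1:8), 40, TRUE),
                            gene_id = sample(1:12, 40, TRUE)))
  txtr <- unique(data.frame(paper_id = sample(paste0("p", 1:8), 40, TRUE),
                            gene_id = sample(1:12, 40, TRUE)))
  got <- compare_figure_vs_text(figr, txtr)
  fk <- paste(figr$paper_id, figr$gene_id)
  tk <- paste(txtr$paper_id, txtr$gene_id)
  expect_equal(sum(got$per_gene$n_papers_both), length(intersect(fk, tk)))
  expect_equal(sum(got$per_gene$n_papers_figure_only), length(setdiff(fk, tk)))
  expect_equal(sum(got$per_gene$n_papers_text_only), length(setdiff(tk, fk)))
})

test_that("database novelty is a set difference over all collections", {
  dbs <- list(wp = list(s1 = 1:5, s2 = 4:8), re = list(s3 = 7:10))
  out <- novel_vs_databases(c(1L, 6L, 11L, 12L), dbs)
  expect_equal(out$n_covered, 2L)
  expect_equal(out$novel, c(11L, 12L))
  expect_equal(novel_vs_databases(1:3, list(a = 1:10))$n_novel, 0L)
  all_novel <- novel_vs_databases(1:3, list())
  expect_equal(all_novel$n_novel, 3L)
})

test_that("classifier metrics reproduce the standard formulas", {
  perfect <- classifier_metrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$mcc, 1)

  # balanced gold, all-positive predictions: degenerate column, MCC 0
  degen <- classifier_metrics(c(TRUE, TRUE, FALSE, FALSE), rep(TRUE, 4))
  expect_equal(degen$mcc, 0)

  # tp=9 fp=1 fn=1 tn=9
  y <- c(rep(TRUE, 10), rep(FALSE, 10))
  p <- c(rep(TRUE, 9), FALSE, TRUE, rep(FALSE, 9))
  m <- classifier_metrics(y, p)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$mcc, 0.8)

  expect_error(classifier_metrics(c(TRUE, FALSE), TRUE), "differ in length")
  # undefined precision is flagged, not zero
  nopos <- classifier_metrics(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_true(is.na(nopos$precision))
})

test_that("classifier metrics agree with a naive confusion recount on random vectors", {
  set.seed(17)
  for (i in 1:20) {
    y <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    p <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    m <- classifier_metrics(y, p)
    tp <- sum(y == TRUE & p == TRUE); fp <- sum(!y & p)
    tn <- sum(!y & !p); fn <- sum(y & !p)
    expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(tp, fp, tn, fn))
    num <- tp * tn - fp * fn
    den <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
    if (den > 0) expect_equal(m$mcc, num / den)
  }
})

test_that("Wald half-width matches the closed form and its monotonicities", {
  expect_equal(proportion_ci(0.5, 100, 0.95),
               stats::qnorm(0.975) * sqrt(0.25 / 100))
  expect_equal(round(proportion_ci(0.5, 100, 0.95), 3), 0.098)
  expect_equal(proportion_ci(0, 50, 0.95), 0)
  expect_equal(proportion_ci(1, 50, 0.95), 0)
  # wider at higher confidence, narrower with more samples
  expect_gt(proportion_ci(0.3, 80, 0.99), proportion_ci(0.3, 80, 0.9))
  expect_lt(proportion_ci(0.3, 800, 0.95), proportion_ci(0.3, 80, 0.95))
  # Wilson stays inside [0, 1] and close to Wald at large n
  expect_lt(abs(proportion_ci(0.5, 1000, 0.95, "wilson") -
                proportion_ci(0.5, 1000, 0.95)), 1e-3)
})

test_that("first-appearance spans use the earliest figure year per gene", {
  sets <- random_sets(3, pool = 1:10, max_size = 3, seed = 3)
  sets$genes <- list(c(1L, 2L), c(2L, 3L), 4L)
  sets$n_genes <- lengths(sets$genes)
  sets$year <- c(2007L, 2003L, 2010L)
  events <- data.frame(gene_id = c(1L, 2L, 3L), year = c(1995L, 2000L, 2005L))
  out <- first_appearance_spans(sets, events)
  expect_equal(out$spans$span[out$spans$gene_id == 1], 12L)   # 2007 - 1995
  expect_equal(out$spans$span[out$spans$gene_id == 2], 3L)    # min(2007, 2003)
  expect_equal(out$spans$span[out$spans$gene_id == 3], -2L)   # negative kept
  expect_true(out$spans$negative[out$spans$gene_id == 3])
  expect_false(4 %in% out$spans$gene_id)                      # no event year
  expect_equal(out$median_span, 3)
  # explicit tiny-median check
  sets$genes <- list(1L, 2L, 3L)
  sets$n_genes <- c(1L, 1L, 1L)
  sets$year <- c(1996L, 2002L, 2008L)
  out2 <- first_appearance_spans(sets, events)
  expect_equal(sort(out2$spans$span), c(1L, 2L, 3L))
  expect_equal(out2$median_span, 2)
})
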
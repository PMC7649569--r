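mk_sets <- function(lst) {
  out <- data.frame(figure_id = names(lst), pmcid = NA_character_,
                    year = NA_integer_, n_genes = lengths(lst),
                    stringsAsFactors = FALSE)
  out$genes <- lapply(unname(lst), function(g) sort(unique(g)))
  class(out) <- c("pf_gene_sets", "data.frame")
  out
}

test_that("set construction deduplicates instances per figure", {
  hits <- data.frame(figure_id = c("F1", "F1", "F1"), pmcid = "PMC1",
                     word_index = 1:3, raw_word = c("TP53", "TP53", "AKT1"),
                     matched_variant = c("TP53", "TP53", "AKT1"),
                     official_symbol = c("TP53", "TP53", "AKT1"),
                     gene_id = c(7157L, 7157L, 207L),
                     source = "hgnc_current", stringsAsFactors = FALSE)
  sets <- build_sets(hits)
  expect_equal(sets$n_genes, 2L)
  expect_equal(sets$genes[[1]], c(207L, 7157L))
  expect_equal(nrow(build_sets(hits[0, ])), 0)
})

test_that("metadata joins by figure_id and warns when absent", {
  hits <- data.frame(figure_id = c("F1", "F2"), pmcid = NA_character_,
                     word_index = 1L, raw_word = "TP53",
                     matched_variant = "TP53", official_symbol = "TP53",
                     gene_id = 7157L, source = "hgnc_current",
                     stringsAsFactors = FALSE)
  meta <- data.frame(figure_id = "F1", pmcid = "PMC1", year = 2001L,
                     figure_title = "t", stringsAsFactors = FALSE)
  expect_warning(sets <- build_sets(hits, meta), "no metadata")
  expect_equal(sets$year[sets$figure_id == "F1"], 2001L)
  expect_true(is.na(sets$year[sets$figure_id == "F2"]))
})

test_that("size filtering is inclusive at the threshold", {
  sets <- mk_sets(list(a = 1:3, b = 1:7, c = 1:12))
  expect_equal(filter_by_size(sets, 7)$figure_id, c("b", "c"))
  expect_equal(filter_by_size(sets, 1)$figure_id, sets$figure_id)
  expect_error(filter_by_size(sets, 0))
})

test_that("duplicate and containment detection on hand-built sets", {
  sets <- mk_sets(list(F1 = c(1, 2), F2 = c(1, 2), F3 = 1))
  dup <- find_duplicates(sets)
  expect_length(dup, 1)
  expect_setequal(dup[[1]], c("F1", "F2"))
  expect_length(find_duplicates(mk_sets(list(a = 1, b = 2))), 0)

  cont <- find_contained(mk_sets(list(F1 = 1, F2 = c(1, 2))))
  expect_equal(cont$inner, "F1")
  expect_equal(cont$outer, "F2")
  # identical sets are duplicates, not containments (strictness)
  expect_equal(nrow(find_contained(sets[1:2, ])), 0)
})

test_that("duplicates and containment match the O(n^2) set oracle on 200 random sets", {
  sets <- random_sets(200, seed = 99)
  dup <- find_duplicates(sets)
  cont <- find_contained(sets)
  gs <- sets$genes
  ids <- sets$figure_id
  oracle_pairs <- data.frame(inner = character(0), outer = character(0))
  dup_flag <- matrix(FALSE, 200, 200)
  for (i in 1:200) {
    for (j in 1:200) {
      if (i == j) next
      if (identical(gs[[i]], gs[[j]])) dup_flag[i, j] <- TRUE
      if (length(gs[[i]]) < length(gs[[j]]) && all(gs[[i]] %in% gs[[j]])) {
        oracle_pairs <- rbind(oracle_pairs,
                              data.frame(inner = ids[i], outer = ids[j]))
      }
    }
  }
  got_pairs <- paste(cont$inner, cont$outer)
  want_pairs <- paste(oracle_pairs$inner, oracle_pairs$outer)
  expect_setequal(got_pairs, want_pairs)
  in_dup_group <- unique(unlist(dup))
  expect_setequal(in_dup_group, ids[apply(dup_flag, 1, any)])
  # a duplicated pair never appears in a containment direction
  for (g in dup) {
    combos <- expand.grid(g, g)
    expect_false(any(paste(combos[, 1], combos[, 2]) %in% got_pairs))
  }
})

test_that("jaccard and overlap follow their set formulas", {
  m <- overlap_matrix(mk_sets(list(X = c("A", "B", "C"), Y = c("B", "C", "D"))))
  expect_equal(m$jaccard["X", "Y"], 0.5)
  m2 <- overlap_matrix(mk_sets(list(S = c("A", "B"), L = c("A", "B", "C", "D"))))
  expect_equal(m2$overlap["S", "L"], 1.0)  # subset rows hit 1
  expect_equal(m2$overlap["L", "S"], 0.5)
  m3 <- overlap_matrix(mk_sets(list(a = 1:2, b = 3:4)))
  expect_equal(m3$jaccard["a", "b"], 0)
  expect_equal(m3$overlap["a", "b"], 0)
  expect_equal(unname(diag(m3$jaccard)), c(1, 1))
  expect_error(overlap_matrix(mk_sets(list(a = integer(0), b = 1))))
})

test_that("matrices agree with naive set arithmetic and the jaccard bound holds", {
  sets <- random_sets(60, seed = 5)
  m <- overlap_matrix(sets)
  gs <- sets$genes
  for (i in seq_len(60)) {
    for (j in seq_len(60)) {
      inter <- length(intersect(gs[[i]], gs[[j]]))
      expect_equal(m$jaccard[i, j], inter / length(union(gs[[i]], gs[[j]])))
      expect_equal(m$overlap[i, j], inter / length(gs[[i]]))
      expect_lte(m$jaccard[i, j],
                 min(m$overlap[i, j], m$overlap[j, i]) + 1e-12)
    }
  }
  expect_equal(m$jaccard, t(m$jaccard))
})

test_that("clustering merges identical sets at zero and obvious pairs first", {
  m <- overlap_matrix(mk_sets(list(a = 1:3, b = 1:3)))
  cl <- cluster_sets(m)
  expect_equal(cl$hclust$height, 0)

  m3 <- overlap_matrix(mk_sets(list(a = 1:4, b = 1:4, c = 20:24)))
  cl3 <- cluster_sets(m3)
  # first merge joins the identical pair a,b (leaves 1 and 2)
  expect_setequal(abs(cl3$hclust$merge[1, ]), c(1, 2))
  expect_error(cluster_sets(overlap_matrix(mk_sets(list(a = 1:2)))),
               "at least 2")
})

test_that("cutting the dendrogram matches connected components of the threshold graph", {
  sets <- random_sets(40, seed = 13)
  m <- overlap_matrix(sets)
  cl <- cluster_sets(m, linkage = "single")   # single linkage = components
  h <- 0.6
  grp <- stats::cutree(cl$hclust, h = h)
  adj <- (1 - m$jaccard) <= h
  reach <- adj
  for (k in 1:40) reach <- (reach %*% adj + reach) > 0   # transitive closure
  comp <- match(apply(reach, 1, paste, collapse = ""),
                unique(apply(reach, 1, paste, collapse = "")))
  expect_equal(length(unique(grp)), length(unique(comp)))
  expect_true(all(tapply(comp, grp, function(x) length(unique(x))) == 1))
})

test_that("GMT writes traceable names and reads back the same members", {
  sets <- mk_sets(list(figX = c(10, 20), figY = c(30, 40, 50)))
  sets$pmcid <- c("PMC1", "PMC2")
  sets$figure_title <- c("Title X", NA)
  path <- tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(names(back), c("PMC1__figX", "PMC2__figY"))
  expect_equal(back[["PMC1__figX"]], c("10", "20"))
  expect_equal(unname(attr(back, "descriptions")[1]), "Title X")
  bad <- tempfile(); writeLines("one\tcolumnpair", bad)
  expect_error(read_gmt(bad), "malformed GMT line 1")
})

test_that("dendrogram exports as parseable Newick with figure ids as tips", {
  sets <- random_sets(8, seed = 2)
  cl <- cluster_sets(overlap_matrix(sets))
  nwk <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(cl, nwk)
  tree <- ape::read.tree(nwk)
  expect_setequal(tree$tip.label, sets$figure_id)
})
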
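# Shared fixtures: the toy lexicon (with and without the amino-acid
# stoplist) and a default transform chain, built once per test run.

toy_paths <- toy_lexicon_files(file.path(tempdir(), "pf-toy-lexicon"))
toy_lex <- build_lexicon(toy_paths$hgnc, toy_paths$bioentities,
                         stoplist = default_stoplist())
toy_lex_nostop <- build_lexicon(toy_paths$hgnc, toy_paths$bioentities)
toy_chain <- pf_chain()

# write a minimal single-row HGNC fixture and return its path
write_hgnc_fixture <- function(rows, dir = tempfile("hgnc")) {
  dir.create(dir, showWarnings = FALSE)
  path <- file.path(dir, "hgnc.tsv")
  writeLines(c("symbol\talias_symbol\tprev_symbol\tncbi_gene_id", rows), path)
  path
}

# random gene sets for brute-force comparisons
random_sets <- function(n, pool = 1:40, min_size = 1, max_size = 8,
                        seed = 42) {
  set.seed(seed)
  genes <- lapply(seq_len(n), function(i) {
    sort(sample(pool, sample(min_size:max_size, 1)))
  })
  out <- data.frame(figure_id = sprintf("F%03d", seq_len(n)),
                    pmcid = NA_character_, year = NA_integer_,
                    n_genes = lengths(genes), stringsAsFactors = FALSE)
  out$genes <- genes
  class(out) <- c("pf_gene_sets", "data.frame")
  out
}
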
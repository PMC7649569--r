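# Synthetic test corpora: a closed toy lexicon plus figures whose OCR text
# plants decorated, ranged, slashed and Greek-spelled gene labels among
# distractor words, with a manifest recording exactly which gene IDs each
# figure must yield. Everything is reproducible from (parameters, seed).
#
# The plant grammar covers exactly the transform classes the package ships
# (Greek mapping, OCR confusions, affix stripping, range/slash expansion),
# so recovery assertions test implemented behaviour, nothing more.

.toy_genes <- function() {
  # symbol, "|"-delimited aliases, previous symbols, NCBI-style gene id.
  # IDs for well-known genes are their real NCBI Gene IDs; family blocks and
  # the three stoplist-collision entries (aliases MET/TYR/HIS) are synthetic.
  tab <- c(
    "MAPK1\tERK2|p42\tPRKM1\t5594",
    "MAPK3\tERK1|ERK\t\t5595",
    "MAPK8\tJNK1|ERK\t\t5599",
    "MAPK14\tp38\tCSBP\t1432",
    "AKT1\tAKT|PKB\t\t207",
    "AKT2\t\t\t208",
    "AKT3\t\t\t10000",
    "TP53\tp53\t\t7157",
    "EGFR\tERBB1\tERBB\t1956",
    "KRAS\tKRAS2\tRASK2\t3845",
    "MTOR\tFRAP1\tFRAP\t2475",
    "NFKB1\tp50\t\t4790",
    "RAF1\tc-Raf\t\t5894",
    "TNF\tTNFA\t\t7124",
    "PIK3CA\tp110alpha\t\t5290",
    "MAP2K1\tMEK1\tPRKMK1\t5604",
    "MAP2K2\tMEK2\tPRKMK2\t5605",
    "LATS1\tWARTS\t\t9113",
    "LATS2\t\t\t26524",
    "TEAD1\t\t\t7003",
    "TEAD2\t\t\t8463",
    "TEAD3\t\t\t7005",
    "TEAD4\t\t\t7004",
    "CCND1\tcyclinD1\t\t595",
    "PRKAA1\tAMPKa1\t\t5562",
    "PRKAA2\tAMPKa2\t\t5563",
    "CDK1\tCDC2\t\t983",
    "CDK2\t\t\t1017",
    "CDK3\t\t\t1018",
    "CDK4\t\t\t1019",
    "CDK5\t\t\t1020",
    "CDK6\t\t\t1021",
    "CDK7\t\t\t1022",
    "IL2\t\t\t3558",
    "IL4\t\t\t3565",
    "IL6\t\t\t3569",
    "IL10\t\t\t3586",
    paste0("WNT", 1:11, "\t\t\t", 7470 + 1:11, collapse = "\n"),
    "METL1\tMET\t\t99001",
    "TYRP9\tTYR\t\t99002",
    "HISX1\tHIS\t\t99003"
  )
  utils::read.delim(text = paste(tab, collapse = "\n"), header = FALSE,
                    col.names = c("symbol", "alias_symbol", "prev_symbol",
                                  "ncbi_gene_id"),
                    colClasses = c("character", "character", "character",
                                   "integer"), quote = "")
}

#' Write the toy lexicon source files
#'
#' A small, closed human-gene lexicon (selected kinases, WNT/TEAD/CDK/IL
#' family blocks, Hippo-pathway genes, and three synthetic entries whose
#' aliases collide with amino-acid codes) plus a bioentities-style CSV
#' (NF-kB, AMPK, Cyclin D). Every gene a generated figure can plant is
#' resolvable through these files.
#'
#' @param dir Output directory (created if needed).
#' @return List with paths `hgnc`, `bioentities`, and the `genes` table.
#' @export
toy_lexicon_files <- function(dir = tempfile("toylex")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- .toy_genes()
  hgnc <- file.path(dir, "toy_hgnc.tsv")
  utils::write.table(genes, hgnc, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  be <- file.path(dir, "toy_bioentities.csv")
  writeLines(c("NF-kB,NFKB1",
               "AMPK,PRKAA1,PRKAA2",
               "Cyclin D,CCND1"), be)
  list(hgnc = hgnc, bioentities = be, genes = genes)
}

.pf_decoration_prefixes <- c("P-", "PP-", "PHOSPHO-", "AC-", "MYC-", "HA-",
                             "GST-", "GFP-", "FLAG-")
.pf_decoration_suffixes <- c("-P", "-FLAG", "-GFP", "-HA", "-MYC", "-TAG", "-UB")

# multi-gene plant templates: display string -> expected gene IDs
.pf_multi_templates <- function(genes) {
  id <- stats::setNames(genes$ncbi_gene_id, genes$symbol)
  list(
    list(display = "WNT1-5", ids = unname(id[paste0("WNT", 1:5)])),
    list(display = "WNT2-6", ids = unname(id[paste0("WNT", 2:6)])),
    list(display = "WNT7-11", ids = unname(id[paste0("WNT", 7:11)])),
    list(display = "TEAD1-4", ids = unname(id[paste0("TEAD", 1:4)])),
    list(display = "CDK1-3", ids = unname(id[paste0("CDK", 1:3)])),
    list(display = "CDK4-7", ids = unname(id[paste0("CDK", 4:7)])),
    list(display = "LATS1/2", ids = unname(id[c("LATS1", "LATS2")])),
    list(display = "TEAD1/3", ids = unname(id[c("TEAD1", "TEAD3")])),
    list(display = "IL4/6/10", ids = unname(id[c("IL4", "IL6", "IL10")])),
    list(display = "MAP2K1/2", ids = unname(id[c("MAP2K1", "MAP2K2")])),
    list(display = "NF-κB", ids = unname(id["NFKB1"])),
    list(display = "TNFα", ids = unname(id["TNF"])),
    list(display = "AMPK", ids = unname(id[c("PRKAA1", "PRKAA2")]))
  )
}

.pf_distractors <- function(include_amino = TRUE) {
  base <- c("DNA", "RNA", "CELL", "NUCLEUS", "CYTOPLASM", "APOPTOSIS",
            "GROWTH", "SIGNALING", "MEMBRANE", "RECEPTOR", "LIGAND",
            "KINASE", "PATHWAY", "STRESS", "HYPOXIA", "GLUCOSE",
            "PROLIFERATION", "SURVIVAL", "TRANSCRIPTION", "TRANSLATION",
            "UBIQUITIN", "PROTEASOME", "MITOCHONDRIA", "ACTIVATION",
            "INHIBITION", "NUTRIENTS", "CANCER")
  if (include_amino) base <- c(base, "Met", "Tyr", "His", "Ser", "Thr")
  base
}

#' Generate a synthetic figure corpus with ground truth
#'
#' Each figure plants a sampled number of gene labels — bare symbols or
#' aliases, optionally decorated with experimental-tag affixes, or drawn
#' from multi-gene templates (numeric ranges, slash lists, Greek-spelled
#' bioentity names) — among distractor vocabulary that includes amino-acid
#' codes. The manifest records the exact gene IDs each figure must yield,
#' enabling exact-recovery assertions.
#'
#' @param n_figures Number of figures.
#' @param genes_per_figure Integer range `c(min, max)` of plants per figure.
#' @param decoration_rate Probability a single-gene plant is decorated.
#' @param range_rate Probability a plant uses a multi-gene template.
#' @param seed Integer seed; fully determines the corpus.
#' @param dir Optional directory; when given, OCR `.txt` files, the toy
#'   lexicon and a metadata TSV are written there.
#' @param include_amino_distractors Include Met/Tyr/His/... words, which
#'   collide with gene aliases unless the stoplist is enabled.
#' @return List: `manifests` (per figure: figure_id, planted data frame,
#'   distractors, expected_gene_ids), `docs` (list of `pf_ocr_document`),
#'   `lexicon` (paths from [toy_lexicon_files()]), `metadata` (data frame
#'   figure_id, pmcid, year, figure_title), and `dir` when written.
#' @export
make_corpus <- function(n_figures = 50L, genes_per_figure = c(3L, 12L),
                        decoration_rate = 0.2, range_rate = 0.1,
                        seed = 1L, dir = NULL,
                        include_amino_distractors = TRUE) {
  stopifnot(decoration_rate >= 0, decoration_rate <= 1,
            range_rate >= 0, range_rate <= 1, n_figures >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)

  lexdir <- if (is.null(dir)) tempfile("toylex") else file.path(dir, "lexicon")
  lex_files <- toy_lexicon_files(lexdir)
  genes <- lex_files$genes
  templates <- .pf_multi_templates(genes)
  vocab <- .pf_distractors(include_amino_distractors)

  # single-gene plantable variants: current symbols plus unambiguous aliases
  singles <- rbind(
    data.frame(display = genes$symbol, gene_id = genes$ncbi_gene_id,
               stringsAsFactors = FALSE),
    data.frame(display = c("ERK2", "p53", "p38", "JNK1", "MEK1", "MEK2"),
               gene_id = c(5594L, 7157L, 1432L, 5599L, 5604L, 5605L),
               stringsAsFactors = FALSE))
  # drop amino-collision toys from the plant pool: their *aliases* are the
  # point, and the stoplist removes those
  singles <- singles[!(singles$display %in% c("METL1", "TYRP9", "HISX1")), ]

  manifests <- vector("list", n_figures)
  docs <- vector("list", n_figures)
  meta <- data.frame(figure_id = character(n_figures),
                     pmcid = character(n_figures),
                     year = integer(n_figures),
                     figure_title = character(n_figures),
                     stringsAsFactors = FALSE)
  for (i in seq_len(n_figures)) {
    fid <- sprintf("fig%04d", i)
    n_plants <- sample(genes_per_figure[1]:genes_per_figure[2], 1)
    displays <- character(0)
    expected <- vector("list", 0)
    for (k in seq_len(n_plants)) {
      if (stats::runif(1) < range_rate) {
        tpl <- templates[[sample(length(templates), 1)]]
        displays <- c(displays, tpl$display)
        expected <- c(expected, list(as.integer(tpl$ids)))
      } else {
        row <- singles[sample(nrow(singles), 1), ]
        disp <- row$display
        if (stats::runif(1) < decoration_rate) {
          if (stats::runif(1) < 0.5) {
            disp <- paste0(sample(.pf_decoration_prefixes, 1), disp)
          } else {
            disp <- paste0(disp, sample(.pf_decoration_suffixes, 1))
          }
        }
        if (stats::runif(1) < 0.25) disp <- tolower(disp)
        displays <- c(displays, disp)
        expected <- c(expected, list(as.integer(row$gene_id)))
      }
    }
    distractors <- sample(vocab, sample(5:12, 1), replace = FALSE)
    words <- sample(c(displays, distractors))
    seps <- sample(c(" ", "\n"), length(words) - 1, replace = TRUE)
    text <- paste0(words, c(seps, ""), collapse = "")
    pmcid <- sprintf("PMC%06d", 100000 + ceiling(i / 2))
    year <- sample(1995:2019, 1)
    docs[[i]] <- words_from_text(fid, text, pmcid = pmcid, year = year)
    planted <- data.frame(display = displays, stringsAsFactors = FALSE)
    planted$expected_ids <- expected
    manifests[[i]] <- list(figure_id = fid, planted = planted,
                           distractors = distractors,
                           expected_gene_ids = as.integer(sort(unique(unlist(expected)))))
    meta$figure_id[i] <- fid
    meta$pmcid[i] <- pmcid
    meta$year[i] <- year
    meta$figure_title[i] <- paste("Synthetic pathway figure", i)
  }

  out <- list(manifests = manifests, docs = docs, lexicon = lex_files,
              metadata = meta)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "ocr"), showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n_figures)) {
      writeLines(paste(docs[[i]]$words, collapse = "\n"),
                 file.path(dir, "ocr", paste0(meta$figure_id[i], ".txt")),
                 useBytes = TRUE)
    }
    utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    out$dir <- dir
  }
  out
}

#' Render a synthetic figure to PNG
#'
#' Draws the manifest's planted labels and distractors as high-contrast
#' black-on-white text at non-overlapping grid positions — enough for an
#' OCR engine round-trip; no pathway graphics are attempted.
#'
#' @param manifest One element of `make_corpus()$manifests`.
#' @param file Output PNG path.
#' @param width,height Image size in pixels.
#' @param cex Label size.
#' @return `file`, invisibly.
#' @export
render_figure <- function(manifest, file, width = 800, height = 600,
                          cex = 1.4) {
  if (!capabilities("png")) {
    stop("PNG rendering unavailable on this system; ",
         "text fixtures remain fully usable")
  }
  labels <- c(manifest$planted$display, manifest$distractors)
  n <- length(labels)
  ncol <- ceiling(sqrt(n))
  nrow <- ceiling(n / ncol)
  grDevices::png(file, width = width, height = height, bg = "white")
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  xs <- ((seq_len(n) - 1) %% ncol + 0.5) / ncol
  ys <- 1 - (floor((seq_len(n) - 1) / ncol) + 0.5) / nrow
  graphics::text(xs, ys, labels, cex = cex, col = "black", font = 2)
  invisible(file)
}
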
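# OCR document construction: from pre-extracted text fixtures or, via a
# pluggable engine function, from raster images. The pipeline itself never
# depends on any particular OCR engine — its contribution is post-OCR.

#' Construct an OCR document from raw text
#'
#' @param figure_id Non-empty figure identifier.
#' @param ocr_text OCR output: newline- and space-delimited words.
#' @param pmcid,year Optional paper metadata.
#' @param provenance `"fixture"` (default) or `"engine"`.
#' @return A `pf_ocr_document` with words split on any whitespace run,
#'   order preserved, empties dropped.
#' @export
words_from_text <- function(figure_id, ocr_text, pmcid = NULL, year = NULL,
                            provenance = "fixture") {
  stopifnot(is.character(figure_id), length(figure_id) == 1, nzchar(figure_id))
  if (!is.null(year)) {
    year <- as.integer(year)
    stopifnot(year >= 1900, year <= 2100)
  }
  words <- strsplit(paste(ocr_text, collapse = "\n"), "[[:space:]]+")[[1]]
  words <- words[nzchar(words)]
  structure(list(figure_id = figure_id, pmcid = pmcid, year = year,
                 words = words, provenance = provenance),
            class = "pf_ocr_document")
}

#' Construct an OCR document from a raster image
#'
#' The engine is injected as a function taking an image path and returning
#' the recognized text; no engine ships with the package.
#'
#' @param figure_id Figure identifier.
#' @param image Path to a PNG or JPEG file.
#' @param engine Function `path -> text`, e.g. a tesseract wrapper.
#' @inheritParams words_from_text
#' @return A `pf_ocr_document` with `provenance = "engine"`.
#' @export
words_from_image <- function(figure_id, image, engine, pmcid = NULL,
                             year = NULL) {
  if (missing(engine) || is.null(engine) || !is.function(engine)) {
    stop("no OCR engine supplied; pass engine = function(path) text, ",
         "or use text fixtures via words_from_text()/read_ocr_corpus()")
  }
  if (!file.exists(image)) stop("image file not found: ", image)
  magic <- readBin(image, "raw", n = 8)
  is_png <- length(magic) >= 8 &&
    identical(magic[1:8], as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)))
  is_jpeg <- length(magic) >= 2 && identical(magic[1:2], as.raw(c(0xff, 0xd8)))
  if (!is_png && !is_jpeg) stop("not a decodable PNG/JPEG image: ", image)
  txt <- engine(image)
  words_from_text(figure_id, txt, pmcid = pmcid, year = year,
                  provenance = "engine")
}

#' Read a corpus of OCR text fixtures
#'
#' Accepts either a directory of one `.txt` file per figure (file stem used
#' as figure_id) or a TSV with columns `figure_id`, `ocr_text` and optional
#' `pmcid`, `year`. Within the TSV, literal `\n` encodes a newline.
#'
#' @param path Directory or TSV file.
#' @return List of `pf_ocr_document`.
#' @export
read_ocr_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    return(lapply(files, function(f) {
      words_from_text(tools::file_path_sans_ext(basename(f)),
                      paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                            collapse = "\n"))
    }))
  }
  if (!file.exists(path)) stop("no such corpus path: ", path)
  tab <- utils::read.delim(path, sep = "\t", quote = "", comment.char = "",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("figure_id", "ocr_text") %in% names(tab))) {
    stop("corpus TSV needs columns figure_id and ocr_text")
  }
  lapply(seq_len(nrow(tab)), function(i) {
    words_from_text(tab$figure_id[i],
                    gsub("\\n", "\n", tab$ocr_text[i], fixed = TRUE),
                    pmcid = if ("pmcid" %in% names(tab)) tab$pmcid[i],
                    year = if ("year" %in% names(tab)) tab$year[i])
  })
}

#' @export
print.pf_ocr_document <- function(x, ...) {
  cat("pathfigr OCR document", x$figure_id, "-", length(x$words), "words (",
      x$provenance, ")\n")
  invisible(x)
}
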
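#' Normalize raw article text for pattern extraction
#'
#' Canonicalizes the character-level noise that PDF/HTML/DOCX conversion
#' introduces so that the extraction grammar only ever sees ASCII operators
#' and single spaces: Unicode minus signs, en-dashes used as minus and
#' hyphen variants map to `-`; non-breaking, thin and other Unicode spaces
#' map to an ASCII space; soft hyphens are dropped; common ligatures are
#' expanded; superscript 2 flattens to `2` (so the chi-square glyph
#' survives conversion as `χ2`); emphasis asterisks are stripped and
#' single-character subscript markup such as `Q_b_` flattens to `Qb`.
#' Runs of horizontal whitespace collapse to one space; line structure is
#' retained. The function is total and idempotent:
#' `normalize_text(normalize_text(x))` equals `normalize_text(x)`.
#'
#' @param raw Character vector of raw text (each element normalized
#'   independently).
#' @return Character vector of the same length.
#' @export
#' @examples
#' normalize_text("p = −.04")
normalize_text <- function(raw) {
  if (length(raw) == 0L) return(character())
  x <- enc2utf8(as.character(raw))
  x[is.na(x)] <- ""
  # minus / dash variants -> ASCII hyphen-minus
  x <- gsub("[\u2212\u2013\u2010\u2011\ufe63\uff0d]", "-", x, perl = TRUE)
  # space variants -> ASCII space
  x <- gsub("[\u00a0\u1680\u2000-\u200a\u202f\u205f\u3000]", " ", x, perl = TRUE)
  # soft hyphen and zero-width characters removed
  x <- gsub("[\u00ad\u200b\u200c\u200d\ufeff]", "", x, perl = TRUE)
  # ligatures
  x <- gsub("\ufb00", "ff", x, fixed = TRUE)
  x <- gsub("\ufb01", "fi", x, fixed = TRUE)
  x <- gsub("\ufb02", "fl", x, fixed = TRUE)
  x <- gsub("\ufb03", "ffi", x, fixed = TRUE)
  x <- gsub("\ufb04", "ffl", x, fixed = TRUE)
  # superscript two (chi-square glyph) flattens inline
  x <- gsub("\u00b2", "2", x, fixed = TRUE)
  # markdown-ish emphasis asterisks never carry statistical meaning
  x <- gsub("*", "", x, fixed = TRUE)
  # subscript markup: Q_b_ -> Qb (repeat to a fixed point for nesting)
  repeat {
    y <- gsub("_([A-Za-z0-9])_", "\\1", x, perl = TRUE)
    if (identical(y, x)) break
    x <- y
  }
  # line endings, then collapse horizontal whitespace
  x <- gsub("\r\n?", "\n", x, perl = TRUE)
  x <- gsub("[ \t]+", " ", x, perl = TRUE)
  x <- gsub(" ?\n ?", "\n", x, perl = TRUE)
  x
}

#' Load an article file as normalized raw text
#'
#' Converts a PDF, HTML, DOCX or plain-text article into a one-row tibble
#' holding normalized text ready for [extract_results()]. The format is
#' inferred from the file extension unless `format` is supplied. Content
#' inside article tables is not filtered out: exclusion of tables is de
#' facto, because table cells rarely form the full in-text APA sentence
#' pattern.
#'
#' PDF extraction uses a lightweight built-in reader for digital
#' (text-based) PDFs: it decodes plain and Flate-compressed content
#' streams and concatenates the text shown by `Tj`/`TJ`/`'` operators in
#' natural stream order, with no column re-flow. Scanned PDFs yield empty
#' text.
#'
#' @param path Path to the file.
#' @param format Optional format override, one of `"txt"`, `"html"`,
#'   `"docx"`, `"pdf"`.
#' @param year Optional publication year attached to the document for
#'   per-year trend summaries.
#' @return A tibble with one row and columns `doc_id` (filename stem),
#'   `text` (normalized), `source_format`, `year`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines("t(28) = 0.32, p = .751", f)
#' load_document(f)
load_document <- function(path, format = NULL, year = NA_integer_) {
  stopifnot(length(path) == 1L)
  if (!file.exists(path)) {
    stop("cannot ingest '", path, "': file does not exist", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  fmt <- format %||% switch(ext,
    txt = , text = , md = "txt",
    htm = , html = , xhtml = "html",
    docx = "docx",
    pdf = "pdf",
    stop("cannot infer format of '", path,
         "' from its extension; pass `format`", call. = FALSE)
  )
  fmt <- match.arg(fmt, c("txt", "html", "docx", "pdf"))
  text <- tryCatch(
    switch(fmt,
      txt  = read_txt(path),
      html = html_to_text(path),
      docx = docx_to_text(path),
      pdf  = pdf_to_text(path)
    ),
    error = function(e) {
      stop("failed to ingest '", path, "' as ", fmt, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  tibble::tibble(
    doc_id = tools::file_path_sans_ext(basename(path)),
    text = normalize_text(text),
    source_format = fmt,
    year = as.integer(year)
  )
}

read_txt <- function(path) {
  paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
}

# Extract visible text from HTML, one line per block-level element.
html_to_text <- function(path) {
  doc <- xml2::read_html(path, encoding = "UTF-8")
  for (node in xml2::xml_find_all(doc, "//script | //style")) {
    xml2::xml_remove(node)
  }
  blocks <- xml2::xml_find_all(
    doc, "//p | //h1 | //h2 | //h3 | //h4 | //h5 | //h6 | //li | //tr"
  )
  if (length(blocks) > 0) {
    return(paste(xml2::xml_text(blocks), collapse = "\n"))
  }
  body <- xml2::xml_find_first(doc, "//body")
  if (inherits(body, "xml_missing")) xml2::xml_text(doc) else xml2::xml_text(body)
}

# Extract text from the main document part of a DOCX container,
# one line per paragraph, tabs flattened to spaces.
docx_to_text <- function(path) {
  exdir <- tempfile("docx")
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  files <- suppressWarnings(unzip(path, exdir = exdir, unzip = "internal"))
  part <- files[basename(files) == "document.xml"]
  if (length(part) == 0L) stop("no word/document.xml part found")
  doc <- xml2::read_xml(part[[1]])
  paras <- xml2::xml_find_all(doc, "//w:p", ns = xml2::xml_ns(doc))
  lines <- vapply(paras, function(p) {
    runs <- xml2::xml_find_all(p, ".//w:t | .//w:tab", ns = xml2::xml_ns(doc))
    paste(vapply(runs, function(r) {
      if (xml2::xml_name(r) == "tab") " " else xml2::xml_text(r)
    }, character(1)), collapse = "")
  }, character(1))
  paste(lines, collapse = "\n")
}
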
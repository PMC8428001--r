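# Lightweight text extraction for digital (text-based) PDFs.
#
# Handles the common case produced by word processors and LaTeX: page
# content streams, plain or FlateDecode-compressed, with text drawn via
# the Tj / TJ / ' operators inside BT..ET blocks. Positioning operators
# (Td, TD, T*) are treated as line breaks; no font decoding beyond
# literal-string unescaping, no CID/Type0 glyph mapping, no OCR.

pdf_to_text <- function(path) {
  n <- file.info(path)$size
  bytes <- readBin(path, "raw", n)
  # NULs (common inside binary streams) would truncate the char view;
  # blank them in the copy used for locating keywords only
  chr <- bytes
  chr[chr == as.raw(0)] <- as.raw(32L)
  txt <- rawToChar(chr)
  Encoding(txt) <- "latin1"
  if (!startsWith(txt, "%PDF")) stop("not a PDF file")

  starts <- gregexpr("stream(\r\n|\n)", txt, perl = TRUE,
                     useBytes = TRUE)[[1]]
  if (starts[1] == -1L) return("")
  ends <- gregexpr("endstream", txt, fixed = TRUE, useBytes = TRUE)[[1]]
  lens <- attr(starts, "match.length")

  pieces <- character(0)
  for (i in seq_along(starts)) {
    beg <- starts[i] + lens[i]
    fin <- ends[ends >= beg]
    if (length(fin) == 0L) next
    fin <- fin[1] - 1L
    raw_stream <- bytes[beg:fin]
    # dictionary preceding this stream decides the filter
    dict_start <- max(1L, starts[i] - 600L)
    dict <- substr(txt, dict_start, starts[i])
    data <- raw_stream
    if (grepl("FlateDecode", dict, fixed = TRUE, useBytes = TRUE)) {
      data <- tryCatch(memDecompress(raw_stream, type = "gzip"),
                       error = function(e) NULL)
      if (is.null(data)) next
    }
    content <- tryCatch({
      ch <- data
      ch[ch == as.raw(0)] <- as.raw(32L)
      out <- rawToChar(ch)
      Encoding(out) <- "latin1"
      out
    }, error = function(e) "")
    if (!nzchar(content) || !grepl("BT", content, fixed = TRUE, useBytes = TRUE)) next
    pieces <- c(pieces, pdf_content_text(content))
  }
  paste(pieces[nzchar(pieces)], collapse = "\n")
}

# Pull shown strings out of one decoded content stream, in drawing order.
pdf_content_text <- function(content) {
  blocks <- regmatches(
    content, gregexpr("BT(.*?)ET", content, perl = TRUE, useBytes = TRUE)
  )[[1]]
  lit <- "\\(((?:[^()\\\\]|\\\\.)*)\\)"
  tok <- paste0(
    lit, "\\s*(?:Tj|')",                            # single shown string
    "|\\[(?:[^]\\\\()]|", lit, "|\\\\.)*\\]\\s*TJ", # array of strings
    "|T\\*|TD|Td"                                   # line positioning
  )
  out <- vapply(blocks, function(b) {
    toks <- regmatches(b, gregexpr(tok, b, perl = TRUE, useBytes = TRUE))[[1]]
    if (length(toks) == 0L) return("")
    shown <- vapply(toks, function(s) {
      if (s %in% c("T*", "TD", "Td")) return("\n")
      lits <- regmatches(s, gregexpr(lit, s, perl = TRUE, useBytes = TRUE))[[1]]
      paste(vapply(lits, pdf_unescape, character(1)), collapse = "")
    }, character(1))
    paste(shown, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  txt <- paste(out, collapse = "\n")
  gsub("\n{2,}", "\n", txt, perl = TRUE)
}

pdf_unescape <- function(s) {
  s <- sub("^\\(", "", s)
  s <- sub("\\)$", "", s)
  s <- gsub("\\\\([0-7]{1,3})", "", s, perl = TRUE)  # octal escapes dropped
  s <- gsub("\\\\n", "\n", s, perl = TRUE)
  s <- gsub("\\\\[rt]", " ", s, perl = TRUE)
  gsub("\\\\([()\\\\])", "\\1", s, perl = TRUE)
}
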
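# Minimal DOCX writer used by the synthetic-corpus generator.
#
# A DOCX file is a ZIP container with three mandatory parts for plain
# paragraphs. Files are stored uncompressed with fixed timestamps so a
# fixed seed yields byte-identical corpora.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

write_docx <- function(lines, path) {
  ct <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/word/document.xml" ContentType="application/vnd.openxmlformats-officedocument.wordprocessingml.document.main+xml"/>',
    "</Types>"
  )
  rels <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="word/document.xml"/>',
    "</Relationships>"
  )
  paras <- paste0(
    "<w:p><w:r><w:t xml:space=\"preserve\">",
    xml_escape(lines),
    "</w:t></w:r></w:p>",
    collapse = ""
  )
  docxml <- paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>',
    '<w:document xmlns:w="http://schemas.openxmlformats.org/wordprocessingml/2006/main">',
    "<w:body>", paras, "</w:body></w:document>"
  )
  zip_store(
    path,
    list(
      "[Content_Types].xml" = charToRaw(ct),
      "_rels/.rels" = charToRaw(rels),
      "word/document.xml" = charToRaw(enc2utf8(docxml))
    )
  )
  invisible(path)
}

# ---- stored (uncompressed) ZIP writer -------------------------------------

crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        c <- i
        for (k in 1:8) {
          c <- if (bitwAnd(c, 1L) == 1L) {
            bitwXor(bitwShiftR(c, 1), -306674912L)  # 0xEDB88320
          } else {
            bitwShiftR(c, 1)
          }
        }
        t[i + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  crc <- -1L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  crc <- bitwXor(crc, -1L)
  if (crc < 0) crc + 2^32 else as.numeric(crc)
}

zip_store <- function(path, files) {
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v %% 65536), con, size = 2, endian = "little")
  w4 <- function(v) {
    writeBin(as.integer(v %% 65536), con, size = 2, endian = "little")
    writeBin(as.integer((v %/% 65536) %% 65536), con, size = 2, endian = "little")
  }
  offsets <- numeric(length(files))
  crcs <- numeric(length(files))
  sizes <- numeric(length(files))
  pos <- 0
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    data <- files[[i]]
    offsets[i] <- pos
    crcs[i] <- crc32(data)
    sizes[i] <- length(data)
    w4(0x04034b50); w2(20); w2(0); w2(0)       # sig, version, flags, method=store
    w2(0); w2(0x21)                             # fixed DOS time/date (1980-01-01)
    w4(crcs[i]); w4(sizes[i]); w4(sizes[i])
    w2(length(name)); w2(0)
    writeBin(name, con)
    writeBin(data, con)
    pos <- pos + 30 + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(files)) {
    name <- charToRaw(names(files)[i])
    w4(0x02014b50); w2(20); w2(20); w2(0); w2(0)
    w2(0); w2(0x21)
    w4(crcs[i]); w4(sizes[i]); w4(sizes[i])
    w2(length(name)); w2(0); w2(0); w2(0); w2(0)
    w4(0); w4(offsets[i])
    writeBin(name, con)
    pos <- pos + 46 + length(name)
  }
  w4(0x06054b50); w2(0); w2(0)
  w2(length(files)); w2(length(files))
  w4(pos - cd_start); w4(cd_start); w2(0)
  invisible(path)
}
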
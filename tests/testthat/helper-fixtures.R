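# Fixture builders and independent oracles shared across the test files.

# Minimal single-page PDF with one text line per element of `lines`,
# optionally Flate-compressed, written entirely in code.
make_pdf_fixture <- function(lines, path, compress = FALSE) {
  esc <- function(s) gsub("([()\\\\])", "\\\\\\1", s)
  content <- paste0(
    "BT /F1 12 Tf 72 720 Td ",
    paste0("(", esc(lines), ") Tj T* ", collapse = ""),
    "ET"
  )
  craw <- charToRaw(content)
  filt <- ""
  if (compress) {
    craw <- memCompress(craw, type = "gzip")
    filt <- " /Filter /FlateDecode"
  }
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(s) writeBin(charToRaw(s), con)
  w("%PDF-1.4\n")
  w("1 0 obj << /Type /Catalog /Pages 2 0 R >> endobj\n")
  w("2 0 obj << /Type /Pages /Kids [3 0 R] /Count 1 >> endobj\n")
  w(paste0("3 0 obj << /Type /Page /Parent 2 0 R ",
           "/MediaBox [0 0 612 792] /Contents 4 0 R >> endobj\n"))
  w(sprintf("4 0 obj << /Length %d%s >> stream\n", length(craw), filt))
  writeBin(craw, con)
  w("\nendstream endobj\n%%EOF\n")
  path
}

# Simple HTML wrapper, one <p> per line (mirrors common article HTML).
make_html_fixture <- function(lines, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  writeLines(c("<html><body>", paste0("<p>", esc(lines), "</p>"),
               "</body></html>"), path)
  path
}

rhu <- function(x, d) floor(x * 10^d + 0.5) / 10^d

# Reference p-value from first principles (distribution tails only);
# vectorized over the statistic.
oracle_p <- function(family, s, df1, df2) {
  switch(family,
    t = 2 * stats::pt(-abs(s), df1),
    Z = 2 * stats::pnorm(-abs(s)),
    r = ifelse(abs(s) >= 1, 0,
               2 * stats::pt(-abs(s) * sqrt(df1 / pmax(1 - s^2, 1e-300)), df1)),
    F = stats::pf(s, df1, df2, lower.tail = FALSE),
    stats::pchisq(s, df1, lower.tail = FALSE)
  )
}

# Brute-force consistency oracle: scan a dense grid of statistic values
# across the printed statistic's rounding interval, map each to its p,
# and test the reported claim pointwise. Severity follows the same
# reported-vs-recomputed significance rules as the spec of the check.
oracle_classify <- function(family, s, sdec, df1, df2, p_op, val, pdec,
                            one_tailed, alpha, n_grid = 20001L) {
  h <- 5 * 10^-(sdec + 1)
  grid <- seq(s - h, s + h, length.out = n_grid)
  grid <- grid[-n_grid]  # half-open upper bound
  grid <- c(grid, s)
  if (family == "r") grid <- pmin(pmax(grid, -1), 1)
  pgrid <- oracle_p(family, grid, df1, df2)
  ppoint <- oracle_p(family, s, df1, df2)
  claim_ok <- function(p) {
    if (p_op == "=") {
      if (val == 0) return(FALSE)
      # integer comparison avoids spurious binary-representation misses
      return(any(floor(p * 10^pdec + 0.5) == round(val * 10^pdec)))
    }
    if (p_op == "<") return(any(p < val))
    any(p > val)
  }
  satisfied <- if (p_op == "ns") ppoint > alpha else claim_ok(pgrid)
  if (!satisfied && one_tailed && family %in% c("t", "Z", "r") &&
      !(p_op == "=" && !is.na(val) && val == 0)) {
    satisfied <- if (p_op == "ns") ppoint / 2 > alpha else claim_ok(pgrid / 2)
  }
  if (satisfied) return("consistent")
  rep_sig <- if (p_op == "ns") {
    FALSE
  } else if (p_op == "=") {
    val < alpha
  } else if (p_op == "<") {
    if (val <= alpha) TRUE else NA
  } else {
    if (val >= alpha) FALSE else NA
  }
  rec_sig <- ppoint < alpha
  if (!is.na(rep_sig) && rep_sig != rec_sig) "gross" else "inconsistent"
}

# Random but structurally valid results for property tests. Claims mix
# correctly rounded, perturbed, and fully random p-values so that all
# three verdict classes arise.
random_results <- function(n, families = test_families()) {
  fam <- sample(families, n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    f <- fam[i]
    df1 <- df2 <- NA_real_
    s <- switch(f,
      t = {df1 <- sample(3:200, 1); runif(1, 0.02, 4)},
      Z = runif(1, 0.02, 4),
      r = {df1 <- sample(5:300, 1); runif(1, 0.01, 0.8)},
      F = {df1 <- sample(1:12, 1); df2 <- sample(5:300, 1); runif(1, 0.02, 6)},
      {df1 <- sample(1:40, 1); runif(1, 0.05, df1 * 2.5)}
    )
    sdec <- sample(1:3, 1)
    s <- round(s, sdec)
    if (f == "r") s <- min(s, 0.99)
    if (f != "t" && f != "Z" && f != "r" && s <= 0) s <- 0.1
    ptrue <- oracle_p(f, s, df1, df2)
    pdec <- sample(2:3, 1)
    kind <- sample(c("exact", "perturb", "random", "bound", "ns"), 1,
                   prob = c(0.35, 0.2, 0.15, 0.2, 0.1))
    if (kind == "ns") {
      p_op <- "ns"; val <- NA_real_; pdec <- NA_integer_
    } else if (kind == "bound") {
      p_op <- sample(c("<", ">"), 1)
      val <- sample(c(0.001, 0.01, 0.05, 0.1, 0.25), 1)
      pdec <- c("0.001" = 3L, "0.01" = 2L, "0.05" = 2L,
                "0.1" = 1L, "0.25" = 2L)[[format(val)]]
    } else {
      p_op <- "="
      val <- switch(kind,
        exact = rhu(ptrue, pdec),
        perturb = min(1, max(0, rhu(ptrue, pdec) + sample(c(-1, 1), 1) * 10^-pdec)),
        random = rhu(runif(1), pdec)
      )
      # the double a reader of the printed value would parse
      val <- as.numeric(sprintf("%.*f", pdec, val))
    }
    tibble::tibble(
      family = f, df1 = df1, df2 = df2, n = NA_integer_,
      stat_value = s, stat_op = "=", stat_decimals = as.integer(sdec),
      p_op = p_op, p_value = val,
      p_decimals = if (p_op == "ns") NA_integer_ else as.integer(pdec),
      raw_span = "", offset = i
    )
  })
  dplyr::bind_rows(rows)
}
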
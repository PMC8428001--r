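# Extraction grammar for in-text APA-style NHST results.
#
# A result needs all three elements -- test statistic, degrees of freedom
# (except Z), and a p-value claim (or the "ns" sentinel) -- in the APA
# parenthetical shape, e.g. "t(28) = 0.32, p = .751". Free-floating
# degrees of freedom ("Q=35.72, 17 d.f.") are non-APA and never matched.

NUM_RX  <- "(?:\\d+(?:\\.\\d+)?|\\.\\d+)"
SNUM_RX <- paste0("-?", NUM_RX)
# p-value claim: "p = v", "p < v", "p > v", or "ns"/"n.s."
PCLAIM_RX <- paste0(
  "(?:p\\s*(?<pop>[=<>])\\s*(?<pval>", SNUM_RX, ")",
  "|(?<ns>(?<![A-Za-z])n\\.?\\s?s\\.?(?![A-Za-z])))"
)
# statistic comparator and value, then comma, then the p claim
TAIL_RX <- paste0(
  "\\s*(?<sop>[=<>])\\s*(?<sval>", SNUM_RX, ")\\s*,\\s*", PCLAIM_RX
)
GUARD_RX <- "(?<![A-Za-z0-9_])"

family_head <- function(family) {
  df1 <- paste0("\\(\\s*(?<df1>", NUM_RX, ")\\s*\\)")
  switch(family,
    t = paste0("t\\s*", df1),
    F = paste0("F\\s*\\(\\s*(?<df1>", NUM_RX, ")\\s*,\\s*(?<df2>", NUM_RX,
               ")\\s*\\)"),
    r = paste0("r\\s*", df1),
    chi2 = paste0("(?:χ2|chi2|chi[- ]?squared?)\\s*\\(\\s*(?<df1>",
                  NUM_RX, ")\\s*(?:,\\s*n\\s*=\\s*(?<nn>\\d+)\\s*)?\\)"),
    Z = "z(?!\\s*\\()",
    Q = paste0("Q\\s*", df1),
    Q_between = paste0("Q[-_ ]?(?:between|b)\\s*", df1),
    Q_within = paste0("Q[-_ ]?(?:within|w)\\s*", df1)
  )
}

family_regex <- function(family) {
  paste0("(?i)", GUARD_RX, family_head(family), TAIL_RX)
}

n_decimals <- function(s) {
  has <- grepl(".", s, fixed = TRUE)
  out <- integer(length(s))
  out[has] <- nchar(sub("^[^.]*\\.", "", s[has]))
  out
}

match_family <- function(text, family) {
  rx <- family_regex(family)
  m <- gregexpr(rx, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  grab <- function(name, i) {
    if (!name %in% colnames(cs)) return(NA_character_)
    st <- cs[i, name]
    if (st <= 0L) return(NA_character_)
    substr(text, st, st + cl[i, name] - 1L)
  }
  rows <- lapply(seq_along(m), function(i) {
    sval <- grab("sval", i)
    pval <- grab("pval", i)
    pop <- grab("pop", i)
    is_ns <- !is.na(grab("ns", i))
    tibble::tibble(
      family = family,
      df1 = as.numeric(grab("df1", i)),
      df2 = as.numeric(grab("df2", i)),
      n = as.integer(grab("nn", i)),
      stat_value = as.numeric(sval),
      stat_op = grab("sop", i),
      stat_decimals = n_decimals(sval),
      p_op = if (is_ns) "ns" else pop,
      p_value = if (is_ns) NA_real_ else as.numeric(pval),
      p_decimals = if (is_ns) NA_integer_ else n_decimals(pval),
      raw_span = substr(text, m[i], m[i] + attr(m, "match.length")[i] - 1L),
      offset = as.integer(m[i])
    )
  })
  dplyr::bind_rows(rows)
}

#' Extract APA-style NHST results from a document
#'
#' Scans normalized text for in-text APA-style significance-test reports
#' of the eight families in [test_families()] and parses each into one
#' row. Matching is case-insensitive and tolerant of optional spaces
#' around operators, parentheses and commas, and of a missing leading
#' zero in p-values. A test statistic without an accompanying p-value
#' claim (or "ns") is never extracted; candidate matches that violate
#' basic sanity (reported p outside \[0, 1\], correlation outside
#' \[-1, 1\]) are skipped and counted in the `n_skipped` attribute.
#'
#' @param doc A one-row tibble from [load_document()], or a character
#'   string of (normalized) text.
#' @return A tibble with one row per extracted result in document order:
#'   `family`, `df1`, `df2`, `n` (printed sample size, chi-square only),
#'   `stat_value`, `stat_op`, `stat_decimals`, `p_op` (`=`, `<`, `>`, or
#'   `ns`), `p_value` (NA for `ns`), `p_decimals`, `raw_span`, `offset`
#'   (character index of the match). Attribute `n_skipped` counts
#'   rejected near-matches.
#' @export
#' @examples
#' extract_results("The effect was small, t(28) = 0.32, p = .751.")
extract_results <- function(doc) {
  text <- doc_text(doc)
  empty <- tibble::tibble(
    family = character(), df1 = numeric(), df2 = numeric(), n = integer(),
    stat_value = numeric(), stat_op = character(), stat_decimals = integer(),
    p_op = character(), p_value = numeric(), p_decimals = integer(),
    raw_span = character(), offset = integer()
  )
  if (!nzchar(text)) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  # subgroup Q variants are matched before omnibus Q so that the plain-Q
  # pattern never claims a prefix of a Qb/Qw token
  cands <- dplyr::bind_rows(lapply(test_families(), match_family, text = text))
  if (nrow(cands) == 0L) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  cands <- dplyr::arrange(cands, .data$offset, -nchar(.data$raw_span))
  # drop overlapping matches, keeping the earliest (then longest)
  keep <- logical(nrow(cands))
  last_end <- 0L
  for (i in seq_len(nrow(cands))) {
    if (cands$offset[i] > last_end) {
      keep[i] <- TRUE
      last_end <- cands$offset[i] + nchar(cands$raw_span[i]) - 1L
    }
  }
  cands <- cands[keep, ]
  ok <- rep(TRUE, nrow(cands))
  ok <- ok & (is.na(cands$p_value) | (cands$p_value >= 0 & cands$p_value <= 1))
  ok <- ok & !(cands$family == "r" & abs(cands$stat_value) > 1)
  ok <- ok & !(cands$family %in% c(chisq_families(), "F") & cands$stat_value < 0)
  out <- cands[ok, ]
  attr(out, "n_skipped") <- sum(!ok)
  out
}

doc_text <- function(doc) {
  if (is.data.frame(doc)) {
    stopifnot(nrow(doc) == 1L, "text" %in% names(doc))
    doc$text
  } else {
    stopifnot(is.character(doc), length(doc) == 1L)
    doc
  }
}

#' Detect one-tailed-test context in a document
#'
#' Returns `TRUE` when the text mentions directional testing anywhere:
#' the whole words "one-tailed", "one-sided" (hyphen or space), or
#' "directional", case-insensitively. Word boundaries prevent matches
#' inside longer words ("bidirectional" does not count).
#'
#' @param doc A one-row tibble from [load_document()] or a character
#'   string.
#' @return Logical scalar.
#' @export
#' @examples
#' detect_one_tailed_context("All tests were one-tailed.")
#' detect_one_tailed_context("the design was bidirectional")
detect_one_tailed_context <- function(doc) {
  text <- doc_text(doc)
  grepl("(?i)\\bone[- ](tailed|sided)\\b|\\bdirectional\\b", text, perl = TRUE)
}

#' Serialize results back to canonical APA form
#'
#' The inverse of [extract_results()]: renders each result row as the
#' canonical APA sentence fragment, e.g. `"t(24) = 1.77, p = .03"`,
#' `"QB(2) = 6.71, p = .03"`, `"Z = 1.96, ns"`. P-values print without a
#' leading zero at their recorded precision; statistics print at theirs.
#' `extract_results(format_result(x))` reconstructs the semantic fields
#' of `x`.
#'
#' @param results A tibble of results as returned by [extract_results()].
#' @return Character vector, one element per row.
#' @export
#' @examples
#' r <- extract_results("t(24) = 1.77, p = .03")
#' format_result(r)
format_result <- function(results) {
  stopifnot(is.data.frame(results))
  check_result_invariants(results)
  vapply(seq_len(nrow(results)), function(i) {
    x <- results[i, ]
    head <- switch(x$family,
      t = sprintf("t(%s)", fmt_df(x$df1)),
      F = sprintf("F(%s, %s)", fmt_df(x$df1), fmt_df(x$df2)),
      r = sprintf("r(%s)", fmt_df(x$df1)),
      chi2 = if (!is.na(x$n)) {
        sprintf("chi2(%s, n = %d)", fmt_df(x$df1), x$n)
      } else {
        sprintf("chi2(%s)", fmt_df(x$df1))
      },
      Z = "Z",
      Q = sprintf("Q(%s)", fmt_df(x$df1)),
      Q_between = sprintf("QB(%s)", fmt_df(x$df1)),
      Q_within = sprintf("QW(%s)", fmt_df(x$df1))
    )
    stat <- sprintf("%.*f", x$stat_decimals, x$stat_value)
    pclaim <- if (identical(x$p_op, "ns")) {
      "ns"
    } else {
      sprintf("p %s %s", x$p_op, fmt_p(x$p_value, x$p_decimals))
    }
    sprintf("%s %s %s, %s", head, x$stat_op, stat, pclaim)
  }, character(1))
}

fmt_df <- function(df) {
  if (df == floor(df)) format(as.integer(df)) else format(df)
}

# APA p-values print without the leading zero
fmt_p <- function(value, decimals) {
  s <- sprintf("%.*f", decimals, value)
  sub("^0\\.", ".", s)
}

check_result_invariants <- function(results) {
  for (i in seq_len(nrow(results))) {
    x <- results[i, ]
    if (!x$family %in% test_families()) {
      stop("unknown test family: ", x$family, call. = FALSE)
    }
    if (x$family == "Z" && !is.na(x$df1)) {
      stop("Z results carry no degrees of freedom", call. = FALSE)
    }
    if (x$family == "F" && (is.na(x$df1) || is.na(x$df2))) {
      stop("F results need both df1 and df2", call. = FALSE)
    }
    if (x$family %in% c("t", "r", chisq_families()) && is.na(x$df1)) {
      stop(x$family, " results need df1", call. = FALSE)
    }
    if (x$family == "r" && abs(x$stat_value) > 1) {
      stop("correlation outside [-1, 1]", call. = FALSE)
    }
    if (!identical(x$p_op, "ns") &&
        (is.na(x$p_value) || x$p_value < 0 || x$p_value > 1)) {
      stop("reported p-value outside [0, 1]", call. = FALSE)
    }
  }
  invisible(results)
}
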
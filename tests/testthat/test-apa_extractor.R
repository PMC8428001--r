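test_that("canonical APA statements of each family are parsed", {
  res <- extract_results("t(28) = 0.32, p = .751")
  expect_equal(res$family, "t")
  expect_equal(res$df1, 28)
  expect_equal(res$stat_value, 0.32)
  expect_equal(res$stat_decimals, 2L)
  expect_equal(res$p_value, 0.751)
  expect_equal(res$p_decimals, 3L)

  res <- extract_results("(QB(2) = 6.71, p = .03)")
  expect_equal(res$family, "Q_between")
  expect_equal(res$df1, 2)

  res <- extract_results("Z = 1.96, ns")
  expect_equal(res$family, "Z")
  expect_true(is.na(res$df1))
  expect_equal(res$p_op, "ns")

  res <- extract_results("F(2, 45) = 3.10, p = .055")
  expect_equal(res$family, "F")
  expect_equal(c(res$df1, res$df2), c(2, 45))

  res <- extract_results("chi2(5, n = 36) = 11.05, p < .05")
  expect_equal(res$family, "chi2")
  expect_equal(res$n, 36L)
  expect_equal(res$p_op, "<")

  res <- extract_results(normalize_text("χ2(5, N = 36) = 11.05, p < .05"))
  expect_equal(res$family, "chi2")

  res <- extract_results("r(58) = .38, p < .01")
  expect_equal(res$family, "r")

  res <- extract_results("Q(17) = 35.72, p < .0001")
  expect_equal(res$family, "Q")

  res <- extract_results("QW(3) = 2.10, p = .55")
  expect_equal(res$family, "Q_within")
})

test_that("non-APA reporting shapes are not extracted", {
  # free-floating degrees of freedom
  expect_equal(nrow(extract_results("(Q=35.72, 17 d.f., p<.0001)")), 0L)
  # statistic without a p-value claim
  expect_equal(nrow(extract_results("t(28) = 0.32 was small")), 0L)
  # CI-style statements
  expect_equal(nrow(extract_results(
    "SMD -0.32, 95% CI -0.63 to -0.01, P = 0.04"
  )), 0L)
  expect_equal(nrow(extract_results("")), 0L)
  # chi-square with the chi glyph lost entirely
  expect_equal(nrow(extract_results("2 (5, n=36) = 11.05, p < .05")), 0L)
})

test_that("matching tolerates spacing, case and leading-zero variants", {
  variants <- c(
    "t(28) = 0.32, p = .751",
    "t ( 28 ) = 0.32 , p = .751",
    "t(28)=0.32,p=.751",
    "T(28) = 0.32, P = 0.751",
    "t(28) = 0.32, p = 0.751"
  )
  base <- extract_results(variants[1])
  for (v in variants[-1]) {
    res <- extract_results(v)
    expect_equal(nrow(res), 1L, info = v)
    expect_equal(res$family, base$family, info = v)
    expect_equal(res$stat_value, base$stat_value, info = v)
    expect_equal(res$p_value, base$p_value, info = v)
  }
})

test_that("results are returned in document order without overlaps", {
  text <- paste(
    "First, t(12) = 2.20, p = .048; then F(3, 40) = 1.05, p = .38;",
    "and finally QB(1) = 3.78, p < .05."
  )
  res <- extract_results(text)
  expect_equal(res$family, c("t", "F", "Q_between"))
  expect_true(all(diff(res$offset) > 0))
  ends <- res$offset + nchar(res$raw_span) - 1
  expect_true(all(res$offset[-1] > ends[-nrow(res)]))
})

test_that("invalid candidate matches are skipped and tallied", {
  res <- extract_results("r(30) = 1.42, p = .03")
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "n_skipped"), 1L)
  res <- extract_results("t(30) = 1.42, p = 3.5")
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "n_skipped"), 1L)
})

test_that("one-tailed context detection respects word boundaries", {
  expect_true(detect_one_tailed_context("we used a one-tailed test"))
  expect_true(detect_one_tailed_context("a one sided hypothesis"))
  expect_true(detect_one_tailed_context("Directional tests were planned"))
  expect_false(detect_one_tailed_context("the study was bidirectional"))
  expect_false(detect_one_tailed_context("unidirectional flow"))
  expect_false(detect_one_tailed_context(""))
  # brute-force keyword scan agrees on word-tokenized text
  texts <- c("one-tailed", "onesided", "bidirectional scan", "directional",
             "a one sided test", "none", "one- tailed")
  for (tx in texts) {
    words <- strsplit(gsub("-", " ", tolower(tx)), "[^a-z]+")[[1]]
    brute <- any(c("directional") %in% words) ||
      grepl("\\bone (tailed|sided)\\b", gsub("-", " ", tolower(tx)))
    expect_equal(detect_one_tailed_context(tx), brute, info = tx)
  }
})

test_that("format/extract round-trip preserves semantic fields", {
  set.seed(41)
  res <- random_results(300)
  formatted <- format_result(res)
  for (i in seq_len(nrow(res))) {
    back <- extract_results(paste0("Lead-in text, ", formatted[i], ", end."))
    expect_equal(nrow(back), 1L, info = formatted[i])
    for (col in c("family", "df1", "df2", "stat_value", "stat_op",
                  "stat_decimals", "p_op", "p_value", "p_decimals")) {
      expect_equal(back[[col]], res[[col]][i], info = paste(col, formatted[i]))
    }
  }
})

test_that("formatting rejects invariant-violating results", {
  bad <- tibble::tibble(
    family = "F", df1 = 2, df2 = NA_real_, n = NA_integer_,
    stat_value = 1.5, stat_op = "=", stat_decimals = 2L,
    p_op = "=", p_value = 0.05, p_decimals = 2L
  )
  expect_error(format_result(bad), "df2")
  bad$family <- "nope"
  expect_error(format_result(bad), "family")
})
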
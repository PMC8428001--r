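# Statements with known verdicts, used to hand-build corpora.
CONSISTENT_A <- "t(28) = 0.32, p = .751"      # recomputed .751
CONSISTENT_B <- "Z = 1.00, p = .317"          # recomputed .3173
CONSISTENT_SIG <- "Z = 2.58, p = .01"         # recomputed .0099, significant
INCONSISTENT_NG <- "t(28) = 0.32, p = .761"   # mismatch, same side of alpha
GROSS_SIG <- "t(24) = 1.77, p = .03"          # reported sig, recomputed .089

doc_text_of <- function(stmts) {
  paste0("Filler sentence. ", paste0("We found ", stmts, ".", collapse = " "))
}

test_that("document reports tally verdict classes correctly", {
  rep <- check_text(doc_text_of(c(CONSISTENT_A, CONSISTENT_B, GROSS_SIG,
                                  INCONSISTENT_NG, CONSISTENT_SIG)),
                    doc_id = "d1")
  g <- glance(rep)
  expect_equal(g$n_results, 5L)
  expect_equal(g$n_inconsistent, 2L)  # gross counts as inconsistent
  expect_equal(g$n_gross, 1L)
  expect_true(g$n_gross <= g$n_inconsistent)
  expect_true(g$n_inconsistent <= g$n_results)
  expect_equal(g$pct_inconsistent, 40)
  td <- tidy(rep)
  expect_equal(nrow(td), 5L)
  expect_equal(sum(td$consistency == "gross"), 1L)
})

test_that("a document with no APA results yields an all-zero report", {
  rep <- check_text("No statistics here, only prose about methods.")
  g <- glance(rep)
  expect_equal(c(g$n_results, g$n_inconsistent, g$n_gross), c(0L, 0L, 0L))
  expect_true(is.na(g$pct_inconsistent))
})

test_that("pooled and averaged-within-article rates follow their definitions", {
  r1 <- check_text(doc_text_of(c(CONSISTENT_A, CONSISTENT_B)), doc_id = "d1")
  r2 <- check_text(doc_text_of(c(CONSISTENT_SIG, INCONSISTENT_NG)), doc_id = "d2")
  s <- glance(summarize_corpus(list(r1, r2)))
  expect_equal(s$result_level_pct_inconsistent, 25)       # 1 of 4 pooled
  expect_equal(s$mean_within_doc_pct_inconsistent, 25)    # mean of 0 and 50
  expect_equal(s$sd_within_doc_pct_inconsistent, sd(c(0, 50)))
  # unequal document sizes pull the two definitions apart
  r3 <- check_text(doc_text_of(c(CONSISTENT_A, CONSISTENT_B, CONSISTENT_SIG,
                                 INCONSISTENT_NG)), doc_id = "d3")
  r4 <- check_text(doc_text_of(INCONSISTENT_NG), doc_id = "d4")
  s2 <- glance(summarize_corpus(list(r3, r4)))
  expect_equal(s2$result_level_pct_inconsistent, 40)      # 2 of 5
  expect_equal(s2$mean_within_doc_pct_inconsistent, 62.5) # mean of 25, 100
})

test_that("corpus summaries match a brute-force recount on random corpora", {
  set.seed(33)
  for (k in 1:5) {
    n_docs <- sample(3:7, 1)
    reports <- lapply(seq_len(n_docs), function(i) {
      stmts <- sample(c(CONSISTENT_A, CONSISTENT_B, CONSISTENT_SIG,
                        INCONSISTENT_NG, GROSS_SIG),
                      sample(0:5, 1), replace = TRUE)
      txt <- if (length(stmts) == 0) "Prose only." else doc_text_of(stmts)
      check_text(txt, doc_id = sprintf("d%02d", i))
    })
    s <- glance(summarize_corpus(reports))
    per_doc <- t(vapply(reports, function(r) {
      v <- r$results$consistency
      c(n = length(v), inc = sum(v != "consistent"), gross = sum(v == "gross"))
    }, numeric(3)))
    expect_equal(s$total_results, sum(per_doc[, "n"]))
    has <- per_doc[, "n"] > 0
    expect_equal(s$n_docs_with_results, sum(has))
    expect_equal(s$median_results_per_doc, median(per_doc[has, "n"]))
    if (sum(per_doc[, "n"]) > 0) {
      expect_equal(s$result_level_pct_inconsistent,
                   100 * sum(per_doc[, "inc"]) / sum(per_doc[, "n"]))
    }
    if (any(has)) {
      expect_equal(s$mean_within_doc_pct_inconsistent,
                   mean(100 * per_doc[has, "inc"] / per_doc[has, "n"]))
    }
  }
})

test_that("bias rates split gross counts by reported significance", {
  rep <- check_text(doc_text_of(c(GROSS_SIG, CONSISTENT_SIG,
                                  CONSISTENT_A, CONSISTENT_B)), doc_id = "d1")
  b <- summarize_corpus(list(rep))$bias
  sig <- b[b$reported_significant %in% TRUE, ]
  nonsig <- b[b$reported_significant %in% FALSE, ]
  expect_equal(sig$n, 2L)
  expect_equal(sig$pct_gross, 50)
  expect_equal(nonsig$n, 2L)
  expect_equal(nonsig$pct_gross, 0)
  # indeterminate reported significance stays out of both denominators
  rep2 <- check_text(doc_text_of(c(GROSS_SIG, CONSISTENT_A,
                                   "t(30) = 1.50, p < .10")), doc_id = "d2")
  b2 <- summarize_corpus(list(rep2))$bias
  expect_equal(sum(b2$n), 2L)
})

test_that("summaries are permutation-invariant and ignore empty documents' rates", {
  r1 <- check_text(doc_text_of(c(CONSISTENT_A, GROSS_SIG)), doc_id = "a")
  r2 <- check_text(doc_text_of(CONSISTENT_B), doc_id = "b")
  r3 <- check_text("Nothing here.", doc_id = "c")
  s123 <- summarize_corpus(list(r1, r2, r3))
  s321 <- summarize_corpus(list(r3, r2, r1))
  expect_equal(s123$summary, s321$summary)
  expect_equal(dplyr::arrange(s123$per_family, family),
               dplyr::arrange(s321$per_family, family))
  # adding an empty document changes coverage, not inconsistency rates
  s12 <- summarize_corpus(list(r1, r2))
  expect_equal(s123$summary$result_level_pct_inconsistent,
               s12$summary$result_level_pct_inconsistent)
  expect_equal(s123$summary$mean_within_doc_pct_inconsistent,
               s12$summary$mean_within_doc_pct_inconsistent)
  expect_equal(s123$summary$n_docs, s12$summary$n_docs + 1L)
  expect_lt(s123$summary$pct_docs_with_results,
            s12$summary$pct_docs_with_results)
})

test_that("per-year prevalence uses supplied years and skips undated docs", {
  r1 <- check_text(doc_text_of(CONSISTENT_A), doc_id = "a", year = 2010)
  r2 <- check_text("Nothing.", doc_id = "b", year = 2010)
  r3 <- check_text(doc_text_of(CONSISTENT_B), doc_id = "c", year = 2012)
  r4 <- check_text(doc_text_of(CONSISTENT_B), doc_id = "d")  # no year
  py <- summarize_corpus(list(r1, r2, r3, r4))$per_year
  expect_equal(py$year, c(2010L, 2012L))
  expect_equal(py$n_docs, c(2L, 1L))
  expect_equal(py$prop_with_results, c(0.5, 1))
})

test_that("an empty corpus summarizes to zero counts and absent rates", {
  s <- glance(summarize_corpus(list()))
  expect_equal(s$n_docs, 0L)
  expect_equal(s$total_results, 0L)
  expect_true(is.na(s$result_level_pct_inconsistent))
})
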
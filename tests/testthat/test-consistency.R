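classify_text <- function(text, one_tailed = FALSE, alpha = 0.05, ...) {
  classify(extract_results(text), one_tailed_context = one_tailed,
           config = check_config(alpha = alpha, ...))
}

test_that("correctly rounded reports are consistent", {
  v <- classify_text("t(28) = 0.32, p = .751")
  expect_equal(v$consistency, "consistent")
  expect_equal(v$reason, "ok")
  # chi-square tail at df = 2 is exp(-x/2): exp(-6.71/2) = .0349 rounds
  # to .03 within the statistic's rounding interval
  expect_equal(exp(-6.71 / 2), pchisq(6.71, 2, lower.tail = FALSE),
               tolerance = 1e-12)
  v <- classify_text("QB(2) = 6.71, p = .03")
  expect_equal(v$consistency, "consistent")
})

test_that("significance flips are graded gross, plain mismatches are not", {
  v <- classify_text("t(24) = 1.77, p = .03")
  expect_equal(v$consistency, "gross")
  expect_equal(v$reason, "sign_flip")
  expect_true(v$reported_significant)
  expect_false(v$recomputed_significant)
  # same magnitude of error on the same side of alpha: inconsistent only
  v <- classify_text("t(28) = 0.32, p = .761")
  expect_equal(v$consistency, "inconsistent")
  expect_equal(v$reason, "rounding_mismatch")
})

test_that("NS claims are judged against the recomputed point p", {
  v <- classify_text("Z = 1.96, ns")
  expect_equal(v$consistency, "gross")
  expect_equal(v$reason, "ns_but_significant")
  v <- classify_text("Z = 1.96, ns", alpha = 0.01)
  expect_equal(v$consistency, "consistent")
  v <- classify_text("QB(1) = 5.38, ns", alpha = 0.01)
  expect_equal(v$consistency, "consistent")
  v <- classify_text("QB(1) = 5.38, ns")
  expect_equal(v$consistency, "gross")
  # NS consistency is monotone in alpha
  p_point <- recompute_p("Z", 1.96)
  alphas <- c(0.001, 0.01, 0.03, 0.049, 0.051, 0.1, 0.2)
  ok <- vapply(alphas, function(a) {
    classify_text("Z = 1.96, ns", alpha = a)$consistency == "consistent"
  }, logical(1))
  expect_equal(ok, alphas < p_point)
})

test_that("p = .000 violates reporting convention", {
  v <- classify_text("t(40) = 8.00, p = .000")
  expect_equal(v$consistency, "inconsistent")  # conclusion does not flip
  expect_equal(v$reason, "zero_p_convention")
  v <- classify_text("t(40) = 0.80, p = .000")
  expect_equal(v$consistency, "gross")  # flips: reported sig, recomputed not
  expect_equal(v$reason, "zero_p_convention")
  # convention check can be disabled
  v <- classify_text("t(40) = 8.00, p = .000",
                     zero_p_always_inconsistent = FALSE)
  expect_equal(v$consistency, "consistent")
})

test_that("one-tailed rescue halves the interval for directional tests only", {
  txt <- "t(32) = 1.82, p < .05"
  expect_equal(classify_text(txt)$consistency, "gross")
  v <- classify_text(txt, one_tailed = TRUE)
  expect_equal(v$consistency, "consistent")
  expect_equal(v$reason, "one_tailed_rescue")
  expect_true(v$one_tailed_applied)
  # rescue can be disabled
  v <- classify_text(txt, one_tailed = TRUE, one_tailed_detection = FALSE)
  expect_equal(v$consistency, "gross")
  # upper-tail families are never rescued: QB(1) = 3.78 has p = .052,
  # halving would land it under .05, but no two-sided convention exists
  v <- classify_text("QB(1) = 3.78, p < .05", one_tailed = TRUE)
  expect_equal(v$consistency, "gross")
  expect_false(v$one_tailed_applied)
})

test_that("indeterminate reported significance is never graded gross", {
  # "p < .10" at alpha .05 with recomputed p above .10 on all of the
  # interval: the claim fails but the reported side of alpha is unknown
  v <- classify_text("t(30) = 1.50, p < .10")
  expect_equal(v$consistency, "inconsistent")
  expect_equal(v$reason, "rounding_mismatch")
  expect_true(is.na(v$reported_significant))
  v <- classify_text("t(30) = 3.50, p > .01")
  expect_true(is.na(v$reported_significant))
  expect_equal(v$consistency, "inconsistent")
})

test_that("enabling one-tailed detection is monotonically lenient", {
  set.seed(71)
  res <- random_results(250)
  off <- classify(res, one_tailed_context = TRUE,
                  config = check_config(one_tailed_detection = FALSE))
  on <- classify(res, one_tailed_context = TRUE,
                 config = check_config(one_tailed_detection = TRUE))
  worse <- off$consistency == "consistent" & on$consistency != "consistent"
  expect_equal(sum(worse), 0L)
  rescued <- on$one_tailed_applied
  expect_true(all(on$family[rescued] %in% c("t", "Z", "r")))
})

test_that("classification agrees with a dense-grid brute-force oracle", {
  set.seed(101)
  res <- random_results(400)
  one_tailed <- sample(c(TRUE, FALSE), nrow(res), replace = TRUE)
  alpha <- 0.05
  for (otc in c(FALSE, TRUE)) {
    sub <- res[one_tailed == otc, ]
    got <- classify(sub, one_tailed_context = otc,
                    config = check_config(alpha = alpha))
    want <- vapply(seq_len(nrow(sub)), function(i) {
      oracle_classify(sub$family[i], sub$stat_value[i], sub$stat_decimals[i],
                      sub$df1[i], sub$df2[i], sub$p_op[i], sub$p_value[i],
                      sub$p_decimals[i], otc, alpha)
    }, character(1))
    expect_equal(got$consistency, want)
  }
})

test_that("verdicts are deterministic and gross implies a failed claim", {
  set.seed(5)
  res <- random_results(100)
  a <- classify(res, one_tailed_context = FALSE)
  b <- classify(res, one_tailed_context = FALSE)
  expect_identical(a, b)
  gross <- a[a$consistency == "gross", ]
  expect_true(all(gross$reported_significant != gross$recomputed_significant))
})
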
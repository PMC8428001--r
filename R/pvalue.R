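# Recomputation of p-values and rounding-interval propagation.
#
# t, Z and r are two-tailed; F, chi-square and the Q heterogeneity family
# are upper-tail tests on their reference distribution. A correlation r
# with df = n - 2 is referred to a t distribution via
# t = |r| * sqrt(df / (1 - r^2)). No continuity corrections anywhere.

#' Recompute a p-value from a reported statistic
#'
#' @param family One of [test_families()] (vectorized).
#' @param statistic The reported test statistic (sign ignored for the
#'   two-tailed families).
#' @param df1 First degrees of freedom; required except for Z. For r this
#'   is n - 2.
#' @param df2 Second degrees of freedom; required for F only.
#' @return Numeric vector of two-tailed (t, Z, r) or upper-tail (F,
#'   chi-square, Q family) p-values. `|r| = 1` returns 0 with a
#'   degenerate-case warning.
#' @export
#' @examples
#' recompute_p("t", 1.77, 24)
#' recompute_p("Q_between", 6.71, 2)
recompute_p <- function(family, statistic, df1 = NA_real_, df2 = NA_real_) {
  n <- max(length(family), length(statistic), length(df1), length(df2))
  family <- rep_len(family, n)
  statistic <- rep_len(statistic, n)
  df1 <- rep_len(as.numeric(df1), n)
  df2 <- rep_len(as.numeric(df2), n)
  bad <- !family %in% test_families()
  if (any(bad)) stop("unknown test family: ", family[bad][1], call. = FALSE)
  need1 <- family != "Z" & is.na(df1)
  if (any(need1)) {
    stop("df1 is required for ", family[need1][1], " tests", call. = FALSE)
  }
  if (any(family == "F" & is.na(df2))) {
    stop("df2 is required for F tests", call. = FALSE)
  }
  if (any(family == "r" & abs(statistic) > 1)) {
    stop("|r| cannot exceed 1", call. = FALSE)
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- statistic[i]
    out[i] <- switch(family[i],
      t = 2 * pt(-abs(s), df1[i]),
      Z = 2 * pnorm(-abs(s)),
      r = {
        if (abs(s) == 1) {
          warning("degenerate correlation |r| = 1; p = 0", call. = FALSE)
          0
        } else {
          tval <- abs(s) * sqrt(df1[i] / (1 - s^2))
          2 * pt(-tval, df1[i])
        }
      },
      F = pf(s, df1[i], df2[i], lower.tail = FALSE),
      pchisq(s, df1[i], lower.tail = FALSE)  # chi2 and the Q family
    )
  }
  out
}

#' Rounding interval of a printed number
#'
#' A value printed as `2.35` (two decimals) could be any actual value in
#' the half-open interval `[2.345, 2.355)`. For a `<` or `>` comparison
#' the implied one-sided interval is returned instead.
#'
#' @param value Printed value.
#' @param op Comparison operator, one of `"="`, `"<"`, `">"`.
#' @param decimals Number of printed decimal digits.
#' @return A tibble with columns `lo`, `hi` (half-open `[lo, hi)` for
#'   `=`).
#' @export
#' @examples
#' statistic_interval(2.35, "=", 2)
statistic_interval <- function(value, op = "=", decimals = 2L) {
  n <- max(length(value), length(op), length(decimals))
  value <- rep_len(value, n)
  op <- rep_len(op, n)
  decimals <- rep_len(decimals, n)
  half <- 5 * 10^-(decimals + 1)
  lo <- ifelse(op == "=", value - half, ifelse(op == "<", -Inf, value))
  hi <- ifelse(op == "=", value + half, ifelse(op == "<", value, Inf))
  tibble::tibble(lo = lo, hi = hi)
}

#' Propagate a statistic's rounding interval to a p-value interval
#'
#' Evaluates [recompute_p()] at the printed statistic and at the
#' endpoints of its rounding interval. Because every family's tail
#' function is monotone in the statistic's magnitude, endpoint (plus
#' zero-crossing) evaluation bounds the attainable p range.
#'
#' @inheritParams recompute_p
#' @param op,decimals Comparison operator and printed precision of the
#'   statistic (see [statistic_interval()]).
#' @return A tibble with columns `p_lo`, `p_point`, `p_hi` satisfying
#'   `0 <= p_lo <= p_point <= p_hi <= 1`.
#' @export
#' @examples
#' p_interval("Z", 1.96, decimals = 2)
p_interval <- function(family, statistic, df1 = NA_real_, df2 = NA_real_,
                       op = "=", decimals = 2L) {
  n <- max(length(family), length(statistic), length(df1), length(df2),
           length(op), length(decimals))
  family <- rep_len(family, n)
  statistic <- rep_len(statistic, n)
  df1 <- rep_len(as.numeric(df1), n)
  df2 <- rep_len(as.numeric(df2), n)
  si <- statistic_interval(rep_len(statistic, n), rep_len(op, n),
                           rep_len(decimals, n))
  p_point <- recompute_p(family, statistic, df1, df2)
  p_lo <- numeric(n)
  p_hi <- numeric(n)
  for (i in seq_len(n)) {
    cand <- c(si$lo[i], si$hi[i])
    if (family[i] == "r") cand <- pmin(pmax(cand, -1), 1)
    # a sign change inside the interval admits the p at statistic zero
    if (si$lo[i] < 0 && si$hi[i] > 0) cand <- c(cand, 0)
    p <- vapply(cand, function(s) {
      if (!is.finite(s)) return(0)
      suppressWarnings(recompute_p(family[i], s, df1[i], df2[i]))
    }, numeric(1))
    p_lo[i] <- min(p, p_point[i])
    p_hi[i] <- max(p, p_point[i])
  }
  tibble::tibble(p_lo = p_lo, p_point = p_point, p_hi = p_hi)
}

#' Display form of a recomputed p-value
#'
#' Recomputed p-values are displayed floor-truncated to three decimals
#' without a leading zero (e.g. `.089`); internal comparisons always use
#' full precision, truncation is presentation-only.
#'
#' @param p Numeric vector of probabilities.
#' @return Character vector like `".089"`.
#' @export
#' @examples
#' p_display(recompute_p("t", 1.77, 24))
p_display <- function(p) {
  tr <- floor(p * 1000 + 1e-8) / 1000
  sub("^0\\.", ".", sprintf("%.3f", tr))
}

# numeric truncated value, used by the flat result records
p_truncate3 <- function(p) floor(p * 1000 + 1e-8) / 1000
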
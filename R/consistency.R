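# Rounding-aware comparison of the reported p-value claim against the
# recomputed p-value interval, and severity grading.
#
# A claim "p = v" (printed to d decimals) is satisfied when some p* in
# the recomputed interval rounds (half-up, to d decimals) to v, i.e. when
# the recomputed interval overlaps [v - 5*10^-(d+1), v + 5*10^-(d+1)).
# Bound claims "p < v" / "p > v" are satisfied when some p* in the
# interval lies strictly on the claimed side. The "ns" sentinel claims a
# nonsignificant result and is judged against the point-recomputed p
# (an NS claim carries no printed digits, so there is nothing to round):
# it is satisfied when p_point > alpha.

claim_satisfied <- function(p_lo, p_hi, p_point, p_op, p_value, p_decimals,
                            alpha, zero_p_always_inconsistent) {
  if (identical(p_op, "ns")) return(p_point > alpha)
  if (p_op == "=") {
    if (zero_p_always_inconsistent && p_value == 0) return(FALSE)
    half <- 5 * 10^-(p_decimals + 1)
    # overlap of [p_lo, p_hi] with the half-open [v - half, v + half)
    return(p_lo < p_value + half && p_value - half <= p_hi)
  }
  if (p_op == "<") return(p_lo < p_value)
  p_hi > p_value  # ">"
}

# Significance of the claim as printed: strict inequality against alpha;
# a printed value exactly at alpha counts nonsignificant. Bound claims
# whose bound sits on the "wrong" side of alpha are indeterminate (NA).
reported_significance <- function(p_op, p_value, alpha) {
  if (identical(p_op, "ns")) return(FALSE)
  if (p_op == "=") return(p_value < alpha)
  if (p_op == "<") {
    if (p_value <= alpha) return(TRUE)
    return(NA)  # e.g. "p < .10" at alpha .05
  }
  if (p_value >= alpha) return(FALSE)  # "p > .30"
  NA  # e.g. "p > .01" at alpha .05
}

#' Classify extracted results as consistent, inconsistent, or gross
#'
#' For every extracted result, recomputes the p-value interval implied by
#' the printed statistic's rounding interval and tests the reported
#' p-value claim against it. A failed claim is *inconsistent*; it is
#' *grossly inconsistent* when additionally the significance conclusion
#' flips (the claim as printed and the recomputed p fall on opposite
#' sides of alpha). When the document signals directional testing, a
#' failed claim on a t, Z or r result is retested against the halved
#' (one-tailed) interval and counted consistent if it then succeeds.
#'
#' @param results Tibble from [extract_results()].
#' @param one_tailed_context Logical; document-level directional-testing
#'   flag from [detect_one_tailed_context()].
#' @param config A [check_config()].
#' @return The input tibble with columns appended: `p_lo`, `p_recomputed`
#'   (full-precision point value), `p_hi`, `consistency` (one of
#'   `"consistent"`, `"inconsistent"`, `"gross"`), `reason` (`ok`,
#'   `rounding_mismatch`, `sign_flip`, `ns_but_significant`,
#'   `zero_p_convention`, `one_tailed_rescue`), `one_tailed_applied`,
#'   `reported_significant` (NA when indeterminate, e.g. "p < .10" at
#'   alpha .05), `recomputed_significant`.
#' @export
#' @examples
#' r <- extract_results("t(24) = 1.77, p = .03")
#' classify(r)
classify <- function(results, one_tailed_context = FALSE,
                     config = check_config()) {
  stopifnot(inherits(config, "check_config"))
  n <- nrow(results)
  pint <- p_interval(results$family, results$stat_value, results$df1,
                     results$df2, results$stat_op, results$stat_decimals)
  consistency <- character(n)
  reason <- character(n)
  one_tailed_applied <- logical(n)
  rep_sig <- logical(n)
  rec_sig <- logical(n)
  for (i in seq_len(n)) {
    v <- classify_one(
      family = results$family[i],
      p_lo = pint$p_lo[i], p_point = pint$p_point[i], p_hi = pint$p_hi[i],
      p_op = results$p_op[i], p_value = results$p_value[i],
      p_decimals = results$p_decimals[i],
      one_tailed_context = one_tailed_context, config = config
    )
    consistency[i] <- v$consistency
    reason[i] <- v$reason
    one_tailed_applied[i] <- v$one_tailed_applied
    rep_sig[i] <- v$reported_significant
    rec_sig[i] <- v$recomputed_significant
  }
  dplyr::mutate(
    results,
    p_lo = pint$p_lo,
    p_recomputed = pint$p_point,
    p_hi = pint$p_hi,
    consistency = consistency,
    reason = reason,
    one_tailed_applied = one_tailed_applied,
    reported_significant = rep_sig,
    recomputed_significant = rec_sig
  )
}

classify_one <- function(family, p_lo, p_point, p_hi, p_op, p_value,
                         p_decimals, one_tailed_context, config) {
  alpha <- config$alpha
  zero_claim <- identical(p_op, "=") && isTRUE(p_value == 0) &&
    config$zero_p_always_inconsistent
  ok <- claim_satisfied(p_lo, p_hi, p_point, p_op, p_value, p_decimals,
                        alpha, config$zero_p_always_inconsistent)
  rep_sig <- reported_significance(p_op, p_value, alpha)
  rec_sig <- p_point < alpha
  if (ok) {
    return(list(consistency = "consistent", reason = "ok",
                one_tailed_applied = FALSE,
                reported_significant = rep_sig,
                recomputed_significant = rec_sig))
  }
  if (one_tailed_context && config$one_tailed_detection &&
      family %in% directional_families() && !zero_claim) {
    rescued <- claim_satisfied(p_lo / 2, p_hi / 2, p_point / 2, p_op,
                               p_value, p_decimals, alpha,
                               config$zero_p_always_inconsistent)
    if (rescued) {
      return(list(consistency = "consistent", reason = "one_tailed_rescue",
                  one_tailed_applied = TRUE,
                  reported_significant = rep_sig,
                  recomputed_significant = rec_sig))
    }
  }
  gross <- !is.na(rep_sig) && rep_sig != rec_sig
  reason <- if (zero_claim) {
    "zero_p_convention"
  } else if (identical(p_op, "ns") && gross) {
    "ns_but_significant"
  } else if (gross) {
    "sign_flip"
  } else {
    "rounding_mismatch"
  }
  list(
    consistency = if (gross) "gross" else "inconsistent",
    reason = reason,
    one_tailed_applied = FALSE,
    reported_significant = rep_sig,
    recomputed_significant = rec_sig
  )
}
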
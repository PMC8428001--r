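# Seeded synthetic corpus with planted APA-style results and ground-truth
# verdict labels, for end-to-end validation of the extract -> recompute ->
# classify pipeline without any real articles.
#
# Ground-truth labels are computed here with local interval arithmetic
# (sc_* helpers) rather than by calling classify(), so the
# manifest-agreement check exercises two code paths.

#' Specification for a synthetic planted corpus
#'
#' Defaults emulate the reporting landscape the tool is aimed at:
#' the family mix follows the proportions of test families observed
#' across published meta-analyses (Z-tests dominate, then F, chi-square
#' and the Q heterogeneity family, with Q-within rare), and the error
#' mix approximates observed result-level inconsistency prevalence
#' (about 15% of results carry some reporting error, a small minority of
#' which flip the significance conclusion).
#'
#' @param n_docs Number of documents.
#' @param results_per_doc Fixed count, or length-2 range to draw from
#'   uniformly.
#' @param family_mix Named numeric vector of sampling weights over
#'   [test_families()].
#' @param error_rates Named probabilities over
#'   `none`, `rounding_slip`, `typo_digit`, `significance_flip`,
#'   `zero_p`; must sum to 1. `rounding_slip` perturbs the last printed
#'   p digit by one keeping the mismatch non-gross; `typo_digit` swaps
#'   one digit (may or may not be gross); `significance_flip` rewrites
#'   the p claim across alpha forcing a gross inconsistency; `zero_p`
#'   rewrites the claim as "p = .000".
#' @param one_tailed_doc_rate Probability a document mentions one-tailed
#'   testing (labels then account for the one-tailed rescue).
#' @param decoy_rate Probability a document receives non-APA decoy
#'   statements that must not be extracted.
#' @param formats Output formats cycled over documents.
#' @param alpha Significance level the planted labels are computed at.
#' @param seed Integer seed; a fixed seed yields a byte-identical corpus.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(n_docs = 20,
                       results_per_doc = c(2, 8),
                       family_mix = c(Z = 0.32, F = 0.18, chi2 = 0.14,
                                      Q_between = 0.11, Q = 0.11, t = 0.10,
                                      r = 0.03, Q_within = 0.01),
                       error_rates = c(none = 0.85, rounding_slip = 0.07,
                                       typo_digit = 0.04,
                                       significance_flip = 0.02,
                                       zero_p = 0.02),
                       one_tailed_doc_rate = 0.05,
                       decoy_rate = 0.3,
                       formats = c("txt", "html", "docx"),
                       alpha = 0.05,
                       seed = 1L) {
  stopifnot(
    n_docs >= 1,
    length(results_per_doc) %in% 1:2,
    all(names(family_mix) %in% test_families()),
    all(family_mix >= 0), sum(family_mix) > 0,
    setequal(names(error_rates),
             c("none", "rounding_slip", "typo_digit", "significance_flip",
               "zero_p")),
    all(error_rates >= 0 & error_rates <= 1),
    abs(sum(error_rates) - 1) < 1e-8,
    one_tailed_doc_rate >= 0, one_tailed_doc_rate <= 1,
    all(formats %in% c("txt", "html", "docx")),
    alpha > 0, alpha < 1
  )
  structure(
    list(n_docs = as.integer(n_docs), results_per_doc = results_per_doc,
         family_mix = family_mix, error_rates = error_rates,
         one_tailed_doc_rate = one_tailed_doc_rate, decoy_rate = decoy_rate,
         formats = formats, alpha = alpha, seed = as.integer(seed)),
    class = "plant_spec"
  )
}

# ---- local ground-truth arithmetic ----------------------------------------

round_half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d

sc_p <- function(family, s, df1, df2) {
  switch(family,
    t = 2 * pt(-abs(s), df1),
    Z = 2 * pnorm(-abs(s)),
    r = if (abs(s) >= 1) 0 else {
      2 * pt(-abs(s) * sqrt(df1 / (1 - s^2)), df1)
    },
    F = pf(s, df1, df2, lower.tail = FALSE),
    pchisq(s, df1, lower.tail = FALSE)
  )
}

sc_bounds <- function(family, s, sd_dec, df1, df2) {
  h <- 5 * 10^-(sd_dec + 1)
  ends <- c(s - h, s + h)
  if (family == "r") ends <- pmin(pmax(ends, -1), 1)
  p <- vapply(ends, sc_p, numeric(1), family = family, df1 = df1, df2 = df2)
  if (ends[1] < 0 && ends[2] > 0) p <- c(p, 1)
  c(lo = min(p), hi = max(p))
}

sc_claim_ok <- function(lo, hi, point, p_op, val, d, alpha) {
  if (p_op == "ns") return(point > alpha)
  if (p_op == "=") {
    if (val == 0) return(FALSE)
    h <- 5 * 10^-(d + 1)
    return(lo < val + h && val - h <= hi)
  }
  if (p_op == "<") return(lo < val)
  hi > val
}

sc_rep_sig <- function(p_op, val, alpha) {
  if (p_op == "ns") return(FALSE)
  if (p_op == "=") return(val < alpha)
  if (p_op == "<") return(if (val <= alpha) TRUE else NA)
  if (val >= alpha) FALSE else NA
}

sc_verdict <- function(family, s, sd_dec, df1, df2, p_op, val, d,
                       one_tailed, alpha) {
  b <- sc_bounds(family, s, sd_dec, df1, df2)
  point <- sc_p(family, s, df1, df2)
  if (sc_claim_ok(b["lo"], b["hi"], point, p_op, val, d, alpha)) {
    return("consistent")
  }
  if (one_tailed && family %in% c("t", "Z", "r") && !(p_op == "=" && val == 0) &&
      sc_claim_ok(b["lo"] / 2, b["hi"] / 2, point / 2, p_op, val, d, alpha)) {
    return("consistent")
  }
  rs <- sc_rep_sig(p_op, val, alpha)
  if (!is.na(rs) && rs != (point < alpha)) "gross" else "inconsistent"
}

# ---- drawing ---------------------------------------------------------------

sc_draw_base <- function(family, alpha) {
  for (k in 1:200) {
    df1 <- df2 <- NA_real_
    s <- switch(family,
      t = {df1 <- sample(5:200, 1); runif(1, 0.05, 3.2)},
      Z = runif(1, 0.05, 3.2),
      r = {df1 <- sample(10:300, 1); runif(1, 0.01, 0.6)},
      F = {df1 <- sample(1:10, 1); df2 <- sample(10:200, 1); runif(1, 0.05, 5)},
      {df1 <- sample(1:30, 1); runif(1, 0.1, df1 * 2.5)}  # chi2 / Q family
    )
    s <- round(s, 2)
    if (family %in% c("chi2", "Q", "Q_between", "Q_within", "F") && s <= 0) next
    if (family == "r" && abs(s) >= 1) next
    p <- sc_p(family, s, df1, df2)
    # keep recomputed p away from the alpha boundary for stable labels
    if (abs(p - alpha) <= 0.002) next
    return(list(family = family, s = s, df1 = df1, df2 = df2, p = p))
  }
  NULL
}

# returns list(p_op, val, d, verdict) or NULL when the transformation is
# impossible for this base draw
sc_make_claim <- function(base, error, one_tailed, alpha) {
  p <- base$p
  vd <- function(p_op, val, d) {
    sc_verdict(base$family, base$s, 2L, base$df1, base$df2, p_op, val, d,
               one_tailed, alpha)
  }
  if (error == "none") {
    d <- sample(2:3, 1)
    val <- round_half_up(p, d)
    if (val == 0) { d <- 3L; val <- round_half_up(p, d) }
    if (val == 0) {
      if (vd("<", 0.001, 3L) != "consistent") return(NULL)
      return(list(p_op = "<", val = 0.001, d = 3L, verdict = "consistent"))
    }
    if (vd("=", val, d) != "consistent") return(NULL)
    return(list(p_op = "=", val = val, d = d, verdict = "consistent"))
  }
  if (error == "rounding_slip") {
    d <- 2L
    val <- round_half_up(p, d)
    if (val <= 0 || val >= 1) return(NULL)
    for (delta in sample(c(0.01, -0.01))) {
      v2 <- round(val + delta, 2)
      if (v2 <= 0 || v2 >= 1) next
      if (vd("=", v2, d) == "inconsistent" &&
          identical(sc_rep_sig("=", v2, alpha), p < alpha)) {
        return(list(p_op = "=", val = v2, d = d, verdict = "inconsistent"))
      }
    }
    return(NULL)
  }
  if (error == "typo_digit") {
    d <- sample(2:3, 1)
    val <- round_half_up(p, d)
    if (val <= 0 || val >= 1) return(NULL)
    digits <- strsplit(sprintf("%.*f", d, val), "")[[1]]
    pos <- sample(seq_len(d), d) + 2L  # indices after "0."
    for (j in pos) {
      for (newd in sample(setdiff(as.character(0:9), digits[j]), 3)) {
        cand <- digits
        cand[j] <- newd
        v2 <- as.numeric(paste(cand, collapse = ""))
        if (v2 <= 0 || v2 > 1) next
        verdict <- vd("=", v2, d)
        if (verdict != "consistent") {
          return(list(p_op = "=", val = v2, d = d, verdict = verdict))
        }
      }
    }
    return(NULL)
  }
  if (error == "significance_flip") {
    d <- sample(2:3, 1)
    for (k in 1:20) {
      v2 <- if (p < alpha) {
        round_half_up(runif(1, alpha + 0.02, min(0.9, alpha + 0.5)), d)
      } else {
        round_half_up(runif(1, 0.005, alpha - 0.005), d)
      }
      if (v2 <= 0 || v2 >= 1) next
      if ((p < alpha) == (v2 < alpha)) next
      if (vd("=", v2, d) == "gross") {
        return(list(p_op = "=", val = v2, d = d, verdict = "gross"))
      }
    }
    return(NULL)
  }
  # zero_p: "p = .000" is an APA violation; gross only when the
  # significance conclusion also flips
  verdict <- vd("=", 0, 3L)
  list(p_op = "=", val = 0, d = 3L, verdict = verdict)
}

SC_LEADS <- c(
  "The pooled effect for this outcome was small, ",
  "Heterogeneity across the included studies was notable, ",
  "The moderator analysis for study setting yielded ",
  "For the secondary outcome we observed ",
  "The difference between subgroups of trials gave ",
  "Across sensitivity analyses the test result was "
)

SC_FILLER <- c(
  "We synthesized effect sizes with an inverse-variance weighted model.",
  "Study quality was assessed independently by two coders.",
  "Forest plots for each outcome appear in the appendix.",
  "Publication bias was examined with funnel plot asymmetry checks.",
  "Included trials were conducted in twelve countries."
)

SC_DECOYS <- c(
  "The studies were significantly heterogeneous according to the Q statistic (Q=35.72, 17 d.f., p<.0001).",
  "The intervention effect favoured treatment (SMD -0.32, 95% CI -0.63 to -0.01, P = 0.04).",
  "The pooled results indicate a moderate effect (d = .503, p = .03).",
  "For the night-only studies the RES was 1.01 (n.s.), indicating no effect.",
  "Residual heterogeneity remained (I2 = 56%; Tau2 = 0.33; Chi2= 6.80)."
)

#' Generate a synthetic corpus with ground-truth labels
#'
#' Writes `n_docs` article files (TXT/HTML/DOCX) of filler prose with
#' APA-style results planted via [format_result()], applies the error
#' transformations in `spec$error_rates`, and returns a manifest with one
#' row per planted result (and per decoy statement) carrying the true
#' verdict label. The manifest is also written to
#' `file.path(out_dir, "manifest.csv")`. The same seed reproduces the
#' corpus byte for byte.
#'
#' @param spec A [plant_spec()].
#' @param out_dir Writable output directory (created if missing).
#' @return The manifest tibble, invisibly columns: `doc_id`, `file`,
#'   `format`, `one_tailed`, `offset` (character position in the
#'   document's normalized text), `family`, `df1`, `df2`, `n`,
#'   `stat_value`, `stat_op`, `stat_decimals`, `p_op`, `p_value`,
#'   `p_decimals`, `planted_error`, `true_verdict`, `is_decoy`,
#'   `planted_text`.
#' @export
#' @examples
#' dir <- tempfile()
#' m <- generate_corpus(plant_spec(n_docs = 2, seed = 42), dir)
#' table(m$true_verdict)
generate_corpus <- function(spec, out_dir) {
  stopifnot(inherits(spec, "plant_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  rows <- list()
  for (i in seq_len(spec$n_docs)) {
    doc_id <- sprintf("doc%04d", i)
    fmt <- spec$formats[((i - 1L) %% length(spec$formats)) + 1L]
    one_tailed <- runif(1) < spec$one_tailed_doc_rate
    n_res <- if (length(spec$results_per_doc) == 1L) {
      spec$results_per_doc
    } else {
      sample(spec$results_per_doc[1]:spec$results_per_doc[2], 1)
    }
    lines <- sample(SC_FILLER, 2)
    if (one_tailed) {
      lines <- c(lines, "All significance tests reported below were one-tailed.")
    }
    doc_rows <- list()
    for (j in seq_len(n_res)) {
      planted <- NULL
      error <- sample(names(spec$error_rates), 1, prob = spec$error_rates)
      for (attempt in 1:25) {
        family <- sample(names(spec$family_mix), 1, prob = spec$family_mix)
        base <- sc_draw_base(family, spec$alpha)
        if (is.null(base)) next
        claim <- sc_make_claim(base, error, one_tailed, spec$alpha)
        if (!is.null(claim)) {
          planted <- list(base = base, claim = claim)
          break
        }
      }
      if (is.null(planted)) next  # bounded retries exhausted; skip slot
      base <- planted$base
      claim <- planted$claim
      nn <- if (base$family == "chi2" && runif(1) < 0.5) {
        sample(20:500, 1)
      } else NA_integer_
      res_tbl <- tibble::tibble(
        family = base$family, df1 = base$df1, df2 = base$df2, n = nn,
        stat_value = base$s, stat_op = "=", stat_decimals = 2L,
        p_op = claim$p_op, p_value = claim$val, p_decimals = claim$d
      )
      if (base$family == "Z") res_tbl$df1 <- NA_real_
      formatted <- format_result(res_tbl)
      lead <- sample(SC_LEADS, 1)
      line <- paste0(lead, formatted, ".")
      offset_in_line <- nchar(lead) + 1L
      lines <- c(lines, line)
      doc_rows[[length(doc_rows) + 1L]] <- dplyr::mutate(
        res_tbl,
        doc_id = doc_id, format = fmt, one_tailed = one_tailed,
        line_no = length(lines), offset_in_line = offset_in_line,
        planted_error = error, true_verdict = claim$verdict,
        is_decoy = FALSE, planted_text = formatted,
        .before = 1
      )
      if (runif(1) < 0.3) lines <- c(lines, sample(SC_FILLER, 1))
    }
    if (runif(1) < spec$decoy_rate) {
      for (d in sample(SC_DECOYS, sample(1:2, 1))) {
        lines <- c(lines, d)
        doc_rows[[length(doc_rows) + 1L]] <- tibble::tibble(
          doc_id = doc_id, format = fmt, one_tailed = one_tailed,
          line_no = length(lines), offset_in_line = 1L,
          family = NA_character_, df1 = NA_real_, df2 = NA_real_,
          n = NA_integer_, stat_value = NA_real_, stat_op = NA_character_,
          stat_decimals = NA_integer_, p_op = NA_character_,
          p_value = NA_real_, p_decimals = NA_integer_,
          planted_error = "decoy", true_verdict = NA_character_,
          is_decoy = TRUE, planted_text = d
        )
      }
    }
    file <- file.path(out_dir, paste0(doc_id, ".", fmt))
    switch(fmt,
      txt = writeLines(lines, file),
      html = writeLines(c(
        "<html><head><title>synthetic review</title></head><body>",
        paste0("<p>", xml_escape(lines), "</p>"),
        "</body></html>"
      ), file),
      docx = write_docx(lines, file)
    )
    if (length(doc_rows) > 0) {
      # character offset of each planted string in the document text
      starts <- c(0, cumsum(nchar(lines) + 1L))
      dr <- dplyr::bind_rows(doc_rows)
      dr$offset <- as.integer(starts[dr$line_no] + dr$offset_in_line)
      dr$file <- basename(file)
      rows[[length(rows) + 1L]] <- dr
    }
  }
  manifest <- dplyr::bind_rows(rows) |>
    dplyr::select(-"line_no", -"offset_in_line") |>
    dplyr::relocate("file", "offset", .after = "doc_id")
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
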
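# Document- and corpus-level summaries: prevalence of results, pooled and
# averaged-within-article inconsistency rates, per-family tables, and the
# significance-direction bias split.

#' Check one document end to end
#'
#' Runs the full pipeline -- ingest (if given a path), extract, recompute,
#' classify -- and tallies the verdicts for a single article.
#'
#' @param x A file path, a one-row tibble from [load_document()], or raw
#'   text (treated as a plain-text document).
#' @param config A [check_config()].
#' @param doc_id Document identifier used when `x` is raw text.
#' @param year Optional publication year (overrides the one in `x`).
#' @return An object of class `mc_report`: list with `doc_id`,
#'   `source_format`, `year`, `one_tailed_context`, `results` (classified
#'   tibble, see [classify()]), and `n_skipped`. Use [tidy()] for the
#'   per-result tibble and [glance()] for the one-row summary.
#' @export
#' @examples
#' rep <- check_text("We found t(28) = 0.32, p = .751 overall.")
#' glance(rep)
check_document <- function(x, config = check_config(), year = NULL) {
  doc <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
    load_document(x)
  } else if (is.data.frame(x)) {
    x
  } else {
    stop("`x` must be an existing file path or a document tibble; ",
         "use check_text() for raw text", call. = FALSE)
  }
  if (!is.null(year)) doc$year <- as.integer(year)
  results <- extract_results(doc)
  otc <- detect_one_tailed_context(doc)
  verdicts <- classify(results, one_tailed_context = otc, config = config)
  structure(
    list(
      doc_id = doc$doc_id,
      source_format = doc$source_format,
      year = doc$year,
      one_tailed_context = otc,
      results = verdicts,
      n_skipped = attr(results, "n_skipped") %||% 0L,
      config = config
    ),
    class = "mc_report"
  )
}

#' @rdname check_document
#' @param text Character string of article text.
#' @export
check_text <- function(text, config = check_config(), doc_id = "text",
                       year = NA_integer_) {
  doc <- tibble::tibble(
    doc_id = doc_id,
    text = normalize_text(text),
    source_format = "txt",
    year = as.integer(year)
  )
  check_document(doc, config = config)
}

#' Summarize one document's verdicts
#'
#' @param report An `mc_report` from [check_document()].
#' @return One-row tibble: `doc_id`, `n_results`, `n_inconsistent`
#'   (gross included), `n_gross`, `pct_inconsistent`, `pct_gross`
#'   (NA when no results), `one_tailed_context`, `year`.
#' @export
summarize_document <- function(report) {
  stopifnot(inherits(report, "mc_report"))
  v <- report$results
  n <- nrow(v)
  n_inc <- sum(v$consistency != "consistent")
  n_gross <- sum(v$consistency == "gross")
  tibble::tibble(
    doc_id = report$doc_id,
    n_results = n,
    n_inconsistent = n_inc,
    n_gross = n_gross,
    pct_inconsistent = if (n > 0) 100 * n_inc / n else NA_real_,
    pct_gross = if (n > 0) 100 * n_gross / n else NA_real_,
    one_tailed_context = report$one_tailed_context,
    year = report$year
  )
}

tally_by_family <- function(verdicts) {
  verdicts |>
    dplyr::mutate(family = factor(.data$family, levels = test_families())) |>
    dplyr::count(.data$family, .drop = FALSE, name = "extracted") |>
    dplyr::left_join(
      verdicts |>
        dplyr::group_by(.data$family) |>
        dplyr::summarise(
          inconsistent = sum(.data$consistency != "consistent"),
          gross = sum(.data$consistency == "gross")
        ),
      by = "family"
    ) |>
    tidyr::replace_na(list(inconsistent = 0L, gross = 0L)) |>
    dplyr::mutate(
      family = as.character(.data$family),
      pct_inconsistent = ifelse(.data$extracted > 0,
                                100 * .data$inconsistent / .data$extracted,
                                NA_real_),
      pct_gross = ifelse(.data$extracted > 0,
                         100 * .data$gross / .data$extracted, NA_real_)
    )
}

#' Check a corpus of documents
#'
#' @param x A directory containing article files (txt/html/docx/pdf), a
#'   character vector of file paths, or a list of `mc_report` objects.
#' @param config A [check_config()].
#' @param years Optional named integer vector or two-column data frame
#'   (`doc_id`, `year`) supplying publication years for the per-year
#'   prevalence series.
#' @return An object of class `mc_corpus`; see [summarize_corpus()] for
#'   its fields. [tidy()] gives the flat per-result records, [glance()]
#'   the one-row corpus summary, and [ggplot2::autoplot()] the per-year
#'   prevalence figure.
#' @export
check_corpus <- function(x, config = check_config(), years = NULL) {
  reports <- if (is.list(x) && all(vapply(x, inherits, logical(1), "mc_report"))) {
    x
  } else {
    paths <- if (length(x) == 1L && dir.exists(x)) {
      list.files(x, pattern = "(?i)\\.(txt|html?|docx|pdf)$",
                 full.names = TRUE)
    } else {
      as.character(x)
    }
    if (length(paths) == 0L) {
      stop("no supported article files found", call. = FALSE)
    }
    lapply(sort(paths), check_document, config = config)
  }
  if (!is.null(years)) {
    ytab <- if (is.data.frame(years)) {
      setNames(as.integer(years$year), years$doc_id)
    } else {
      setNames(as.integer(years), names(years))
    }
    for (i in seq_along(reports)) {
      y <- ytab[reports[[i]]$doc_id]
      if (!is.na(y)) reports[[i]]$year <- as.integer(y)
    }
  }
  summarize_corpus(reports)
}

#' Aggregate document reports into a corpus summary
#'
#' Computes both prevalence definitions: the pooled result-level rate
#' (`100 * sum(inconsistent) / sum(results)`) and the
#' averaged-within-article rate (mean over documents with at least one
#' result of each document's percentage, with its SD). The
#' significance-direction bias table splits results by the significance
#' of the claim *as reported* and gives both the gross rate and the full
#' inconsistency rate in each stratum; results with indeterminate
#' reported significance (e.g. "p < .10" at alpha .05) are excluded from
#' the bias denominators. The median number of results per document is
#' computed over documents with at least one extracted result.
#'
#' @param reports List of `mc_report` objects.
#' @return An `mc_corpus` object: list with `docs` (per-document summary
#'   rows), `results` (all classified results with `doc_id`), `summary`
#'   (one-row tibble of corpus-level fields), `per_family`, `bias`,
#'   `per_year`.
#' @export
summarize_corpus <- function(reports) {
  stopifnot(all(vapply(reports, inherits, logical(1), "mc_report")))
  docs <- dplyr::bind_rows(lapply(reports, summarize_document))
  if (nrow(docs) == 0L) {
    docs <- tibble::tibble(
      doc_id = character(), n_results = integer(),
      n_inconsistent = integer(), n_gross = integer(),
      pct_inconsistent = numeric(), pct_gross = numeric(),
      one_tailed_context = logical(), year = integer()
    )
  }
  results <- dplyr::bind_rows(lapply(reports, function(r) {
    if (nrow(r$results) == 0L) return(NULL)
    dplyr::mutate(r$results, doc_id = r$doc_id, .before = 1)
  }))
  n_docs <- nrow(docs)
  with_res <- docs[docs$n_results > 0, ]
  total_results <- sum(docs$n_results)
  total_inc <- sum(docs$n_inconsistent)
  total_gross <- sum(docs$n_gross)
  summary <- tibble::tibble(
    n_docs = n_docs,
    n_docs_with_results = nrow(with_res),
    pct_docs_with_results = if (n_docs > 0) 100 * nrow(with_res) / n_docs else NA_real_,
    total_results = total_results,
    median_results_per_doc = if (nrow(with_res) > 0) median(with_res$n_results) else NA_real_,
    n_docs_with_inconsistency = sum(docs$n_inconsistent > 0),
    pct_docs_with_inconsistency = if (nrow(with_res) > 0) {
      100 * sum(docs$n_inconsistent > 0) / nrow(with_res)
    } else NA_real_,
    n_docs_with_gross = sum(docs$n_gross > 0),
    pct_docs_with_gross = if (nrow(with_res) > 0) {
      100 * sum(docs$n_gross > 0) / nrow(with_res)
    } else NA_real_,
    result_level_pct_inconsistent = if (total_results > 0) {
      100 * total_inc / total_results
    } else NA_real_,
    result_level_pct_gross = if (total_results > 0) {
      100 * total_gross / total_results
    } else NA_real_,
    mean_within_doc_pct_inconsistent = if (nrow(with_res) > 0) {
      mean(with_res$pct_inconsistent)
    } else NA_real_,
    sd_within_doc_pct_inconsistent = if (nrow(with_res) > 1) {
      sd(with_res$pct_inconsistent)
    } else NA_real_,
    mean_within_doc_pct_gross = if (nrow(with_res) > 0) {
      mean(with_res$pct_gross)
    } else NA_real_,
    sd_within_doc_pct_gross = if (nrow(with_res) > 1) {
      sd(with_res$pct_gross)
    } else NA_real_
  )
  per_family <- if (nrow(results) > 0) {
    tally_by_family(results)
  } else {
    tibble::tibble(family = test_families(), extracted = 0L,
                   inconsistent = 0L, gross = 0L,
                   pct_inconsistent = NA_real_, pct_gross = NA_real_)
  }
  bias <- bias_table(results)
  per_year <- per_year_prevalence(docs)
  structure(
    list(docs = docs, results = results, summary = summary,
         per_family = per_family, bias = bias, per_year = per_year),
    class = "mc_corpus"
  )
}

# Gross and inconsistency rates split by reported-significance direction.
bias_table <- function(results) {
  empty <- tibble::tibble(
    reported_significant = c(TRUE, FALSE), n = 0L,
    n_gross = 0L, pct_gross = NA_real_,
    n_inconsistent = 0L, pct_inconsistent = NA_real_
  )
  if (is.null(results) || nrow(results) == 0L) return(empty)
  det <- results[!is.na(results$reported_significant), ]
  if (nrow(det) == 0L) return(empty)
  det |>
    dplyr::mutate(reported_significant = factor(.data$reported_significant,
                                                levels = c(TRUE, FALSE))) |>
    dplyr::group_by(.data$reported_significant, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_gross = sum(.data$consistency == "gross"),
      n_inconsistent = sum(.data$consistency != "consistent")
    ) |>
    dplyr::mutate(
      reported_significant = as.logical(.data$reported_significant),
      pct_gross = ifelse(.data$n > 0, 100 * .data$n_gross / .data$n, NA_real_),
      pct_inconsistent = ifelse(.data$n > 0,
                                100 * .data$n_inconsistent / .data$n,
                                NA_real_)
    ) |>
    dplyr::select("reported_significant", "n", "n_gross", "pct_gross",
                  "n_inconsistent", "pct_inconsistent")
}

per_year_prevalence <- function(docs) {
  dated <- docs[!is.na(docs$year), ]
  if (nrow(dated) == 0L) {
    return(tibble::tibble(year = integer(), n_docs = integer(),
                          n_docs_with_results = integer(),
                          prop_with_results = numeric()))
  }
  dated |>
    dplyr::group_by(year = .data$year) |>
    dplyr::summarise(
      n_docs = dplyr::n(),
      n_docs_with_results = sum(.data$n_results > 0)
    ) |>
    dplyr::mutate(prop_with_results = .data$n_docs_with_results / .data$n_docs) |>
    dplyr::arrange(.data$year)
}

#' Flat per-result records
#'
#' One row per extracted result with everything the consistency check
#' produced, ordered by `doc_id` then text offset -- the shape written by
#' [run_check()] as CSV/JSON.
#'
#' @param x An `mc_report` or `mc_corpus`.
#' @return A tibble with columns `doc_id`, `raw_span`, `family`, `df1`,
#'   `df2`, `n`, `statistic`, `stat_op`, `p_reported`, `p_op`,
#'   `p_decimals`, `p_recomputed` (full precision),
#'   `p_recomputed_display` (floor-truncated to 3 decimals, no leading
#'   zero), `consistency`, `reason`, `one_tailed_applied`, `offset`.
#' @export
result_records <- function(x) {
  v <- if (inherits(x, "mc_report")) {
    if (nrow(x$results) == 0L) {
      tibble::tibble()
    } else {
      dplyr::mutate(x$results, doc_id = x$doc_id, .before = 1)
    }
  } else if (inherits(x, "mc_corpus")) {
    x$results
  } else {
    stop("`x` must be an mc_report or mc_corpus", call. = FALSE)
  }
  if (is.null(v) || nrow(v) == 0L) {
    return(tibble::tibble(
      doc_id = character(), raw_span = character(), family = character(),
      df1 = numeric(), df2 = numeric(), n = integer(), statistic = numeric(),
      stat_op = character(), p_reported = numeric(), p_op = character(),
      p_decimals = integer(), p_recomputed = numeric(),
      p_recomputed_display = character(), consistency = character(),
      reason = character(), one_tailed_applied = logical(),
      offset = integer()
    ))
  }
  v |>
    dplyr::transmute(
      doc_id = .data$doc_id,
      raw_span = .data$raw_span,
      family = .data$family,
      df1 = .data$df1,
      df2 = .data$df2,
      n = .data$n,
      statistic = .data$stat_value,
      stat_op = .data$stat_op,
      p_reported = .data$p_value,
      p_op = .data$p_op,
      p_decimals = .data$p_decimals,
      p_recomputed = .data$p_recomputed,
      p_recomputed_display = p_display(.data$p_recomputed),
      consistency = .data$consistency,
      reason = .data$reason,
      one_tailed_applied = .data$one_tailed_applied,
      offset = .data$offset
    ) |>
    dplyr::arrange(.data$doc_id, .data$offset)
}
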
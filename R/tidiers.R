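# broom-style tidiers and plot methods for report and corpus objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a document report
#'
#' @param x An `mc_report` from [check_document()].
#' @param ... Unused.
#' @return The classified per-result tibble (see [classify()]) with a
#'   `doc_id` column.
#' @method tidy mc_report
#' @export
tidy.mc_report <- function(x, ...) {
  if (nrow(x$results) == 0L) return(x$results)
  dplyr::mutate(x$results, doc_id = x$doc_id, .before = 1)
}

#' @rdname tidy.mc_report
#' @method glance mc_report
#' @export
glance.mc_report <- function(x, ...) summarize_document(x)

#' Tidy a corpus summary
#'
#' @param x An `mc_corpus` from [check_corpus()].
#' @param ... Unused.
#' @return [tidy()] returns the flat per-result records
#'   ([result_records()]); [glance()] the one-row corpus summary.
#' @method tidy mc_corpus
#' @export
tidy.mc_corpus <- function(x, ...) result_records(x)

#' @rdname tidy.mc_corpus
#' @method glance mc_corpus
#' @export
glance.mc_corpus <- function(x, ...) x$summary

#' @export
print.mc_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<mc_report> %s (%s): %d result(s), %d inconsistent, %d grossly inconsistent\n",
    x$doc_id, x$source_format, g$n_results, g$n_inconsistent, g$n_gross
  ))
  if (x$one_tailed_context) cat("  one-tailed context detected\n")
  if (nrow(x$results) > 0) {
    print(dplyr::select(
      x$results, "raw_span", "p_recomputed", "consistency", "reason"
    ))
  }
  invisible(x)
}

#' @export
print.mc_corpus <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<mc_corpus> %d document(s), %d with APA results (%.1f%%)\n",
      "  %d results: %.1f%% inconsistent, %.1f%% grossly inconsistent (pooled)\n",
      "  averaged within documents: %.1f%% inconsistent, %.1f%% gross\n"
    ),
    s$n_docs, s$n_docs_with_results, s$pct_docs_with_results,
    s$total_results, s$result_level_pct_inconsistent,
    s$result_level_pct_gross, s$mean_within_doc_pct_inconsistent,
    s$mean_within_doc_pct_gross
  ))
  invisible(x)
}

#' Plot a document report
#'
#' Bar chart of extracted results per test family, filled by consistency
#' class.
#'
#' @param object An `mc_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mc_report
#' @export
autoplot.mc_report <- function(object, ...) {
  v <- object$results
  if (nrow(v) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No APA-style results extracted"))
  }
  v |>
    dplyr::mutate(
      family = factor(.data$family, levels = test_families()),
      consistency = factor(.data$consistency,
                           levels = c("consistent", "inconsistent", "gross"))
    ) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$family, fill = .data$consistency)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(
      values = c(consistent = "#2b8cbe", inconsistent = "#fdae61",
                 gross = "#d7191c"),
      drop = FALSE
    ) +
    ggplot2::labs(x = "test family", y = "results",
                  title = object$doc_id) +
    ggplot2::theme_minimal()
}

#' Plot corpus-level summaries
#'
#' `type = "trend"` draws the per-year prevalence of documents containing
#' at least one APA-style result (line = proportion per year, dot size =
#' number of documents); `type = "family"` draws per-family inconsistency
#' rates.
#'
#' @param object An `mc_corpus`.
#' @param type `"trend"` or `"family"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mc_corpus
#' @export
autoplot.mc_corpus <- function(object, type = c("trend", "family"), ...) {
  type <- match.arg(type)
  if (type == "trend") {
    py <- object$per_year
    if (nrow(py) == 0L) {
      return(ggplot2::ggplot() +
               ggplot2::labs(title = "No publication years supplied"))
    }
    return(
      ggplot2::ggplot(py, ggplot2::aes(x = .data$year,
                                       y = .data$prop_with_results)) +
        ggplot2::geom_line() +
        ggplot2::geom_point(ggplot2::aes(size = .data$n_docs)) +
        ggplot2::scale_y_continuous(limits = c(0, 1)) +
        ggplot2::labs(y = "proportion of documents with APA results",
                      size = "documents") +
        ggplot2::theme_minimal()
    )
  }
  pf <- object$per_family[object$per_family$extracted > 0, ]
  pf |>
    tidyr::pivot_longer(c("pct_inconsistent", "pct_gross"),
                        names_to = "rate", values_to = "pct") |>
    ggplot2::ggplot(ggplot2::aes(
      x = factor(.data$family, levels = test_families()),
      y = .data$pct, fill = .data$rate
    )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "test family", y = "% of results") +
    ggplot2::theme_minimal()
}
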
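#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a code database
#'
#' One row per code: ID, clade, parent ID, site, gene, state set and
#' plesiomorphic state.
#'
#' @param x a `code_db`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.code_db <- function(x, ...) x$codes

#' @rdname tidy.code_db
#' @export
glance.code_db <- function(x, ...) {
  depths <- vapply(x$terminals$name, function(nm) nrow(x$designed[[nm]]),
                   integer(1))
  tibble::tibble(n_codes = length(x$id_order),
                 n_terminals = nrow(x$terminals),
                 n_genes = length(unique(stats::na.omit(x$codes$gene))),
                 max_lineage_length = if (length(depths)) max(depths) else 0L)
}

#' Tidy a query evaluation
#'
#' @param x an `apo_query_eval` from [evaluate_queries()].
#' @param ... unused.
#' @return per-query tibble (`tidy`) or one-row category counts (`glance`).
#' @export
tidy.apo_query_eval <- function(x, ...) x$results

#' @rdname tidy.apo_query_eval
#' @export
glance.apo_query_eval <- function(x, ...) {
  cat_tab <- table(factor(x$results$category,
                          levels = c("positive", "false_negative",
                                     "false_positive", "negative")))
  tibble::tibble(n_queries = nrow(x$results),
                 positive = as.integer(cat_tab[["positive"]]),
                 false_negative = as.integer(cat_tab[["false_negative"]]),
                 false_positive = as.integer(cat_tab[["false_positive"]]),
                 negative = as.integer(cat_tab[["negative"]]),
                 complete_matches = sum(x$results$complete_match))
}

#' Plot the sequential code table of a database
#'
#' Terminal categories against code IDs; filled cells show the designed
#' state on each lineage, mirroring the two-dimensional table presentation
#' of hierarchical codes.
#'
#' @param object a `code_db`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.code_db <- function(object, ...) {
  tab <- export_code_table(object)
  long <- tidyr::pivot_longer(tab, -"terminal", names_to = "id",
                              values_to = "state")
  long <- dplyr::filter(long, nzchar(.data$state))
  long$id <- factor(long$id, levels = object$id_order)
  long$terminal <- factor(long$terminal, levels = rev(object$terminals$name))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$id, y = .data$terminal)) +
    ggplot2::geom_tile(fill = "grey92", colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$state), size = 3) +
    ggplot2::labs(x = "code ID (database order)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 7))
}

#' Plot query-evaluation category counts
#'
#' @param object an `apo_query_eval`.
#' @param ... unused.
#' @return a ggplot bar chart of the four assignment categories.
#' @export
autoplot.apo_query_eval <- function(object, ...) {
  d <- dplyr::count(object$results,
                    category = factor(.data$category,
                                      levels = c("positive", "false_negative",
                                                 "false_positive", "negative")),
                    .drop = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "queries") +
    ggplot2::theme_minimal()
}
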
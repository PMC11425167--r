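# ggplot2 views of run records, sigma distributions and the aux comparison.

#' Plot the hit distribution of one run record
#'
#' Bar chart of the 16 node-state counts, with the marked state highlighted.
#'
#' @param record A one-row run-record tibble.
#' @return A ggplot object.
#' @export
plot_hit_distribution <- function(record) {
  if (nrow(record) != 1L) {
    stop("`record` must be a single run record (one row)", call. = FALSE)
  }
  labs <- node_state_labels()
  df <- tibble::tibble(
    state = factor(labs, levels = labs),
    hits = as.integer(as.matrix(record[labs])[1, ]),
    marked = labs == record$mark
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$state, y = .data$hits,
                                   fill = .data$marked)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey55",
                                          `TRUE` = "firebrick"),
                               name = "marked") +
    ggplot2::labs(
      x = "node state", y = sprintf("hits / %d shots", record$shots),
      title = sprintf("init %s%s%s%s, mark %s",
                      record$aux, record$coin, record$node, record$theta,
                      record$mark)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot the sigma distribution of a census
#'
#' Histogram of per-record hit-distribution standard deviations with the
#' category boundaries drawn as vertical lines.
#'
#' @param census A [category_census()].
#' @param binwidth Histogram bin width (sigma units).
#' @return A ggplot object.
#' @export
plot_sigma_histogram <- function(census, binwidth = 1) {
  if (!inherits(census, "category_census")) {
    stop("`census` must be a category_census", call. = FALSE)
  }
  ggplot2::ggplot(census$record_sigma, ggplot2::aes(x = .data$sigma)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            color = "white") +
    ggplot2::geom_vline(xintercept = census$scheme$breaks,
                        linetype = "dashed", color = "grey30") +
    ggplot2::labs(x = "per-record sigma (hits)", y = "records",
                  title = "Hit-distribution standard deviations") +
    ggplot2::theme_minimal()
}

#' Plot the auxiliary-qubit hit-difference distribution
#'
#' @param x An [aux_effect()] object.
#' @param cumulative If `TRUE`, plot the cumulative distribution instead of
#'   the binned histogram.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.aux_effect <- function(x, cumulative = FALSE, ...) {
  if (cumulative) {
    ggplot2::ggplot(x$histogram,
                    ggplot2::aes(x = .data$midpoint, y = .data$cumulative)) +
      ggplot2::geom_step() +
      ggplot2::labs(x = "|hit difference| bin midpoint",
                    y = "cumulative fraction",
                    title = "aux = 0 vs aux = 1: cumulative hit differences") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(x$histogram,
                    ggplot2::aes(x = .data$midpoint, y = .data$n)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "|hit difference| bin midpoint", y = "count",
                    title = "aux = 0 vs aux = 1: per-state hit differences") +
      ggplot2::theme_minimal()
  }
}
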
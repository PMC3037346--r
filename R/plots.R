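#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a filter development trace
#'
#' Shows every candidate evaluation by development step: retrieval count
#' (or recall) on the y axis, with the selected path drawn as a line and
#' eliminated candidates marked. Alternative tie branches appear in
#' their own colour.
#'
#' @param object A `filter_trace`.
#' @param metric `"retrieved"` or `"recall_pct"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.filter_trace <- function(object, metric = c("retrieved", "recall_pct"), ...) {
  metric <- match.arg(metric)
  tr <- object$trace
  sel <- tr[tr$action == "selected", , drop = FALSE]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data[[metric]])) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$action, colour = .data$branch),
                        size = 2.5, alpha = 0.8) +
    ggplot2::geom_line(data = sel[sel$branch == "main", , drop = FALSE],
                       colour = "grey30") +
    ggplot2::geom_text(
      data = sel,
      ggplot2::aes(label = .data$term), vjust = -0.9, size = 3
    ) +
    ggplot2::scale_x_continuous(breaks = unique(tr$step)) +
    ggplot2::labs(
      x = "development step",
      y = if (metric == "retrieved") "records retrieved" else "recall (%)",
      shape = NULL, colour = "branch",
      title = "Greedy filter development trace"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a candidate term list against its cutoff
#'
#' Horizontal bar chart of record occurrence percentages with the cutoff
#' threshold drawn as a dashed line.
#'
#' @param candidates A candidate tibble (from [mesh_frequency()],
#'   [textword_frequency()] or [phrase_candidates()]).
#' @param cutoff Optional [cutoff_spec()] whose threshold is drawn.
#' @param top_n Show at most this many candidates (default 25).
#' @return A ggplot object.
#' @export
plot_candidates <- function(candidates, cutoff = NULL, top_n = 25) {
  d <- utils::head(candidates, top_n)
  d$term <- factor(d$term, levels = rev(d$term))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$occurrence_pct, y = .data$term,
                                       fill = .data$scope)) +
    ggplot2::geom_col(alpha = 0.9) +
    ggplot2::labs(x = "record occurrence (%)", y = NULL, fill = "field scope",
                  title = "Candidate term record occurrence") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(
      xintercept = 100 * cutoff$min_count / cutoff$set_size,
      linetype = "dashed", colour = "grey40"
    )
  }
  p
}
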
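#' @export
autoplot.berry_design <- function(object, ...) {
  df <- as.data.frame(object)
  if (ncol(df) < 2) abort("need at least two dimensions to plot a design.")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x1, y = .data$x2)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(title = "Design points (first two factors)",
                  x = "x1", y = "x2") +
    ggplot2::theme_minimal()
}

#' Plot main-effect curves
#'
#' One panel per response, one line per factor: the mean predicted response
#' as each normalized factor moves across its range.
#'
#' @param object A `main_effects` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.main_effects <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$level, y = .data$mean,
                                       colour = .data$factor)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~response, scales = "free_y") +
    ggplot2::labs(x = "normalized factor level", y = "mean predicted response",
                  colour = "factor", title = "Main-effect curves") +
    ggplot2::theme_minimal()
}

#' Plot signed Pareto term contributions
#'
#' Horizontal Pareto chart per response: term influence shares with the
#' association direction encoded by fill.
#'
#' @param object A `contribution_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contribution_table <- function(object, ...) {
  df <- dplyr::mutate(object,
                      direction = ifelse(.data$sign > 0, "positive", "negative"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$percent,
                                   y = stats::reorder(.data$term, .data$percent),
                                   fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~response) +
    ggplot2::labs(x = "contribution (%)", y = NULL, fill = "association",
                  title = "Pareto term contributions") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pareto_archive <- function(object, ...) {
  df <- tidy(object)
  obj_names <- colnames(object$objectives)
  if (length(obj_names) < 2) abort("need at least two objectives to plot.")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[obj_names[1]]],
                                   y = .data[[obj_names[2]]])) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$crowding)) +
    ggplot2::labs(title = "Pareto archive (first two objectives)") +
    ggplot2::theme_minimal()
}
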
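# ggplot2 visualisations of the package's result types.

#' Learning-curve plot (mean accuracy with SEM bars per method)
#'
#' @param object a `benchmark_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.benchmark_result <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$n_train, y = .data$mean_accuracy,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$sem,
                   ymax = .data$mean_accuracy + .data$sem),
      width = 0.3, alpha = 0.6) +
    ggplot2::labs(x = "Number of training examples",
                  y = "Mean classification accuracy",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' Information-gain trajectory of an active-learning run
#'
#' @param object an `al_state`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.al_state <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration,
                               y = .data$information_gain)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Iteration", y = "Information gain (log det FIM)") +
    ggplot2::theme_minimal()
}

#' Per-tumor analyte summary plot (median dot, 25th-75th percentile bars)
#'
#' @param object an `analyte_report`.
#' @param quantity `"positive_fraction"` or `"class_fraction"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.analyte_report <- function(object,
                                    quantity = "positive_fraction", ...) {
  dat <- dplyr::filter(object$per_tumor, .data$quantity == !!quantity)
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$tumor_id),
                                    y = .data$median)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                           width = 0.2) +
    ggplot2::labs(x = "Tumor", y = quantity) +
    ggplot2::theme_minimal()
}

#' Display a label map with ggplot2
#'
#' @param labels integer label map.
#' @return a ggplot object (background blank, one colour per nucleus).
#' @export
plot_label_map <- function(labels) {
  df <- tidyr::expand_grid(row = seq_len(nrow(labels)),
                           col = seq_len(ncol(labels)))
  df$id <- as.vector(t(labels))  # expand_grid varies col fastest
  df <- dplyr::filter(df, .data$id > 0L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = factor(.data$id))) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @keywords internal
NULL
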
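#' Plot age-model accuracy against tolerance
#'
#' One line per age model showing the proportion of known-age animals
#' classified within 0, 1, 2, ... days of their true age class.
#'
#' @param accuracy Accuracy tibble(s) from [accuracy_table()] (bind rows of
#'   several models to compare them).
#' @return A ggplot object.
#' @export
plot_accuracy <- function(accuracy) {
  ggplot2::ggplot(accuracy, ggplot2::aes(
    .data$tolerance, .data$proportion,
    colour = .data$model_name, group = .data$model_name
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1), labels = function(x) 100 * x) +
    ggplot2::labs(
      x = "Tolerance (days)", y = "Correctly classified (%)",
      colour = "Age model"
    ) +
    ggplot2::theme_minimal()
}
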
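#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
generics::tidy

#' @export
generics::glance

#' Plot concept trajectories of a simulation
#'
#' One line per concept over iteration steps.
#'
#' @param object An `fcm_trace`.
#' @param concepts Optional subset of concepts to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fcm_trace <- function(object, concepts = NULL, ...) {
  df <- tidy(object)
  if (!is.null(concepts)) {
    df <- dplyr::filter(df, .data$concept %in% concepts)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$step, .data$value,
                                   colour = .data$concept)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "activation", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' Outcome level versus the swept concept's initial value, one line per
#' concept.
#'
#' @param object An `fcm_sweep` tibble or a list of them.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fcm_sweep <- function(object, ...) {
  if (!is.data.frame(object)) object <- dplyr::bind_rows(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$initial, .data$outcome_value,
                                       colour = .data$concept)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "initial value of swept concept",
                  y = "outcome level", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Box-plot comparison of sweep results
#'
#' @param results A list of `fcm_sweep` tibbles (or one).
#' @return A ggplot object: one box of outcome values per swept concept.
#' @export
plot_sweep_boxes <- function(results) {
  if (inherits(results, "fcm_sweep")) results <- list(results)
  df <- dplyr::bind_rows(lapply(results, tibble::as_tibble))
  ggplot2::ggplot(df, ggplot2::aes(.data$concept, .data$outcome_value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "outcome level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
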
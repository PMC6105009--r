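#' Plot belief and relevance trajectories
#'
#' Two panels: the first-level association predictions of both branches and
#' the relevance weights over trials.
#'
#' @param object an `"hgf_trajectories"` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot hgf_trajectories
#' @export
autoplot.hgf_trajectories <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(trial = object$trial, branch = "color",
                   `association belief` = object$mu1hat_color,
                   `relevance weight` = object$rel_color),
    tibble::tibble(trial = object$trial, branch = "shape",
                   `association belief` = object$mu1hat_shape,
                   `relevance weight` = object$rel_shape)) |>
    tidyr::pivot_longer(c("association belief", "relevance weight"),
                        names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(.data$trial, .data$value,
                                     colour = .data$branch)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "trial", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot model posterior and protected exceedance probabilities
#'
#' @param object a `"bms_result"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot bms_result
#' @export
autoplot.bms_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$models, c("pp", "pxp"),
                              names_to = "measure")
  ggplot2::ggplot(long, ggplot2::aes(.data$model_id, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~measure, ncol = 1) +
    ggplot2::labs(x = NULL, y = "probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot recovered against generating parameter values
#'
#' @param object a `"recovery_report"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot recovery_report
#' @export
autoplot.recovery_report <- function(object, ...) {
  ggplot2::ggplot(object$values,
                  ggplot2::aes(.data$true, .data$recovered)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "generating value", y = "recovered value") +
    ggplot2::theme_minimal()
}
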
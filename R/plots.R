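#' Plot the cross-validation trace of a fitted index
#'
#' Cross-validated Harrell c-index against the penalty (log scale), with the
#' chosen penalty marked.
#'
#' @param object An `mdci_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mdci_fit <- function(object, ...) {
  df <- tibble::tibble(lambda = object$lambda, cv_cindex = object$cv_cindex)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$cv_cindex)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$chosen_lambda, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "penalty (lambda, log scale)",
      y = "cross-validated c-index",
      title = "Penalty selection",
      subtitle = sprintf("chosen lambda = %.4g, CV c-index = %.3f",
                         object$chosen_lambda, max(object$cv_cindex))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a calibration curve
#'
#' Observed Kaplan-Meier survival against mean predicted survival per
#' predicted-probability bin, with the identity line.
#'
#' @param object An `mdci_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mdci_calibration <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_predicted, y = .data$observed_km)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::coord_equal(xlim = 0:1, ylim = 0:1) +
    ggplot2::labs(
      x = sprintf("mean predicted %d-year survival", attr(object, "horizon_years")),
      y = sprintf("observed %d-year survival (KM)", attr(object, "horizon_years")),
      size = "subjects",
      title = "Calibration"
    ) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by index category
#'
#' @param categories Factor of index categories (e.g. quartiles).
#' @param time,event Observed outcome.
#' @return A ggplot of the stratified survival curves.
#' @export
plot_km_by_category <- function(categories, time, event) {
  categories <- factor(categories)
  curves <- lapply(levels(categories), function(lv) {
    idx <- categories == lv
    km <- kaplan_meier(time[idx], event[idx])
    tibble::tibble(
      category = lv,
      time = c(0, km$time / 365.25),
      surv = c(1, km$surv)
    )
  })
  df <- dplyr::bind_rows(curves)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$category)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "years since index date", y = "survival",
                  colour = "index category") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
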
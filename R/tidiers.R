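#' Tidy a fitted comorbidity index
#'
#' One row per selected predictor: the code variant, the predictor dimension
#' and its coefficient (log hazard ratio).
#'
#' @param x An `mdci_fit`.
#' @param ... Unused.
#' @return Tibble with columns `variant`, `dimension`, `name`, `coefficient`.
#' @export
tidy.mdci_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a fitted comorbidity index
#'
#' @param x An `mdci_fit`.
#' @param ... Unused.
#' @return One-row tibble: cohort size, events, candidate and selected
#'   predictor counts, mixing weight, chosen penalty and its CV c-index.
#' @export
glance.mdci_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects,
    n_events = x$n_events,
    n_candidate = length(x$beta),
    n_selected = nrow(x$coefficients),
    n_variants_selected = length(unique(x$coefficients$variant)),
    alpha = x$alpha,
    chosen_lambda = x$chosen_lambda,
    cv_cindex = max(x$cv_cindex)
  )
}

#' @rdname tidy.mdci_fit
#' @export
tidy.mdci_calibration <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$horizon_years <- attr(x, "horizon_years")
  out
}

#' @rdname tidy.mdci_fit
#' @export
tidy.mdci_km <- function(x, ...) tibble::as_tibble(x)
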
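#' Harrell's concordance index
#'
#' Probability that, of a usable subject pair, the subject with the higher
#' risk score dies first. A pair is usable when the ordering of death times
#' is determinable under censoring (the earlier observed time is an event;
#' tied times are usable only when exactly one is an event). Score ties
#' count 0.5.
#'
#' @param scores Risk scores (higher = higher predicted mortality).
#' @param time,event Observed follow-up time and 0/1 event indicator.
#' @return Concordance in `[0, 1]`.
#' @export
harrell_cindex <- function(scores, time, event) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  cnt <- .cindex_counts(as.numeric(scores), as.numeric(time), as.integer(event))
  if (cnt[2] == 0) abort("No usable pairs: concordance is undefined.")
  cnt[1] / cnt[2]
}

#' Percentile bootstrap confidence interval
#'
#' Resamples subjects (rows) with replacement and returns the percentile
#' interval of a statistic. Resamples on which the statistic is undefined
#' (error or `NA`) are redrawn and counted.
#'
#' @param statistic_fn Function of a resampled `data` returning a scalar.
#' @param data Vector or data frame; resampling is over elements/rows.
#' @param n_boot Number of bootstrap replications (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed (required: the interval is deterministic given
#'   the seed).
#' @return Named numeric `c(low, high)`, with attributes `n_redrawn` and
#'   `estimates` (the bootstrap distribution).
#' @export
bootstrap_ci <- function(statistic_fn, data, n_boot = 1000, level = 0.95,
                         seed = NULL) {
  if (n_boot < 2) abort("`n_boot` must be at least 2.")
  if (is.null(seed)) abort("`seed` is required for the bootstrap.")
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  take <- function(idx) {
    if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
  }
  with_local_seed(seed, {
    est <- numeric(n_boot)
    redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        val <- tryCatch(statistic_fn(take(sample.int(n, n, replace = TRUE))),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        redrawn <- redrawn + 1L
        if (redrawn > 10L * n_boot) {
          abort("Statistic undefined on too many bootstrap resamples.")
        }
      }
      est[b] <- val
    }
    alpha <- (1 - level) / 2
    out <- unname(quantile(est, c(alpha, 1 - alpha)))
    structure(c(low = out[1], high = out[2]),
              n_redrawn = redrawn, estimates = est)
  })
}

#' Kaplan-Meier product-limit estimator
#'
#' Thin wrapper around [survival::survfit()] returning the survival step
#' function as a tidy table; `S(0) = 1` and the curve is right-continuous.
#'
#' @param time,event Follow-up time and 0/1 event indicator.
#' @return Object of class `mdci_km`: tibble with `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`.
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0L) abort("Empty input: no survival data.")
  if (any(time < 0)) abort("Survival times must be nonnegative.")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- tibble::tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv
  )
  class(out) <- c("mdci_km", class(out))
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km An `mdci_km` from [kaplan_meier()].
#' @param t Times at which to evaluate the (right-continuous) step function.
#' @return Numeric vector of survival probabilities; `NA` beyond the last
#'   observed time when the curve is undefined there (last subject was
#'   censored before `t`).
#' @export
km_survival_at <- function(km, t) {
  last_i <- which.max(km$time)
  # beyond the last observed time the estimator is undefined unless the
  # curve already reached zero
  undefined_beyond <- km$surv[last_i] > 0
  vapply(t, function(tt) {
    idx <- which(km$time <= tt)
    if (!length(idx)) return(1)
    if (tt > km$time[last_i] && undefined_beyond) return(NA_real_)
    km$surv[max(idx)]
  }, numeric(1))
}

#' Calibration curve for an index score
#'
#' Fits a one-covariate Cox proportional hazards model with the index score
#' as predictor on the evaluation cohort, computes each subject's predicted
#' survival at the horizon from the Breslow baseline hazard, bins subjects
#' by predicted survival at fixed cutoffs, and compares the per-bin mean
#' predicted survival with the observed Kaplan-Meier survival at the horizon
#' within the bin. Bins containing zero subjects are omitted.
#'
#' @param scores Index scores of the evaluation cohort.
#' @param time,event Observed outcome of the evaluation cohort.
#' @param horizon_years Prediction horizon (default 10).
#' @param bin_edges Predicted-survival cutoffs; default
#'   `c(0, .50, .55, .60, .65, .70, .75, .80, .85, .90, 1)`.
#' @return Object of class `mdci_calibration`: tibble with `bin`, `n`,
#'   `mean_predicted`, `observed_km`, plus attributes `horizon_years`,
#'   `bin_edges`, `cox_coef` and `baseline_cumhaz`.
#' @export
calibration_curve <- function(scores, time, event, horizon_years = 10,
                              bin_edges = c(0, seq(0.50, 0.90, by = 0.05), 1)) {
  stopifnot(length(scores) == length(time), length(time) == length(event))
  h <- lookback_days(horizon_years)
  if (stats::sd(scores) == 0) {
    # constant scores: the one-covariate model degenerates to the null model
    fit <- survival::coxph(survival::Surv(time, event) ~ 1, ties = "breslow")
    beta <- 0
  } else {
    fit <- survival::coxph(survival::Surv(time, event) ~ scores, ties = "breslow")
    beta <- unname(coef(fit)[1])
  }
  bh <- survival::basehaz(fit, centered = FALSE)
  at_h <- which(bh$time <= h)
  if (!length(at_h)) abort("Horizon precedes the first observed event time.")
  H0 <- bh$hazard[max(at_h)]
  pred <- exp(-H0 * exp(beta * scores))

  bin <- cut(pred, breaks = bin_edges, include.lowest = TRUE, right = TRUE)
  rows <- lapply(levels(bin)[tabulate(bin, nbins = nlevels(bin)) > 0], function(b) {
    in_bin <- which(bin == b)
    km <- kaplan_meier(time[in_bin], event[in_bin])
    obs <- km_survival_at(km, h)
    tibble::tibble(
      bin = b, n = length(in_bin),
      mean_predicted = mean(pred[in_bin]),
      observed_km = obs
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(
    out,
    class = c("mdci_calibration", class(out)),
    horizon_years = horizon_years,
    bin_edges = bin_edges,
    cox_coef = beta,
    baseline_cumhaz = H0
  )
}

#' Hazard ratios across index categories, within strata
#'
#' Within each stratum, fits an unpenalized Cox model of the index category
#' (reference `Q1`) on mortality censored at `followup_years`, and reports
#' hazard ratios with Wald 95% confidence intervals. A contrast is reported
#' `NA` when either arm has fewer than `min_events` events (the minimum-
#' events rule), or when the model cannot be fit.
#'
#' @param categories Factor of index categories (`Q1`-`Q4`) per subject.
#' @param strata Factor/vector of stratum labels per subject (use a single
#'   constant for an unstratified analysis).
#' @param time,event Observed outcome.
#' @param followup_years Follow-up horizon for the hazard ratios (default 1).
#' @param min_events Minimum events per contrast arm (default 5).
#' @return Tibble with `stratum`, `contrast`, `hr`, `ci_low`, `ci_high`,
#'   `n`, `events`, `status` (`"estimated"` or `"NA"`).
#' @export
stratified_hazard_ratios <- function(categories, strata, time, event,
                                     followup_years = 1, min_events = 5) {
  stopifnot(length(categories) == length(time))
  categories <- factor(categories)
  ref <- levels(categories)[1]
  cens <- horizon_censor(time, event, followup_years)
  strata <- factor(strata)

  rows <- list()
  for (s in levels(strata)) {
    in_s <- strata == s
    for (lev in setdiff(levels(categories), ref)) {
      arm <- in_s & categories %in% c(ref, lev)
      n_arm <- sum(arm)
      ev_ref <- sum(cens$event[in_s & categories == ref])
      ev_lev <- sum(cens$event[in_s & categories == lev])
      row <- tibble::tibble(
        stratum = s, contrast = paste(lev, "vs", ref),
        hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        n = n_arm, events = ev_ref + ev_lev, status = "NA"
      )
      if (ev_ref >= min_events && ev_lev >= min_events) {
        dat <- data.frame(
          time = cens$time_days[arm], event = cens$event[arm],
          grp = droplevels(factor(categories[arm], levels = c(ref, lev)))
        )
        fit <- tryCatch(
          survival::coxph(survival::Surv(time, event) ~ grp, data = dat,
                          ties = "breslow"),
          error = function(e) NULL, warning = function(w) NULL
        )
        if (!is.null(fit) && is.finite(coef(fit)[1])) {
          b <- coef(fit)[1]
          se <- sqrt(diag(fit$var))[1]
          row$hr <- exp(b)
          row$ci_low <- exp(b - 1.96 * se)
          row$ci_high <- exp(b + 1.96 * se)
          row$status <- "estimated"
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  dplyr::bind_rows(rows)
}

#' Correlation between two comorbidity indices
#'
#' Rank (Spearman) correlation by default, since index scores are used
#' ordinally; Pearson available.
#'
#' @param scores_a,scores_b Numeric score vectors of equal length (>= 3).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
index_correlation <- function(scores_a, scores_b,
                              method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(scores_a) != length(scores_b) || length(scores_a) < 3) {
    abort("Score vectors must have equal length >= 3.")
  }
  if (stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0) {
    abort("Correlation undefined: at least one score vector is constant.")
  }
  cor(scores_a, scores_b, method = method)
}
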
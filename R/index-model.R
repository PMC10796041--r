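# extract (matrix, column metadata) from an mdci_design or a bare matrix
as_design_matrix <- function(x) {
  if (inherits(x, "mdci_design")) {
    list(matrix = x$matrix, columns = x$columns)
  } else {
    cols <- tibble::tibble(
      variant = NA_character_, dimension = NA_character_,
      name = colnames(x) %||% paste0("x", seq_len(ncol(x)))
    )
    list(matrix = x, columns = cols)
  }
}

#' Restrict a design matrix to selected predictor dimensions
#'
#' Used e.g. to build an occurrence-only comparator index by keeping only the
#' `occ_any` columns.
#'
#' @param design An `mdci_design`.
#' @param dimensions Character vector of dimension names to keep.
#' @return An `mdci_design` with the column subset.
#' @export
select_dimensions <- function(design, dimensions) {
  stopifnot(inherits(design, "mdci_design"))
  keep <- design$columns$dimension %in% dimensions
  structure(
    list(
      matrix = design$matrix[, keep, drop = FALSE],
      columns = design$columns[keep, , drop = FALSE],
      lookback_years = design$lookback_years
    ),
    class = "mdci_design"
  )
}

#' Breslow partial log-likelihood of a Cox model
#'
#' Computes the Cox partial log-likelihood with Breslow handling of tied
#' event times, and optionally its gradient (via the martingale-residual
#' identity, so it is cheap even for wide sparse designs).
#'
#' @param x Design matrix (dense or sparse) or `mdci_design`.
#' @param beta Coefficient vector, length `ncol(x)`.
#' @param time,event Survival outcome: follow-up time and 0/1 event indicator.
#' @param gradient If `TRUE`, attach the score vector as attribute
#'   `"gradient"`.
#' @return The partial log-likelihood (a scalar).
#' @export
cox_partial_loglik <- function(x, beta, time, event, gradient = FALSE) {
  d <- as_design_matrix(x)
  X <- d$matrix
  stopifnot(length(beta) == ncol(X), length(time) == nrow(X), length(event) == nrow(X))
  if (!any(event == 1)) abort("No events in the data; partial likelihood undefined.")
  eta <- as.numeric(X %*% beta)
  ord <- order(time, decreasing = TRUE)     # risk sets by cumulative sums
  w <- exp(eta)[ord]
  t_ord <- time[ord]
  d_ord <- event[ord]
  cum_w <- cumsum(w)
  # S0 at each subject's own time: sum of w over subjects with t_j >= t_i.
  # With decreasing order and ties, take the last index of each tie block.
  last_of_block <- cumsum(rle(t_ord)$lengths)
  block_id <- rep(seq_along(last_of_block), rle(t_ord)$lengths)
  s0 <- cum_w[last_of_block][block_id]
  ll <- sum(d_ord * (eta[ord] - log(s0)))
  if (gradient) {
    # grad = X'(d - exp(eta) * H0(t)), H0 the Breslow cumulative hazard
    events_per_block <- vapply(
      split(d_ord, block_id), sum, numeric(1)
    )
    s0_block <- cum_w[last_of_block]
    # blocks are ordered by decreasing time; H0(t) sums d_s/S0(s) over s <= t
    inc <- events_per_block / s0_block
    H0_block <- rev(cumsum(rev(inc)))
    H0 <- H0_block[block_id]
    resid <- d_ord - exp(eta[ord]) * H0
    g <- numeric(length(resid))
    g[ord] <- resid
    attr(ll, "gradient") <- as.numeric(Matrix::crossprod(X, g))
  }
  ll
}

# deterministic fold assignment, stratified on the event indicator
make_folds <- function(event, nfolds, seed) {
  with_local_seed(seed, {
    foldid <- integer(length(event))
    for (g in c(0L, 1L)) {
      idx <- which(event == g)
      foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
    foldid
  })
}

#' Fit the elastic-net Cox comorbidity index
#'
#' Fits an elastic-net-penalized Cox proportional hazards model (Breslow
#' ties) over a log-spaced grid of `n_lambda` penalty values starting at the
#' smallest penalty giving the all-zero solution, selects the penalty by
#' k-fold cross-validation maximizing the held-out Harrell concordance index
#' (fold-wise c-indices averaged with event-count weights; ties broken toward
#' the larger penalty, i.e. the sparser model), and refits on all data at the
#' chosen penalty. Folds are stratified on the event indicator and
#' deterministic given `seed`. Coordinate-descent solving is delegated to
#' glmnet with convergence threshold `1e-7`.
#'
#' @param x Design matrix (`mdci_design` or sparse/dense matrix).
#' @param time,event Survival outcome (days from index date, 0/1 indicator),
#'   already censored at the modelling horizon (see [horizon_censor()]).
#' @param alpha Elastic-net mixing weight in (0,1]; `1` is the lasso,
#'   default `0.5`.
#' @param n_lambda Number of penalty values (default 100).
#' @param n_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed for fold assignment (required).
#' @param standardize Standardize predictors internally for penalization
#'   (coefficients are returned on the original 0/1 scale); default `TRUE`.
#' @param lambda_min_ratio Smallest penalty as a fraction of the largest
#'   (default 0.01).
#' @param thresh Coordinate-descent convergence tolerance for the final path
#'   (default 1e-7).
#' @param cv_thresh Convergence tolerance for the fold fits, which only rank
#'   penalties (default 1e-5).
#' @param horizon_years Stored as metadata (default 10).
#' @return An object of class `mdci_fit` with elements `beta` (named sparse
#'   coefficient vector at the chosen penalty), `coefficients` (tibble of the
#'   selected predictors: `variant`, `dimension`, `name`, `coefficient`),
#'   `lambda` (the full grid), `cv_cindex` (per-lambda cross-validated
#'   c-index), `chosen_lambda`, `alpha`, `quartile_cutoffs` (25/50/75%
#'   development-cohort score quantiles), `columns`, `foldid`, and metadata.
#' @export
fit_penalized_cox <- function(x, time, event, alpha = 0.5, n_lambda = 100,
                              n_folds = 10, seed = NULL, standardize = TRUE,
                              lambda_min_ratio = 0.01, thresh = 1e-7,
                              cv_thresh = 1e-5, horizon_years = 10) {
  d <- as_design_matrix(x)
  X <- d$matrix
  n <- nrow(X)
  stopifnot(length(time) == n, length(event) == n)
  if (!any(event == 1)) abort("All observations are censored; cannot fit a Cox model.")
  if (n < n_folds) abort("Fewer subjects than cross-validation folds.")
  if (is.null(seed)) abort("`seed` is required for fold assignment.")

  # glmnet's Cox path iterates much faster on a dense matrix; densify while
  # that stays comfortably in memory
  if (inherits(X, "sparseMatrix") && prod(dim(X)) <= 1.5e8) {
    X <- as.matrix(X)
  }

  y <- survival::Surv(time, event)
  # a predictor with fewer than two positive subjects in the data a fit sees
  # is unidentifiable and numerically fragile once standardized; such columns
  # are excluded from that fit (their coefficient is zero)
  too_rare <- function(M) which(Matrix::colSums(M) < 2)

  # one shallow pilot fit to locate lambda_max (a deep pilot path would be
  # wasted work), then an explicit 100-value grid so the path never
  # terminates early
  pilot <- glmnet::glmnet(
    X, y, family = "cox", alpha = alpha, nlambda = 3, lambda.min.ratio = 0.5,
    standardize = standardize, thresh = thresh, exclude = too_rare(X)
  )
  lambda_max <- pilot$lambda[1]
  grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = n_lambda))

  full <- glmnet::glmnet(
    X, y, family = "cox", alpha = alpha, lambda = grid,
    standardize = standardize, thresh = thresh, exclude = too_rare(X)
  )

  foldid <- make_folds(event, n_folds, seed)
  cv <- matrix(NA_real_, nrow = n_folds, ncol = length(grid))
  fold_events <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    test <- foldid == f
    if (!any(event[!test] == 1) || !any(event[test] == 1)) {
      abort("A cross-validation fold has no events; reduce `n_folds`.")
    }
    X_tr <- X[!test, , drop = FALSE]
    fit_f <- glmnet::glmnet(
      X_tr, y[!test, ], family = "cox", alpha = alpha,
      lambda = grid, standardize = standardize, thresh = cv_thresh,
      exclude = too_rare(X_tr)
    )
    lp <- predict(fit_f, newx = X[test, , drop = FALSE], s = grid)
    fold_events[f] <- sum(event[test])
    cv[f, ] <- apply(lp, 2, function(s) {
      harrell_cindex(s, time[test], event[test])
    })
  }
  cv_cindex <- as.numeric(colSums(cv * fold_events) / sum(fold_events))

  best <- max(cv_cindex)
  chosen_idx <- min(which(cv_cindex == best))  # grid is decreasing: ties -> larger lambda
  chosen_lambda <- grid[chosen_idx]

  beta <- as.numeric(coef(full, s = chosen_lambda, exact = FALSE))
  names(beta) <- d$columns$name
  scores <- as.numeric(X %*% beta)
  cutoffs <- unname(quantile(scores, c(0.25, 0.50, 0.75)))

  sel <- which(beta != 0)
  coefficients <- tibble::tibble(
    variant = d$columns$variant[sel],
    dimension = d$columns$dimension[sel],
    name = d$columns$name[sel],
    coefficient = beta[sel]
  )

  structure(
    list(
      beta = beta,
      coefficients = coefficients,
      path = full,
      lambda = grid,
      cv_cindex = cv_cindex,
      chosen_lambda = chosen_lambda,
      alpha = alpha,
      quartile_cutoffs = cutoffs,
      columns = d$columns,
      foldid = foldid,
      n_folds = n_folds,
      seed = seed,
      standardize = standardize,
      horizon_years = horizon_years,
      lookback_years = if (inherits(x, "mdci_design")) x$lookback_years else NA_real_,
      n_subjects = n,
      n_events = sum(event)
    ),
    class = "mdci_fit"
  )
}

#' @export
print.mdci_fit <- function(x, ...) {
  cat(
    "<mdci_fit> elastic-net Cox comorbidity index\n",
    "  ", length(x$beta), " candidate predictors, ",
    nrow(x$coefficients), " selected (alpha = ", x$alpha, ")\n",
    "  chosen lambda = ", signif(x$chosen_lambda, 4),
    ", CV c-index = ", signif(max(x$cv_cindex), 4), "\n",
    "  quartile cutoffs: ", paste(signif(x$quartile_cutoffs, 4), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Score subjects with a fitted comorbidity index
#'
#' The index value is the Cox linear predictor: the sum of the selected
#' predictors' coefficients over the predictors the subject is positive on.
#'
#' @param index An `mdci_fit`.
#' @param features An `mdci_design`, a matrix with columns matching the fit,
#'   or a single named 0/1 feature vector from [subject_features()].
#' @return Numeric vector of scores (one per subject/row).
#' @export
mdci_score <- function(index, features) {
  stopifnot(inherits(index, "mdci_fit"))
  if (is.numeric(features) && is.null(dim(features))) {
    features <- matrix(features, nrow = 1, dimnames = list(NULL, names(features)))
  }
  d <- as_design_matrix(features)
  X <- d$matrix
  if (ncol(X) != length(index$beta) ||
      !identical(colnames(X), names(index$beta))) {
    abort("Feature columns are not aligned with the fitted index's predictors.")
  }
  as.numeric(X %*% index$beta)
}

#' Categorize index scores into development-cohort quartiles
#'
#' @param scores Numeric scores.
#' @param cutoffs Three non-decreasing cutoffs (the 25/50/75% quantiles of
#'   the development cohort). A score equal to a cutoff falls in the lower
#'   category. Tied cutoffs (possible with heavily zero-inflated scores)
#'   simply leave the squeezed category empty.
#' @return Factor with levels `Q1`-`Q4`.
#' @export
categorize_index <- function(scores, cutoffs) {
  stopifnot(length(cutoffs) == 3L, !is.unsorted(cutoffs))
  idx <- 1L + (scores > cutoffs[1]) + (scores > cutoffs[2]) + (scores > cutoffs[3])
  factor(c("Q1", "Q2", "Q3", "Q4")[idx], levels = c("Q1", "Q2", "Q3", "Q4"))
}

#' Censor survival outcomes at a fixed horizon
#'
#' Truncates follow-up at the horizon; deaths after the horizon are recoded
#' as censored at the horizon. Idempotent.
#'
#' @param time_days,event Observed time (days) and 0/1 event indicator.
#' @param horizon_years Horizon, typically 1, 5 or 10.
#' @return Tibble with censored `time_days` and `event`.
#' @export
horizon_censor <- function(time_days, event, horizon_years) {
  h <- lookback_days(horizon_years)
  over <- time_days > h
  tibble::tibble(
    time_days = ifelse(over, h, time_days),
    event = as.integer(ifelse(over, 0L, event))
  )
}

#' Check elastic-net KKT conditions at a solution
#'
#' Verifies the subgradient optimality conditions of the elastic-net Cox
#' objective `-(1/n) loglik + lambda * (alpha*|b|_1 + (1-alpha)/2*|b|_2^2)`
#' at a coefficient vector, in the (optionally standardized) coordinates the
#' penalty applies to.
#'
#' @param x Design matrix or `mdci_design`.
#' @param time,event Survival outcome.
#' @param beta Coefficients on the original scale.
#' @param lambda,alpha Penalty and mixing weight at which to check.
#' @param sd Optional per-column scale used for internal standardization
#'   (`NULL` = unstandardized fit).
#' @return Tibble with per-coordinate `violation` (0 when the condition
#'   holds exactly); `max(violation)` should be within solver tolerance.
#' @export
kkt_check <- function(x, time, event, beta, lambda, alpha, sd = NULL) {
  d <- as_design_matrix(x)
  X <- d$matrix
  n <- nrow(X)
  ll <- cox_partial_loglik(X, beta, time, event, gradient = TRUE)
  g <- attr(ll, "gradient") / n
  if (!is.null(sd)) {
    g <- g * sd
    b <- beta * sd
  } else {
    b <- beta
  }
  viol <- ifelse(
    b == 0,
    pmax(0, abs(g) - lambda * alpha),
    abs(g - lambda * alpha * sign(b) - lambda * (1 - alpha) * b)
  )
  tibble::tibble(name = d$columns$name, beta = beta, violation = viol)
}

# glmnet-style column scale: sqrt of variance with denominator n
glmnet_column_sd <- function(X) {
  n <- nrow(X)
  mu <- Matrix::colMeans(X)
  sqrt(Matrix::colMeans(X^2) - mu^2)
}
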
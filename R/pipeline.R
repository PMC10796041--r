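#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: either a simulation config (for
#' synthetic cohorts) or paths to events/subjects tables, plus the feature,
#' fitting and evaluation parameters. A seed is mandatory: every stochastic
#' step (simulation, fold assignment, bootstrap) derives from it, so a run is
#' reproducible from its configuration alone.
#'
#' @param sim A [sim_config()] for synthetic input, or `NULL` when reading
#'   tables from disk.
#' @param events_path,subjects_path Input tables (ignored when `sim` given).
#' @param lookback_years History window (default 10).
#' @param horizon_years Mortality horizon the index is developed for
#'   (default 10).
#' @param eval_horizons Horizons at which the validation c-index is computed
#'   (default `c(1, 5, 10)`).
#' @param min_prevalence Vocabulary retention threshold (default 1e-4).
#' @param alpha Elastic-net mixing weight (default 0.5).
#' @param n_lambda,n_folds Penalty grid size and CV folds (defaults 100, 10).
#' @param n_boot Bootstrap replications for c-index CIs (default 1000).
#' @param dev_fraction Temporal split: the earliest fraction of index dates
#'   forming the development cohort (default 0.85); validation is the
#'   disjoint remainder.
#' @param seed Integer seed (required).
#' @return A list of class `mdci_run_config`.
#' @export
pipeline_config <- function(sim = NULL, events_path = NULL, subjects_path = NULL,
                            lookback_years = 10, horizon_years = 10,
                            eval_horizons = c(1, 5, 10),
                            min_prevalence = 1e-4, alpha = 0.5,
                            n_lambda = 100, n_folds = 10, n_boot = 1000,
                            dev_fraction = 0.85, seed = NULL) {
  if (is.null(seed)) abort("`seed` is required: every stochastic step derives from it.")
  if (is.null(sim) && (is.null(events_path) || is.null(subjects_path))) {
    abort("Provide either `sim` or both `events_path` and `subjects_path`.")
  }
  if (dev_fraction <= 0 || dev_fraction >= 1) {
    abort("`dev_fraction` must be strictly between 0 and 1.")
  }
  structure(
    list(
      sim = sim, events_path = events_path, subjects_path = subjects_path,
      lookback_years = lookback_years, horizon_years = horizon_years,
      eval_horizons = eval_horizons, min_prevalence = min_prevalence,
      alpha = alpha, n_lambda = n_lambda, n_folds = n_folds, n_boot = n_boot,
      dev_fraction = dev_fraction, seed = as.integer(seed)
    ),
    class = "mdci_run_config"
  )
}

# temporal development/validation split on the index date
temporal_split <- function(subjects, dev_fraction) {
  cutoff <- quantile(as.numeric(subjects$index_date), dev_fraction, type = 1)
  is_dev <- as.numeric(subjects$index_date) <= cutoff
  if (!any(is_dev) || all(is_dev)) {
    abort("Temporal split produced an empty cohort; adjust `dev_fraction`.")
  }
  list(dev = is_dev, cutoff = as.Date(cutoff, origin = "1970-01-01"))
}

#' Run the full comorbidity-index pipeline
#'
#' Orchestrates simulate/load, temporal split, vocabulary construction on
#' the development cohort, design-matrix building, elastic-net Cox fitting,
#' scoring, quartile categorization, and validation (c-indices with
#' bootstrap CIs at the configured horizons, a Charlson comparator,
#' calibration at the development horizon, quartile hazard ratios, and index
#' correlation). All stage outputs are pure functions of the configuration,
#' so rerunning an identical configuration reproduces identical coefficients
#' and reports.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage output is
#'   written (tables, MatrixMarket matrix, index JSON, evaluation report,
#'   run log with content hashes).
#' @param verbose Print per-stage progress (default `TRUE`).
#' @return A list of class `mdci_run`: `cohort`, `split`, `vocabulary`,
#'   `fit`, `scores` (tibble with subject id, cohort, score, quartile, cci),
#'   `evaluation` (list: `cindex` tibble, `calibration`, `hr_table`,
#'   `correlation_mdci_cci`).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "mdci_run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(what) say("[%5.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"), what)

  ## -- input cohort ---------------------------------------------------------
  if (!is.null(config$sim)) {
    stage("simulating cohort")
    sim_cfg <- config$sim
    if (is.null(sim_cfg$seed)) {
      sim_cfg$seed <- config$seed
    }
    cohort <- simulate_cohort(sim_cfg)
    subjects <- cohort$subjects
    events <- cohort$events
  } else {
    stage("reading input tables")
    subjects <- read_subjects(config$subjects_path)
    events <- read_events(config$events_path)
    if (!all(c("time_days", "event") %in% names(subjects))) {
      abort("Subjects table must carry `time_days` and `event` for fitting.")
    }
    cohort <- list(subjects = subjects, events = events)
  }

  ## -- temporal split -------------------------------------------------------
  sp <- temporal_split(subjects, config$dev_fraction)
  dev_s <- subjects[sp$dev, , drop = FALSE]
  val_s <- subjects[!sp$dev, , drop = FALSE]
  dev_e <- events[events$subject_id %in% dev_s$subject_id, , drop = FALSE]
  val_e <- events[events$subject_id %in% val_s$subject_id, , drop = FALSE]
  say("  development n=%d, validation n=%d (split at %s)",
      nrow(dev_s), nrow(val_s), format(sp$cutoff))

  ## -- vocabulary and design matrices --------------------------------------
  stage("building vocabulary")
  vocab <- build_vocabulary(dev_e, n_subjects = nrow(dev_s),
                            min_prevalence = config$min_prevalence)
  say("  %d variants -> %d candidate predictors", nrow(vocab), 10L * nrow(vocab))

  stage("building design matrices")
  X_dev <- build_design_matrix(dev_e, dev_s, vocab, config$lookback_years)
  X_val <- build_design_matrix(val_e, val_s, vocab, config$lookback_years)

  ## -- fit ------------------------------------------------------------------
  stage("fitting elastic-net Cox index")
  out_dev <- horizon_censor(dev_s$time_days, dev_s$event, config$horizon_years)
  fit <- fit_penalized_cox(
    X_dev, out_dev$time_days, out_dev$event,
    alpha = config$alpha, n_lambda = config$n_lambda,
    n_folds = config$n_folds, seed = config$seed,
    horizon_years = config$horizon_years
  )
  say("  %d predictors selected, CV c-index %.3f",
      nrow(fit$coefficients), max(fit$cv_cindex))

  ## -- scores ---------------------------------------------------------------
  stage("scoring")
  scores <- dplyr::bind_rows(
    tibble::tibble(
      subject_id = dev_s$subject_id, cohort = "development",
      score = mdci_score(fit, X_dev)
    ),
    tibble::tibble(
      subject_id = val_s$subject_id, cohort = "validation",
      score = mdci_score(fit, X_val)
    )
  )
  scores$quartile <- categorize_index(scores$score, fit$quartile_cutoffs)
  cci <- charlson_index(events, subjects, lookback_years = config$lookback_years)
  scores <- dplyr::left_join(scores, cci, by = "subject_id")

  ## -- validation -----------------------------------------------------------
  stage("validating")
  val_scores <- scores[scores$cohort == "validation", , drop = FALSE]
  val_scores <- val_scores[match(val_s$subject_id, val_scores$subject_id), ]
  evaluation <- evaluate_scores(
    score_list = list(mdci = val_scores$score, cci = val_scores$cci),
    time_days = val_s$time_days, event = val_s$event,
    horizons = config$eval_horizons, n_boot = config$n_boot,
    seed = config$seed + 1L
  )
  evaluation$calibration <- calibration_curve(
    val_scores$score, val_s$time_days, val_s$event,
    horizon_years = config$horizon_years
  )
  hr_strata <- cut(val_s$age, c(-Inf, 59, 69, 79, Inf),
                   labels = c("<60", "60-69", "70-79", ">=80"))
  evaluation$hr_table <- stratified_hazard_ratios(
    val_scores$quartile, hr_strata, val_s$time_days, val_s$event,
    followup_years = 1
  )
  evaluation$hr_overall <- stratified_hazard_ratios(
    val_scores$quartile, rep("all", nrow(val_s)), val_s$time_days, val_s$event,
    followup_years = 1
  )
  evaluation$correlation_mdci_cci <- tryCatch(
    index_correlation(val_scores$score, val_scores$cci),
    error = function(e) NA_real_
  )

  run <- structure(
    list(cohort = cohort, split = sp, vocabulary = vocab, fit = fit,
         scores = scores, evaluation = evaluation, config = config),
    class = "mdci_run"
  )

  if (!is.null(out_dir)) {
    stage("writing outputs")
    write_run(run, out_dir)
  }
  stage("done")
  run
}

# c-indices with bootstrap CIs for several indices at several horizons
evaluate_scores <- function(score_list, time_days, event, horizons,
                            n_boot, seed) {
  rows <- list()
  b <- 0L
  for (nm in names(score_list)) {
    sc <- score_list[[nm]]
    for (h in horizons) {
      cens <- horizon_censor(time_days, event, h)
      dat <- data.frame(score = sc, time = cens$time_days, event = cens$event)
      ci <- bootstrap_ci(
        function(d) harrell_cindex(d$score, d$time, d$event),
        dat, n_boot = n_boot, seed = seed + b
      )
      b <- b + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        index = nm, horizon_years = h,
        cindex = harrell_cindex(sc, cens$time_days, cens$event),
        ci_low = ci[["low"]], ci_high = ci[["high"]]
      )
    }
  }
  list(cindex = dplyr::bind_rows(rows))
}

# write every stage output plus a manifest of content hashes
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  paths <- c(paths, write_cohort(run$cohort, file.path(out_dir, "cohort")))
  paths <- c(paths, write_vocabulary(run$vocabulary, file.path(out_dir, "vocabulary.csv")))
  paths <- c(paths, write_index(run$fit, file.path(out_dir, "index")))
  sc_path <- file.path(out_dir, "scores.csv")
  readr::write_csv(run$scores, sc_path)
  paths <- c(paths, sc_path)

  report <- list(
    cindex = run$evaluation$cindex,
    calibration = tibble::as_tibble(run$evaluation$calibration),
    hr_table = run$evaluation$hr_table,
    hr_overall = run$evaluation$hr_overall,
    correlation_mdci_cci = run$evaluation$correlation_mdci_cci,
    split_cutoff = format(run$split$cutoff),
    n_development = sum(run$split$dev),
    n_validation = sum(!run$split$dev)
  )
  rep_path <- file.path(out_dir, "evaluation.json")
  jsonlite::write_json(report, rep_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  paths <- c(paths, rep_path)

  manifest <- tibble::tibble(
    file = sub(paste0("^", out_dir, "/?"), "", unname(paths)),
    md5 = unname(tools::md5sum(unname(paths)))
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(out_dir)
}

#' @export
print.mdci_run <- function(x, ...) {
  ci <- x$evaluation$cindex
  cat("<mdci_run>\n")
  cat("  development n=", sum(x$split$dev),
      ", validation n=", sum(!x$split$dev), "\n", sep = "")
  cat("  vocabulary: ", nrow(x$vocabulary), " variants (",
      10L * nrow(x$vocabulary), " candidate predictors)\n", sep = "")
  cat("  selected predictors: ", nrow(x$fit$coefficients), "\n", sep = "")
  main <- ci[ci$index == "mdci" & ci$horizon_years == x$config$horizon_years, ]
  if (nrow(main)) {
    cat(sprintf("  validation c-index (MDCI, %dy): %.3f (%.3f-%.3f)\n",
                x$config$horizon_years, main$cindex, main$ci_low, main$ci_high))
  }
  invisible(x)
}
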
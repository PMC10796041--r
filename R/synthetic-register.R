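#' Synthetic ICD-10 condition code table
#'
#' Deterministic table of synthetic chronic conditions, each carrying one
#' valid-shaped ICD-10 code (letter + 2-4 digits) spread across chapters and
#' recorded at three, four, or five characters so that granularity expansion
#' is non-trivial. Three-character bases are unique across conditions, so each
#' condition's own code variant is supported only by that condition's events.
#'
#' @param n_conditions Number of conditions.
#' @return Tibble with columns `condition` (1..n), `code`, `chapter`.
#' @export
synthetic_code_table <- function(n_conditions = 50) {
  stopifnot(n_conditions >= 1)
  chapters <- c("A", "B", "C", "E", "F", "G", "H", "I",
                "J", "K", "L", "M", "N", "R", "S", "T", "Z")
  k <- seq_len(n_conditions)
  letter <- chapters[((k - 1L) %% length(chapters)) + 1L]
  num <- 10L + ((k - 1L) %/% length(chapters)) * 3L
  if (any(num > 99L)) abort("Too many conditions for the synthetic code table.")
  base <- sprintf("%s%02d", letter, num)
  len <- 3L + ((k - 1L) %% 3L)            # cycle 3, 4, 5 characters
  d4 <- as.character((k * 3L) %% 10L)
  d5 <- as.character(k %% 10L)
  code <- ifelse(len == 3L, base,
          ifelse(len == 4L, paste0(base, d4), paste0(base, d4, d5)))
  tibble::tibble(condition = k, code = code, chapter = letter)
}

#' Default true-effect specification
#'
#' Twelve (condition, dimension, log hazard ratio) triples spread across the
#' occurrence, frequency, recency and duration dimensions, all with
#' |log-HR| >= 0.5, placed on the most prevalent conditions so the affected
#' features have support.
#'
#' @param n_conditions Number of conditions in the cohort (must be >= 12).
#' @return Tibble with columns `condition`, `dimension`, `log_hr`.
#' @export
default_effect_spec <- function(n_conditions = 50) {
  stopifnot(n_conditions >= 12)
  tibble::tibble(
    condition = 1:12,
    dimension = c(
      "occ_primary", "occ_any", "freq_ge2", "freq_ge3",
      "rec_90", "rec_180", "rec_365",
      "dur_gt7", "dur_gt14",
      "occ_primary", "rec_90", "dur_gt7"
    ),
    log_hr = c(0.7, 0.5, 0.6, 0.5, 0.8, 0.5, 0.5, 0.6, 0.8, 0.9, 0.6, 0.5)
  )
}

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic hospital-register
#' generator. Defaults describe a cohort with a 10-year pre-index code
#' history, mixed inpatient/outpatient care episodes, and roughly 30%
#' 10-year all-cause mortality.
#'
#' @param n_subjects Cohort size (positive integer).
#' @param n_conditions Number of synthetic chronic conditions (default 50).
#' @param condition_prevalence Per-condition lifetime prevalence in (0,1);
#'   default a geometric decline from 0.25 to 0.0125 across conditions.
#' @param episode_rate Per-condition mean care episodes per year for an
#'   affected subject of average severity (Poisson intensity, default 0.5).
#' @param p_inpatient Probability a care episode is an inpatient admission
#'   (default 0.3).
#' @param los_mean Mean extra length of stay in days at average severity; a
#'   stay lasts `rpois(los_mean * severity)` days beyond the admission day
#'   (default 3).
#' @param p_secondary Probability an episode also records one of the
#'   subject's other active conditions as a secondary diagnosis (default 0.2).
#' @param effect_spec Tibble of (condition, dimension, log_hr) triples
#'   defining the true linear predictor (default [default_effect_spec()]).
#' @param baseline_hazard Constant baseline hazard per year (default 0.0143,
#'   calibrated so the default cohort has ~30% 10-year mortality).
#' @param admin_censor_years Administrative censoring horizon (default 10).
#' @param dropout_rate Per-year random-censoring intensity (default 0.01).
#' @param lookback_years Length of pre-index history (default 10).
#' @param index_date_range Two dates bounding the uniformly drawn per-subject
#'   index dates (default 2008-01-01 to 2014-12-31, a multi-year window so
#'   temporal development/validation splits are possible).
#' @param seed Integer seed; mandatory for any stochastic step.
#' @return A validated list of class `mdci_sim_config`.
#' @export
sim_config <- function(n_subjects,
                       n_conditions = 50,
                       condition_prevalence = NULL,
                       episode_rate = 0.5,
                       p_inpatient = 0.3,
                       los_mean = 3,
                       p_secondary = 0.2,
                       effect_spec = default_effect_spec(n_conditions),
                       baseline_hazard = 0.0143,
                       admin_censor_years = 10,
                       dropout_rate = 0.01,
                       lookback_years = 10,
                       index_date_range = as.Date(c("2008-01-01", "2014-12-31")),
                       seed = NULL) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1) {
    abort("`n_subjects` must be a positive integer.")
  }
  stopifnot(n_conditions >= 1)
  if (is.null(condition_prevalence)) {
    k <- seq_len(n_conditions)
    condition_prevalence <-
      0.25 * exp(-log(20) * (k - 1) / max(1, n_conditions - 1))
  }
  if (length(condition_prevalence) == 1L) {
    condition_prevalence <- rep(condition_prevalence, n_conditions)
  }
  if (length(episode_rate) == 1L) episode_rate <- rep(episode_rate, n_conditions)
  probs <- c(condition_prevalence, p_inpatient, p_secondary)
  if (any(probs < 0 | probs > 1)) abort("All probabilities must lie in [0, 1].")
  if (any(episode_rate < 0) || baseline_hazard < 0 || dropout_rate < 0 || los_mean < 0) {
    abort("Rates and hazards must be nonnegative.")
  }
  if (baseline_hazard == 0) abort("`baseline_hazard` must be positive.")
  effect_spec <- tibble::as_tibble(effect_spec)
  stopifnot(all(c("condition", "dimension", "log_hr") %in% names(effect_spec)))
  if (any(!effect_spec$condition %in% seq_len(n_conditions))) {
    abort("`effect_spec` references conditions outside 1..n_conditions.")
  }
  if (any(!effect_spec$dimension %in% mdci_dimensions())) {
    abort("`effect_spec` references unknown predictor dimensions.")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_conditions = as.integer(n_conditions),
      condition_prevalence = condition_prevalence,
      episode_rate = episode_rate,
      p_inpatient = p_inpatient,
      los_mean = los_mean,
      p_secondary = p_secondary,
      effect_spec = effect_spec,
      baseline_hazard = baseline_hazard,
      admin_censor_years = admin_censor_years,
      dropout_rate = dropout_rate,
      lookback_years = lookback_years,
      index_date_range = as.Date(index_date_range),
      seed = seed
    ),
    class = "mdci_sim_config"
  )
}

empty_events <- function() {
  tibble::tibble(
    subject_id = character(0),
    code = character(0),
    event_date = as.Date(character(0)),
    setting = character(0),
    position = character(0),
    admission_date = as.Date(character(0)),
    discharge_date = as.Date(character(0))
  )
}

# ages drawn to resemble an elderly male register cohort:
# <60 10%, 60-69 38%, 70-79 35%, >=80 17%
sample_ages <- function(n) {
  band <- sample.int(4L, n, replace = TRUE, prob = c(0.10, 0.38, 0.35, 0.17))
  lo <- c(45, 60, 70, 80)[band]
  hi <- c(59, 69, 79, 95)[band]
  as.integer(floor(runif(n, lo, hi + 1)))
}

#' Simulate a synthetic hospital-register cohort
#'
#' Draws, per subject, a set of active chronic conditions; each active
#' condition carries a severity factor and emits a Poisson process of care
#' episodes over the lookback window. Severity inflates the episode count,
#' the length of inpatient stays, and the share of episodes falling in the
#' last year before the index date, so duration and recency signal are
#' correlated but not collinear. Each episode records the condition's
#' synthetic ICD-10 code as primary diagnosis (inpatient with probability
#' `p_inpatient`, carrying admission/discharge dates) and, with probability
#' `p_secondary`, one of the subject's other active conditions as a secondary
#' code. The true linear predictor is obtained by evaluating the effect
#' specification against the subject's realized predictor features, and
#' survival is then drawn from the baseline hazard scaled by `exp(eta)`.
#'
#' @param config A [sim_config()].
#' @return A list of class `mdci_cohort`: `subjects` (tibble `subject_id`,
#'   `index_date`, `age`, `time_days`, `event`), `events` (tibble
#'   `subject_id`, `code`, `event_date`, `setting`, `position`,
#'   `admission_date`, `discharge_date`), `true_eta` (named numeric),
#'   `truth` (the effect spec joined with condition codes), `code_table`,
#'   and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "mdci_sim_config"))
  if (is.null(config$seed)) abort("`config$seed` is required for simulation.")

  with_local_seed(config$seed, {
    n <- config$n_subjects
    K <- config$n_conditions
    codes <- synthetic_code_table(K)
    subject_id <- sprintf("S%06d", seq_len(n))
    index_date <- config$index_date_range[1] +
      floor(runif(n) * (as.numeric(diff(config$index_date_range)) + 1))
    age <- sample_ages(n)
    L <- lookback_days(config$lookback_years)

    # active (subject, condition) pairs
    active <- which(
      matrix(
        rbinom(n * K, 1L, rep(config$condition_prevalence, each = n)) == 1L,
        nrow = n
      ),
      arr.ind = TRUE
    )
    subj_i <- active[, 1]
    cond_k <- active[, 2]
    severity <- rgamma(length(subj_i), shape = 2, rate = 2)
    n_epi <- rpois(
      length(subj_i),
      config$episode_rate[cond_k] * config$lookback_years * severity
    )

    rep_i <- rep.int(seq_along(subj_i), n_epi)
    e_subj <- subj_i[rep_i]
    e_cond <- cond_k[rep_i]
    e_sev <- severity[rep_i]
    m <- length(e_subj)

    if (m > 0) {
      # severity biases episodes toward the last year before index
      p_recent <- 0.4 * e_sev / (1 + e_sev)
      recent <- runif(m) < p_recent
      days_before <- ifelse(
        recent,
        1 + floor(runif(m) * min(365, L)),
        1 + floor(runif(m) * L)
      )
      event_date <- index_date[e_subj] - days_before
      inpat <- runif(m) < config$p_inpatient
      stay_days <- ifelse(inpat, rpois(m, config$los_mean * e_sev), NA_real_)

      events <- tibble::tibble(
        subject_id = subject_id[e_subj],
        code = codes$code[e_cond],
        event_date = event_date,
        setting = ifelse(inpat, "IN", "OUT"),
        position = "PRIMARY",
        admission_date = as.Date(ifelse(inpat, event_date, NA), origin = "1970-01-01"),
        discharge_date = as.Date(ifelse(inpat, event_date + stay_days, NA),
                                 origin = "1970-01-01")
      )
    } else {
      events <- empty_events()
    }

    # secondary diagnoses drawn from the subject's other active conditions
    if (config$p_secondary > 0 && m > 0) {
      act_by_subj <- split(cond_k, subj_i)
      n_active <- lengths(act_by_subj)
      key <- as.character(e_subj)
      has_other <- n_active[key] >= 2L
      want_sec <- runif(m) < config$p_secondary & has_other
      if (any(want_sec)) {
        pick <- which(want_sec)
        r <- ceiling(runif(length(pick)) * n_active[key[pick]])
        sec_cond <- vapply(
          seq_along(pick),
          function(ii) act_by_subj[[key[pick[ii]]]][r[ii]],
          numeric(1)
        )
        keep <- sec_cond != e_cond[pick]      # never duplicate the primary code
        pick <- pick[keep]
        sec_cond <- sec_cond[keep]
        if (length(pick)) {
          sec <- events[pick, , drop = FALSE]
          sec$code <- codes$code[sec_cond]
          sec$position <- "SECONDARY"
          events <- dplyr::bind_rows(events, sec)
        }
      }
    }
    events <- dplyr::arrange(
      events, .data$subject_id, .data$event_date, .data$code, .data$position
    )

    subjects <- tibble::tibble(
      subject_id = subject_id, index_date = index_date, age = age
    )

    # true linear predictor: the effect spec evaluated on realized features
    truth <- dplyr::inner_join(config$effect_spec, codes, by = "condition")
    true_eta <- evaluate_effect_spec(events, subjects, truth, config$lookback_years)

    surv <- simulate_survival(true_eta, config, seed = NULL)
    subjects$time_days <- surv$time_days
    subjects$event <- surv$event

    structure(
      list(
        subjects = subjects, events = events, true_eta = true_eta,
        truth = truth, code_table = codes, config = config
      ),
      class = "mdci_cohort"
    )
  })
}

# eta_i = sum over effect triples of log_hr * feature(subject i, code, dimension)
evaluate_effect_spec <- function(events, subjects, truth, lookback_years) {
  eta <- setNames(numeric(nrow(subjects)), subjects$subject_id)
  if (nrow(truth) == 0L || nrow(events) == 0L) return(eta)
  vocab <- tibble::tibble(variant = unique(truth$code))
  st <- variant_stats(events, subjects, vocab, lookback_years)
  if (nrow(st) == 0L) return(eta)
  on <- stats_to_dimensions(st)
  hit <- dplyr::inner_join(
    on, truth,
    by = c("variant" = "code", "dimension"),
    relationship = "many-to-many"
  )
  if (nrow(hit)) {
    contrib <- hit |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(eta = sum(.data$log_hr), .groups = "drop")
    eta[contrib$subject_id] <- contrib$eta
  }
  eta
}

#' Simulate survival outcomes from a true linear predictor
#'
#' Draws death times from an exponential model with per-year hazard
#' `baseline_hazard * exp(eta)`, applies random dropout (exponential with
#' rate `dropout_rate`) and administrative censoring at the horizon, and
#' returns the observed time in days and the event indicator.
#'
#' @param true_eta Numeric vector of per-subject log hazard ratios.
#' @param config A [sim_config()] (fields `baseline_hazard`,
#'   `admin_censor_years`, `dropout_rate` are used).
#' @param seed Optional seed; pass `NULL` to draw from the current RNG state
#'   (as [simulate_cohort()] does internally).
#' @return Tibble with `time_days` (positive integer) and `event` (0/1).
#' @export
simulate_survival <- function(true_eta, config, seed = config$seed) {
  if (any(!is.finite(true_eta))) abort("`true_eta` must be finite.")
  if (config$baseline_hazard <= 0) abort("`baseline_hazard` must be positive.")
  with_local_seed(seed, {
    n <- length(true_eta)
    death_y <- rexp(n, rate = 1) / (config$baseline_hazard * exp(true_eta))
    drop_y <- if (config$dropout_rate > 0) {
      rexp(n, rate = config$dropout_rate)
    } else {
      rep(Inf, n)
    }
    t_y <- pmin(death_y, drop_y, config$admin_censor_years)
    tibble::tibble(
      time_days = pmax(1L, as.integer(round(t_y * 365.25))),
      event = as.integer(death_y <= pmin(drop_y, config$admin_censor_years))
    )
  })
}

#' @export
print.mdci_cohort <- function(x, ...) {
  cat(
    "<mdci_cohort> ", nrow(x$subjects), " subjects, ",
    nrow(x$events), " diagnosis events, ",
    sum(x$subjects$event), " deaths (",
    round(100 * mean(x$subjects$event)), "%), ",
    x$config$lookback_years, "y lookback / ",
    x$config$admin_censor_years, "y follow-up\n",
    sep = ""
  )
  invisible(x)
}
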
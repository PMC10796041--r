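# Shared fixtures and independent oracles for the test suite.

# Exhaustive O(n^2) pair-enumeration oracle for Harrell's concordance:
# risk orientation, usable pairs under censoring, score ties count 0.5.
cindex_oracle <- function(score, time, event) {
  conc <- 0
  usable <- 0
  n <- length(score)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) {
        if (event[i] + event[j] != 1L) next
        first <- if (event[i] == 1L) i else j
      } else {
        first <- if (time[i] < time[j]) i else j
        if (event[first] != 1L) next
      }
      other <- if (first == i) j else i
      usable <- usable + 1
      if (score[first] > score[other]) conc <- conc + 1
      else if (score[first] == score[other]) conc <- conc + 0.5
    }
  }
  if (usable == 0) stop("no usable pairs")
  conc / usable
}

# event-table constructor with sensible defaults
make_events <- function(subject_id, code, event_date,
                        setting = "OUT", position = "PRIMARY",
                        admission_date = as.Date(NA),
                        discharge_date = as.Date(NA)) {
  tibble::tibble(
    subject_id = subject_id,
    code = code,
    event_date = as.Date(event_date),
    setting = setting,
    position = position,
    admission_date = as.Date(admission_date),
    discharge_date = as.Date(discharge_date)
  )
}

# random single-subject event history for property-based tests
random_history <- function(n_events, index_date, vocab_codes, lookback_years = 10) {
  n <- n_events
  days_before <- sample.int(mdci:::lookback_days(lookback_years), n, replace = TRUE)
  event_date <- as.Date(index_date) - days_before
  inpat <- runif(n) < 0.4
  stay <- ifelse(inpat, rpois(n, 4), NA)
  make_events(
    subject_id = "P1",
    code = sample(vocab_codes, n, replace = TRUE),
    event_date = event_date,
    setting = ifelse(inpat, "IN", "OUT"),
    position = sample(c("PRIMARY", "SECONDARY"), n, replace = TRUE, prob = c(0.8, 0.2)),
    admission_date = as.Date(ifelse(inpat, event_date, NA), origin = "1970-01-01"),
    discharge_date = as.Date(ifelse(inpat, event_date + stay, NA), origin = "1970-01-01")
  )
}

# Heavy shared fixture: a development cohort, its design/fit, and a fresh
# validation cohort from the same generator. Built once per test run and
# cached, since several acceptance checks reuse it.
.mdci_fixture_env <- new.env(parent = emptyenv())

big_fixture <- function(n_dev = 20000, n_val = 4000) {
  key <- sprintf("fix_%d_%d", n_dev, n_val)
  if (!is.null(.mdci_fixture_env[[key]])) return(.mdci_fixture_env[[key]])

  cfg_dev <- sim_config(n_subjects = n_dev, seed = 20)
  dev <- simulate_cohort(cfg_dev)
  vocab <- build_vocabulary(dev$events, n_subjects = n_dev)
  X_dev <- build_design_matrix(dev$events, dev$subjects, vocab)
  fit <- fit_penalized_cox(
    X_dev, dev$subjects$time_days, dev$subjects$event, seed = 20
  )

  cfg_val <- sim_config(n_subjects = n_val, seed = 21)
  val <- simulate_cohort(cfg_val)
  X_val <- build_design_matrix(val$events, val$subjects, vocab)

  out <- list(
    dev = dev, val = val, vocab = vocab,
    X_dev = X_dev, X_val = X_val, fit = fit,
    scores_val = mdci_score(fit, X_val)
  )
  .mdci_fixture_env[[key]] <- out
  out
}
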
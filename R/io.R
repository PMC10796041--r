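# Fixed on-disk schemas: delimited tables with headers, ISO-8601 dates.
# subjects: subject_id, index_date[, age, time_days, event]
# events:   subject_id, code, event_date, setting, position,
#           admission_date, discharge_date

#' Write a cohort to delimited tables
#'
#' @param cohort An `mdci_cohort` (or a list with `subjects` and `events`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    subjects = file.path(dir, "subjects.csv"),
    events = file.path(dir, "events.csv")
  )
  readr::write_csv(cohort$subjects, paths["subjects"])
  readr::write_csv(cohort$events, paths["events"])
  if (!is.null(cohort$true_eta)) {
    paths <- c(paths, true_eta = file.path(dir, "true_eta.csv"))
    readr::write_csv(
      tibble::tibble(subject_id = names(cohort$true_eta),
                     true_eta = unname(cohort$true_eta)),
      paths["true_eta"]
    )
  }
  invisible(paths)
}

#' Read a subjects table
#'
#' @param path CSV with columns `subject_id`, `index_date` and optionally
#'   `age`, `time_days`, `event`.
#' @return Validated tibble.
#' @export
read_subjects <- function(path) {
  s <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "index_date")
  if (!all(need %in% names(s))) {
    abort(paste0("Subjects table must have columns: ", paste(need, collapse = ", ")))
  }
  s$subject_id <- as.character(s$subject_id)
  s$index_date <- as.Date(s$index_date)
  if (anyNA(s$index_date)) abort("Unparseable index_date values (expect ISO-8601).")
  if (anyDuplicated(s$subject_id)) abort("Duplicate subject_id in subjects table.")
  s
}

#' Read and validate a diagnosis-events table
#'
#' Normalizes codes with [clean_code()]; malformed codes are dropped and
#' counted (reported via a message and the `n_malformed` attribute).
#' Validates the setting/position vocabulary and the inpatient stay-date
#' invariants (`admission_date <= event_date <= discharge_date`; outpatient
#' events carry no stay dates).
#'
#' @param path CSV with the fixed events schema.
#' @return Validated tibble of normalized events.
#' @export
read_events <- function(path) {
  ev <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "code", "event_date", "setting", "position")
  if (!all(need %in% names(ev))) {
    abort(paste0("Events table must have columns: ", paste(need, collapse = ", ")))
  }
  ev$subject_id <- as.character(ev$subject_id)
  ev$event_date <- as.Date(ev$event_date)
  if (!"admission_date" %in% names(ev)) ev$admission_date <- as.Date(NA)
  if (!"discharge_date" %in% names(ev)) ev$discharge_date <- as.Date(NA)
  ev$admission_date <- as.Date(ev$admission_date)
  ev$discharge_date <- as.Date(ev$discharge_date)
  if (!all(ev$setting %in% c("IN", "OUT"))) {
    abort("`setting` must be 'IN' or 'OUT'.")
  }
  if (!all(ev$position %in% c("PRIMARY", "SECONDARY"))) {
    abort("`position` must be 'PRIMARY' or 'SECONDARY'.")
  }
  inp <- ev$setting == "IN"
  if (any(inp & (is.na(ev$admission_date) | is.na(ev$discharge_date)))) {
    abort("Inpatient events must carry admission_date and discharge_date.")
  }
  bad_stay <- inp & !(ev$admission_date <= ev$event_date &
                        ev$event_date <= ev$discharge_date)
  if (any(bad_stay)) {
    abort("Inpatient events require admission_date <= event_date <= discharge_date.")
  }
  if (any(!inp & (!is.na(ev$admission_date) | !is.na(ev$discharge_date)))) {
    abort("Outpatient events must not carry stay dates.")
  }
  code <- clean_code(ev$code, on_malformed = "drop")
  n_bad <- attr(code, "n_malformed") %||% 0L
  if (n_bad > 0L) {
    message(n_bad, " event(s) with malformed codes dropped.")
  }
  ev$code <- as.character(code)
  out <- ev[!is.na(ev$code), , drop = FALSE]
  attr(out, "n_malformed") <- n_bad
  out
}

#' Write / read a code vocabulary
#'
#' Two-column table (`variant`, `prevalence`).
#' @param vocabulary A [build_vocabulary()] result.
#' @param path CSV path.
#' @return `write_vocabulary()`: the path, invisibly. `read_vocabulary()`:
#'   the vocabulary tibble.
#' @export
write_vocabulary <- function(vocabulary, path) {
  readr::write_csv(tibble::as_tibble(vocabulary), path)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  v <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         variant = readr::col_character(),
                         prevalence = readr::col_double()
                       ))
  class(v) <- c("mdci_vocabulary", class(v))
  v
}

#' Persist a design matrix
#'
#' MatrixMarket sparse matrix plus a sidecar column-metadata table and the
#' row (subject) keys.
#'
#' @param design An `mdci_design`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_design <- function(design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    matrix = file.path(dir, "matrix.mtx"),
    columns = file.path(dir, "columns.csv"),
    rows = file.path(dir, "rows.csv"),
    meta = file.path(dir, "design.json")
  )
  Matrix::writeMM(design$matrix, paths["matrix"])
  readr::write_csv(design$columns, paths["columns"])
  readr::write_csv(tibble::tibble(subject_id = rownames(design$matrix)), paths["rows"])
  jsonlite::write_json(list(lookback_years = design$lookback_years),
                       paths["meta"], auto_unbox = TRUE)
  invisible(paths)
}

#' @rdname write_design
#' @export
read_design <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  m <- m * 1  # pattern/logical MatrixMarket payloads back to numeric 0/1
  cols <- readr::read_csv(file.path(dir, "columns.csv"), show_col_types = FALSE)
  rows <- readr::read_csv(file.path(dir, "rows.csv"), show_col_types = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "design.json"))
  dimnames(m) <- list(as.character(rows$subject_id), cols$name)
  structure(
    list(matrix = m, columns = tibble::as_tibble(cols),
         lookback_years = meta$lookback_years),
    class = "mdci_design"
  )
}

#' Serialize / restore a fitted index
#'
#' The fit is written as a JSON document (metadata, quartile cutoffs, the
#' penalty grid and cross-validation trace) plus a coefficients table
#' (`variant`, `dimension`, `name`, `coefficient`) holding the selected
#' predictors — enough to score new subjects.
#'
#' @param fit An `mdci_fit`.
#' @param prefix Path prefix; writes `<prefix>.json` and
#'   `<prefix>_coefficients.csv`.
#' @return `write_index()`: invisibly, the paths. `read_index()`: an
#'   `mdci_fit` (without fold assignments).
#' @export
write_index <- function(fit, prefix) {
  stopifnot(inherits(fit, "mdci_fit"))
  paths <- c(json = paste0(prefix, ".json"),
             coefficients = paste0(prefix, "_coefficients.csv"))
  meta <- list(
    alpha = fit$alpha,
    chosen_lambda = fit$chosen_lambda,
    lambda = fit$lambda,
    cv_cindex = fit$cv_cindex,
    quartile_cutoffs = fit$quartile_cutoffs,
    n_folds = fit$n_folds,
    seed = fit$seed,
    standardize = fit$standardize,
    horizon_years = fit$horizon_years,
    lookback_years = fit$lookback_years,
    n_subjects = fit$n_subjects,
    n_events = fit$n_events,
    columns = fit$columns$name
  )
  jsonlite::write_json(meta, paths["json"], auto_unbox = TRUE, digits = NA)
  readr::write_csv(fit$coefficients, paths["coefficients"])
  invisible(paths)
}

#' @rdname write_index
#' @export
read_index <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  coefs <- readr::read_csv(paste0(prefix, "_coefficients.csv"),
                           show_col_types = FALSE)
  beta <- setNames(numeric(length(meta$columns)), meta$columns)
  beta[coefs$name] <- coefs$coefficient
  nm <- meta$columns
  structure(
    list(
      beta = beta,
      coefficients = tibble::as_tibble(coefs),
      lambda = meta$lambda,
      cv_cindex = meta$cv_cindex,
      chosen_lambda = meta$chosen_lambda,
      alpha = meta$alpha,
      quartile_cutoffs = meta$quartile_cutoffs,
      columns = tibble::tibble(
        variant = sub("\\..*$", "", nm),
        dimension = sub("^[^.]*\\.", "", nm),
        name = nm
      ),
      foldid = NULL,
      n_folds = meta$n_folds,
      seed = meta$seed,
      standardize = meta$standardize,
      horizon_years = meta$horizon_years,
      lookback_years = meta$lookback_years,
      n_subjects = meta$n_subjects,
      n_events = meta$n_events
    ),
    class = "mdci_fit"
  )
}
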
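# Lookback window: events contribute when event_date is in
# [index_date - lookback, index_date). Years are converted at 365.25 days.
lookback_days <- function(lookback_years) as.integer(round(lookback_years * 365.25))

# per-(subject, variant) summary statistics behind the ten binary dimensions
variant_stats <- function(events, subjects, vocabulary, lookback_years) {
  stopifnot(
    all(c("subject_id", "code", "event_date", "setting", "position") %in% names(events)),
    all(c("subject_id", "index_date") %in% names(subjects))
  )
  unknown <- setdiff(unique(events$subject_id), subjects$subject_id)
  if (length(unknown)) {
    abort(paste0(
      "Events reference subject(s) absent from the subject table: ",
      paste(utils::head(unknown, 5L), collapse = ", ")
    ))
  }

  ev <- dplyr::inner_join(
    tibble::as_tibble(events),
    dplyr::select(subjects, "subject_id", "index_date"),
    by = "subject_id"
  )
  if (any(ev$event_date >= ev$index_date)) {
    abort("Events dated on or after the subject's index date are not allowed.")
  }
  win_start <- ev$index_date - lookback_days(lookback_years)
  ev <- ev[ev$event_date >= win_start, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(tibble::tibble(
      subject_id = character(0), variant = character(0),
      any_occ = logical(0), primary_occ = logical(0),
      n_primary_dates = integer(0), min_days_before = numeric(0),
      hosp_days = numeric(0)
    ))
  }

  exp <- expand_granularity(ev$code)
  idx <- rep(seq_len(nrow(ev)), each = 4L)
  long <- tibble::tibble(
    subject_id = ev$subject_id[idx],
    variant = exp$variant,
    event_date = ev$event_date[idx],
    index_date = ev$index_date[idx],
    setting = ev$setting[idx],
    position = ev$position[idx],
    admission_date = if ("admission_date" %in% names(ev)) ev$admission_date[idx] else as.Date(NA),
    discharge_date = if ("discharge_date" %in% names(ev)) ev$discharge_date[idx] else as.Date(NA)
  )
  long <- dplyr::semi_join(long, vocabulary, by = "variant")
  if (nrow(long) == 0L) {
    return(variant_stats(events[0, , drop = FALSE], subjects, vocabulary, lookback_years))
  }

  is_primary <- long$position == "PRIMARY"
  days_before <- as.numeric(long$index_date - long$event_date)

  occ <- long |>
    dplyr::mutate(
      primary = is_primary,
      days_before = days_before
    ) |>
    dplyr::group_by(.data$subject_id, .data$variant) |>
    dplyr::summarise(
      any_occ = TRUE,
      primary_occ = any(.data$primary),
      n_primary_dates = dplyr::n_distinct(.data$event_date[.data$primary]),
      min_days_before = if (any(.data$primary)) min(.data$days_before[.data$primary]) else Inf,
      .groups = "drop"
    )

  # inpatient duration: distinct stays with the variant as primary diagnosis,
  # clipped to the lookback window, same-day stays count one day
  stays <- long[is_primary & long$setting == "IN" & !is.na(long$admission_date), , drop = FALSE]
  if (nrow(stays)) {
    stays <- dplyr::distinct(
      stays, .data$subject_id, .data$variant,
      .data$admission_date, .data$discharge_date, .data$index_date
    )
    clip_start <- pmax(stays$admission_date, stays$index_date - lookback_days(lookback_years))
    clip_end <- pmin(stays$discharge_date, stays$index_date)
    stays$stay_days <- pmax(1, as.numeric(clip_end - clip_start))
    dur <- stays |>
      dplyr::group_by(.data$subject_id, .data$variant) |>
      dplyr::summarise(hosp_days = sum(.data$stay_days), .groups = "drop")
  } else {
    dur <- tibble::tibble(
      subject_id = character(0), variant = character(0), hosp_days = numeric(0)
    )
  }

  dplyr::left_join(occ, dur, by = c("subject_id", "variant")) |>
    dplyr::mutate(hosp_days = dplyr::coalesce(.data$hosp_days, 0))
}

# map the summary statistics onto the ten binary dimensions
stats_to_dimensions <- function(st) {
  tibble::tibble(
    subject_id = rep(st$subject_id, 10L),
    variant = rep(st$variant, 10L),
    dimension = rep(mdci_dimensions(), each = nrow(st)),
    value = c(
      st$primary_occ,
      st$any_occ,
      st$n_primary_dates >= 2L,
      st$n_primary_dates >= 3L,
      st$n_primary_dates >= 4L,
      st$min_days_before <= 90,
      st$min_days_before <= 180,
      st$min_days_before <= 365,
      st$hosp_days > 7,
      st$hosp_days > 14
    )
  ) |>
    dplyr::filter(.data$value)
}

#' Binary predictor vector for one subject
#'
#' Evaluates the ten predictor dimensions for every vocabulary variant on one
#' subject's diagnosis history. Occurrence dimensions reflect at least one
#' primary (`occ_primary`) or primary-or-secondary (`occ_any`) event;
#' frequency dimensions (`freq_ge2/3/4`) count distinct event dates of primary
#' events; recency dimensions (`rec_90/180/365`) flag a primary event within
#' that many days before the index date (boundary inclusive); duration
#' dimensions (`dur_gt7/14`) flag more than 7 or 14 total days in hospital
#' with the variant as primary diagnosis, stays clipped to the lookback
#' window and same-day stays counting one day. Only events dated within
#' `[index_date - lookback, index_date)` contribute.
#'
#' @param events Data frame of this subject's normalized diagnosis events
#'   (columns `subject_id`, `code`, `event_date`, `setting` in `IN`/`OUT`,
#'   `position` in `PRIMARY`/`SECONDARY`, and `admission_date`,
#'   `discharge_date` for inpatient stays).
#' @param vocabulary An [build_vocabulary()] result (or any data frame with a
#'   `variant` column in the intended column order).
#' @param index_date The subject's index date (`Date`).
#' @param lookback_years Length of the history window in years (default 10).
#' @return Named integer 0/1 vector of length `10 * nrow(vocabulary)`, named
#'   `<variant>.<dimension>` in vocabulary-major order.
#' @export
subject_features <- function(events, vocabulary, index_date, lookback_years = 10) {
  stopifnot(length(index_date) == 1L)
  sid <- if (nrow(events)) unique(events$subject_id) else "subject"
  if (length(sid) != 1L) abort("subject_features() expects events for a single subject.")
  subjects <- tibble::tibble(subject_id = sid, index_date = as.Date(index_date))
  cols <- design_columns(vocabulary)
  out <- setNames(integer(nrow(cols)), cols$name)
  st <- variant_stats(events, subjects, vocabulary, lookback_years)
  if (nrow(st)) {
    on <- stats_to_dimensions(st)
    out[paste(on$variant, on$dimension, sep = ".")] <- 1L
  }
  out
}

# deterministic column metadata: vocabulary order (lexicographic) x dimensions
design_columns <- function(vocabulary) {
  v <- vocabulary$variant
  tibble::tibble(
    variant = rep(v, each = 10L),
    dimension = rep(mdci_dimensions(), times = length(v)),
    name = paste(rep(v, each = 10L), rep(mdci_dimensions(), times = length(v)), sep = ".")
  )
}

#' Build the sparse binary design matrix
#'
#' One row per subject, one column per (vocabulary variant, predictor
#' dimension) pair — ten columns per variant, in deterministic
#' vocabulary-major order. Subjects with no qualifying events get all-zero
#' rows; events referencing subjects absent from the subject table are an
#' error.
#'
#' @param events Data frame of normalized diagnosis events for the cohort.
#' @param subjects Data frame with one row per subject (`subject_id`,
#'   `index_date`).
#' @param vocabulary A [build_vocabulary()] result.
#' @param lookback_years History window in years (default 10).
#' @return An object of class `mdci_design`: list with `matrix` (a
#'   `dgCMatrix`, rownames = subject ids), `columns` (tibble `variant`,
#'   `dimension`, `name`) and `lookback_years`.
#' @export
build_design_matrix <- function(events, subjects, vocabulary, lookback_years = 10) {
  cols <- design_columns(vocabulary)
  st <- variant_stats(events, subjects, vocabulary, lookback_years)
  on <- stats_to_dimensions(st)
  i <- match(on$subject_id, subjects$subject_id)
  j <- match(paste(on$variant, on$dimension, sep = "."), cols$name)
  m <- Matrix::sparseMatrix(
    i = i, j = j, x = 1,
    dims = c(nrow(subjects), nrow(cols)),
    dimnames = list(subjects$subject_id, cols$name)
  )
  structure(
    list(matrix = m, columns = cols, lookback_years = lookback_years),
    class = "mdci_design"
  )
}

#' @export
print.mdci_design <- function(x, ...) {
  cat(
    "<mdci_design> ", nrow(x$matrix), " subjects x ", ncol(x$matrix),
    " predictors (", ncol(x$matrix) / 10L, " variants x 10 dimensions), ",
    "lookback ", x$lookback_years, "y, density ",
    signif(Matrix::nnzero(x$matrix) / max(1, prod(dim(x$matrix))), 3), "\n",
    sep = ""
  )
  invisible(x)
}
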
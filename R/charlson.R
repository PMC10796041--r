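#' Charlson condition mapping (ICD-10)
#'
#' Loads the shipped ICD-10 coding of the 17 Charlson conditions (the Quan et
#' al. 2005 enumeration) with the original Charlson weights, as an editable
#' three-column table. Users can supply their own mapping in the same format
#' (e.g. a nationally adapted one).
#'
#' @param path Path to a CSV with columns `condition`, `prefix`, `weight`;
#'   default the table shipped with the package.
#' @return Tibble with one row per code prefix.
#' @export
charlson_mapping <- function(path = system.file("extdata", "charlson_icd10.csv",
                                                package = "mdci")) {
  map <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           condition = readr::col_character(),
                           prefix = readr::col_character(),
                           weight = readr::col_integer()
                         ))
  if (any(map$weight < 1)) abort("Charlson weights must be positive integers.")
  map$prefix <- clean_code(map$prefix)
  map
}

#' Charlson comorbidity index
#'
#' Computes the classical occurrence-only comparator: the sum of condition
#' weights over the distinct Charlson conditions a subject has at least one
#' diagnosis code for — primary or secondary position, any care setting —
#' within the lookback window before the index date. Each condition counts
#' once regardless of how many codes support it. For cancer cohorts, codes
#' for the index cancer (and its metastasis codes in subjects who carry the
#' index cancer code) can be excluded first via `cancer_exclusion`.
#'
#' @param events Data frame of normalized diagnosis events.
#' @param subjects Data frame with `subject_id` and `index_date`.
#' @param mapping Mapping table from [charlson_mapping()].
#' @param lookback_years History window in years (default 10).
#' @param cancer_exclusion Optional: either a single code prefix (the index
#'   cancer, e.g. `"C61"`; metastasis prefixes `C77`-`C80` are then excluded
#'   in subjects who carry it) or a list with elements `target` and
#'   `companions`.
#' @return Tibble with `subject_id` and integer `cci`, one row per subject in
#'   `subjects` (0 when no condition is found).
#' @export
charlson_index <- function(events, subjects, mapping = charlson_mapping(),
                           lookback_years = 10, cancer_exclusion = NULL) {
  stopifnot(
    all(c("subject_id", "code", "event_date") %in% names(events)),
    all(c("subject_id", "index_date") %in% names(subjects))
  )
  ev <- tibble::as_tibble(events)
  if (!is.null(cancer_exclusion)) {
    if (is.character(cancer_exclusion)) {
      cancer_exclusion <- list(
        target = cancer_exclusion,
        companions = c("C77", "C78", "C79", "C80")
      )
    }
    ev <- apply_outcome_exclusion(ev, cancer_exclusion$target,
                                  cancer_exclusion$companions)
  }
  out <- tibble::tibble(subject_id = subjects$subject_id, cci = 0L)
  if (nrow(ev) == 0L) return(out)

  ev <- dplyr::inner_join(
    ev, dplyr::select(subjects, "subject_id", "index_date"),
    by = "subject_id"
  )
  win_start <- ev$index_date - lookback_days(lookback_years)
  ev <- ev[ev$event_date >= win_start & ev$event_date < ev$index_date, , drop = FALSE]
  if (nrow(ev) == 0L) return(out)

  hits <- vector("list", 0L)
  for (len in sort(unique(nchar(mapping$prefix)))) {
    sub_map <- mapping[nchar(mapping$prefix) == len, , drop = FALSE]
    key <- substr(ev$code, 1L, len)
    idx <- match(key, sub_map$prefix)
    ok <- !is.na(idx)
    if (any(ok)) {
      hits[[length(hits) + 1L]] <- tibble::tibble(
        subject_id = ev$subject_id[ok],
        condition = sub_map$condition[idx[ok]],
        weight = sub_map$weight[idx[ok]]
      )
    }
  }
  if (!length(hits)) return(out)

  cci <- dplyr::bind_rows(hits) |>
    dplyr::distinct(.data$subject_id, .data$condition, .data$weight) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(cci = as.integer(sum(.data$weight)), .groups = "drop")
  out$cci[match(cci$subject_id, out$subject_id)] <- cci$cci
  out
}
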
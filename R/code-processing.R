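#' Normalize raw ICD-10 code strings
#'
#' Uppercases, strips dots, hyphens and whitespace, removes trailing
#' non-alphanumeric characters, and truncates codes recorded at more than five
#' characters (sub-classifications) to five. The result must be a chapter
#' letter followed by one to four digits (`^[A-Z][0-9]{1,4}$`).
#'
#' @param raw Character vector of raw code strings.
#' @param on_malformed `"error"` (default) aborts on the first malformed code;
#'   `"drop"` returns `NA` for malformed entries so callers can count and drop
#'   them.
#' @return Character vector of normalized codes (with `NA` for malformed
#'   entries when `on_malformed = "drop"`). The number of malformed entries is
#'   attached as attribute `n_malformed` when dropping.
#' @export
#' @examples
#' clean_code("i73.1")  # "I731"
#' clean_code(c("I7319", " k55-8 "))
clean_code <- function(raw, on_malformed = c("error", "drop")) {
  on_malformed <- match.arg(on_malformed)
  if (length(raw) == 0L) return(character(0))
  if (!is.character(raw)) raw <- as.character(raw)
  x <- toupper(raw)
  x <- gsub("[.[:space:]-]", "", x)
  x <- sub("[^A-Z0-9]+$", "", x)
  x <- substr(x, 1L, 5L)
  ok <- !is.na(x) & grepl("^[A-Z][0-9]{1,4}$", x)
  if (!all(ok)) {
    if (on_malformed == "error") {
      bad <- utils::head(raw[!ok], 5L)
      abort(
        paste0(
          "Malformed ICD-10 code(s), not reducible to letter + 1-4 digits: ",
          paste(sprintf("'%s'", bad), collapse = ", ")
        ),
        class = "mdci_malformed_code"
      )
    }
    x[!ok] <- NA_character_
    attr(x, "n_malformed") <- sum(!ok)
  }
  x
}

#' Expand a code to its four granularity levels
#'
#' Every normalized ICD-10 code contributes information at four granularity
#' levels: two, three, four and five characters. Levels below the recorded
#' length are prefixes; levels above it are obtained by padding with trailing
#' `"9"`s (the ICD-10 "unspecified" convention), so `"I731"` expands to
#' `I7, I73, I731, I7319` and `"I5"` to `I5, I59, I599, I5999`.
#'
#' @param code Character vector of normalized codes (see [clean_code()]).
#' @return A tibble with columns `code`, `level` (2:5) and `variant`; four rows
#'   per input code, in input order.
#' @export
#' @examples
#' expand_granularity("I731")
expand_granularity <- function(code) {
  stopifnot(is.character(code))
  if (length(code) && !all(grepl("^[A-Z][0-9]{1,4}$", code))) {
    abort("expand_granularity() expects normalized codes; run clean_code() first.")
  }
  n <- length(code)
  padded <- paste0(code, strrep("9", pmax(0L, 5L - nchar(code))))
  tibble::tibble(
    code = rep(code, each = 4L),
    level = rep(2:5, times = n),
    variant = substr(rep(padded, each = 4L), 1L, rep(2:5, times = n))
  )
}

#' Build the prevalence-filtered code vocabulary
#'
#' Expands every event's code to its four granularity levels, credits each
#' variant to the event's subject (any diagnosis position, any care setting),
#' and retains a variant when the fraction of cohort subjects with at least
#' one credit reaches `min_prevalence`. The boundary is inclusive: 1 subject in
#' 10,000 survives the default 0.01% filter.
#'
#' @param events Data frame of diagnosis events with at least `subject_id` and
#'   `code` (normalized).
#' @param n_subjects Number of subjects in the cohort (the prevalence
#'   denominator); must be positive. Subjects with no events still count.
#' @param min_prevalence Retention threshold as a fraction (default `1e-4`).
#' @param exclusions Character vector of code prefixes to remove from the
#'   vocabulary regardless of prevalence (default none).
#' @param prune If `TRUE`, additionally drop any child variant whose supporting
#'   subject set is identical to its parent variant's, since such a child can
#'   carry no information beyond its parent. Default `FALSE`.
#' @return An object of class `mdci_vocabulary`: a tibble with columns
#'   `variant` (lexicographically ordered) and `prevalence`, plus attributes
#'   `min_prevalence`, `exclusions` and `n_subjects`.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   subject_id = c("a", "b", "c"),
#'   code = c("I731", "I739", "J10")
#' )
#' build_vocabulary(ev, n_subjects = 3)
build_vocabulary <- function(events, n_subjects, min_prevalence = 1e-4,
                             exclusions = character(0), prune = FALSE) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects <= 0) {
    abort("`n_subjects` must be a single positive number.")
  }
  stopifnot(is.data.frame(events), all(c("subject_id", "code") %in% names(events)))

  ev <- dplyr::distinct(events, .data$subject_id, .data$code)
  exp <- expand_granularity(ev$code)
  credits <- dplyr::distinct(
    tibble::tibble(
      subject_id = rep(ev$subject_id, each = 4L),
      variant = exp$variant
    )
  )
  tab <- credits |>
    dplyr::count(.data$variant, name = "n_subj") |>
    dplyr::mutate(prevalence = .data$n_subj / n_subjects) |>
    dplyr::filter(.data$prevalence >= min_prevalence)

  if (length(exclusions)) {
    keep <- !Reduce(`|`, lapply(exclusions, function(p) startsWith(tab$variant, p)))
    tab <- tab[keep, , drop = FALSE]
  }

  if (isTRUE(prune) && nrow(tab)) {
    # a child is redundant when exactly the same subjects support it as its parent
    sets <- split(credits$subject_id, credits$variant)
    redundant <- vapply(tab$variant, function(v) {
      if (nchar(v) <= 2L) return(FALSE)
      parent <- substr(v, 1L, nchar(v) - 1L)
      identical(sort(unique(sets[[v]])), sort(unique(sets[[parent]])))
    }, logical(1))
    tab <- tab[!redundant, , drop = FALSE]
  }

  out <- tab |>
    dplyr::arrange(.data$variant) |>
    dplyr::select("variant", "prevalence")
  structure(
    out,
    class = c("mdci_vocabulary", class(out)),
    min_prevalence = min_prevalence,
    exclusions = exclusions,
    n_subjects = n_subjects
  )
}

#' Remove outcome-related codes from an event table
#'
#' Removes all events whose code falls under `target_code`, and removes events
#' under any `companion_prefixes` only for subjects who also carry at least one
#' `target_code` event (on any date). Used to strip the index cancer (e.g.
#' prostate cancer C61) and its metastasis codes (C77-C80) from a cancer
#' cohort before computing a comorbidity score, so the outcome-defining
#' disease does not masquerade as comorbidity.
#'
#' @param events Data frame of normalized diagnosis events.
#' @param target_code Code prefix defining the outcome disease (e.g. `"C61"`).
#' @param companion_prefixes Prefixes removed only in subjects who have the
#'   target (e.g. `c("C77", "C78", "C79", "C80")`).
#' @return The filtered events tibble.
#' @export
apply_outcome_exclusion <- function(events, target_code,
                                    companion_prefixes = character(0)) {
  stopifnot(is.data.frame(events), all(c("subject_id", "code") %in% names(events)))
  ev <- tibble::as_tibble(events)
  if (nrow(ev) == 0L) return(ev)
  is_target <- startsWith(ev$code, target_code)
  target_subjects <- unique(ev$subject_id[is_target])
  is_companion <- if (length(companion_prefixes)) {
    Reduce(`|`, lapply(companion_prefixes, function(p) startsWith(ev$code, p)))
  } else {
    rep(FALSE, nrow(ev))
  }
  drop <- is_target | (is_companion & ev$subject_id %in% target_subjects)
  ev[!drop, , drop = FALSE]
}
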
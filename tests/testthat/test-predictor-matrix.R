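vocab_of <- function(codes) {
  v <- sort(unique(expand_granularity(codes)$variant))
  structure(tibble::tibble(variant = v, prevalence = NA_real_),
            class = c("mdci_vocabulary", "tbl_df", "tbl", "data.frame"))
}

test_that("the ten dimensions evaluate the stated thresholds on a worked history", {
  index <- as.Date("2015-06-01")
  # three distinct primary dates (60, 200, 400 days pre-index); the 200-day
  # one is an inpatient admission lasting 10 days
  ev <- make_events(
    subject_id = "P1",
    code = "I731",
    event_date = index - c(60, 200, 400),
    setting = c("OUT", "IN", "OUT"),
    position = "PRIMARY",
    admission_date = as.Date(c(NA, index - 200, NA)),
    discharge_date = as.Date(c(NA, index - 190, NA))
  )
  vocab <- vocab_of("I731")
  f <- subject_features(ev, vocab, index)
  expected <- c(
    occ_primary = 1, occ_any = 1,
    freq_ge2 = 1, freq_ge3 = 1, freq_ge4 = 0,
    rec_90 = 1, rec_180 = 1, rec_365 = 1,
    dur_gt7 = 1, dur_gt14 = 0
  )
  for (variant in c("I7", "I73", "I731", "I7319")) {
    got <- f[paste(variant, names(expected), sep = ".")]
    expect_equal(unname(got), unname(expected), label = variant)
  }
})

test_that("a single secondary-only code sets occ_any and nothing else", {
  index <- as.Date("2015-06-01")
  ev <- make_events("P1", "J10", index - 30, position = "SECONDARY")
  f <- subject_features(ev, vocab_of("J10"), index)
  expect_equal(sum(f), 4L)  # occ_any on each of the four granularity variants
  expect_true(all(f[grepl("occ_any$", names(f))] == 1))
  expect_true(all(f[!grepl("occ_any$", names(f))] == 0))
})

test_that("no events in the lookback yields an all-zero row", {
  index <- as.Date("2015-06-01")
  ev <- make_events("P1", "J10", index - mdci:::lookback_days(10) - 5)
  f <- subject_features(ev, vocab_of("J10"), index)
  expect_true(all(f == 0))
  f2 <- subject_features(make_events(character(0), character(0), as.Date(character(0))),
                         vocab_of("J10"), index)
  expect_true(all(f2 == 0))
})

test_that("recency boundary is inclusive and events at/after index are rejected", {
  index <- as.Date("2015-06-01")
  ev <- make_events("P1", "J10", index - 90)
  f <- subject_features(ev, vocab_of("J10"), index)
  expect_equal(unname(f["J10.rec_90"]), 1L)
  expect_error(
    subject_features(make_events("P1", "J10", index), vocab_of("J10"), index),
    "index date"
  )
})

test_that("duration accrues only for primary inpatient stays, clipped, 1-day minimum", {
  index <- as.Date("2015-06-01")
  # same-day admission: counts 1 day
  ev1 <- make_events("P1", "I50", index - 10, setting = "IN",
                     admission_date = index - 10, discharge_date = index - 10)
  f1 <- subject_features(ev1, vocab_of("I50"), index)
  expect_equal(unname(f1["I50.dur_gt7"]), 0L)

  # a 20-day stay straddling the lookback start is clipped
  lb <- mdci:::lookback_days(10)
  ev2 <- make_events("P1", "I50", index - lb + 2, setting = "IN",
                     admission_date = index - lb - 10,
                     discharge_date = index - lb + 10)
  f2 <- subject_features(ev2, vocab_of("I50"), index)
  expect_equal(unname(f2["I50.dur_gt7"]), 1L)   # clipped stay = 10 days
  expect_equal(unname(f2["I50.dur_gt14"]), 0L)

  # secondary inpatient stays contribute no duration
  ev3 <- make_events("P1", "I50", index - 50, setting = "IN", position = "SECONDARY",
                     admission_date = index - 50, discharge_date = index - 20)
  f3 <- subject_features(ev3, vocab_of("I50"), index)
  expect_equal(unname(f3["I50.dur_gt7"]), 0L)
  expect_equal(unname(f3["I50.occ_any"]), 1L)
})

test_that("design matrix equals stacked per-subject feature rows", {
  set.seed(101)
  index <- as.Date("2014-01-01")
  codes <- c("I731", "J10", "K55", "E112")
  subjects <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    index_date = index + c(0, 40, -30)
  )
  events <- dplyr::bind_rows(lapply(seq_len(nrow(subjects)), function(i) {
    h <- random_history(8, subjects$index_date[i], codes)
    h$subject_id <- subjects$subject_id[i]
    h
  }))
  vocab <- build_vocabulary(events, 3)
  design <- build_design_matrix(events, subjects, vocab)
  stacked <- t(vapply(seq_len(nrow(subjects)), function(i) {
    subject_features(events[events$subject_id == subjects$subject_id[i], ],
                     vocab, subjects$index_date[i])
  }, numeric(10 * nrow(vocab))))
  expect_equal(unname(as.matrix(design$matrix)), unname(stacked))
  expect_equal(rownames(design$matrix), subjects$subject_id)
})

test_that("column-count law: exactly ten columns per vocabulary variant", {
  for (codes in list("I50", c("I50", "J10"), c("A01", "B2", "C333", "D4444"))) {
    v <- vocab_of(codes)
    d <- build_design_matrix(
      make_events(character(0), character(0), as.Date(character(0))),
      tibble::tibble(subject_id = character(0), index_date = as.Date(character(0))),
      v
    )
    expect_equal(ncol(d$matrix), 10L * nrow(v))
    expect_equal(nrow(d$matrix), 0L)
  }
})

test_that("nesting invariants hold on randomized histories", {
  set.seed(2024)
  index <- as.Date("2013-05-15")
  codes <- c("I731", "I50", "J10", "K558", "E11")
  for (rep in 1:25) {
    ev <- random_history(sample.int(30, 1), index, codes)
    vocab <- build_vocabulary(ev, 1)
    f <- subject_features(ev, vocab, index)
    for (variant in vocab$variant) {
      g <- function(dim) f[[paste(variant, dim, sep = ".")]]
      # frequency chain
      expect_true(g("freq_ge4") <= g("freq_ge3"))
      expect_true(g("freq_ge3") <= g("freq_ge2"))
      expect_true(g("freq_ge2") <= g("occ_primary"))
      # recency chain
      expect_true(g("rec_90") <= g("rec_180"))
      expect_true(g("rec_180") <= g("rec_365"))
      expect_true(g("rec_365") <= g("occ_primary"))
      # duration chain
      expect_true(g("dur_gt14") <= g("dur_gt7"))
      # occurrence
      expect_true(g("occ_primary") <= g("occ_any"))
    }
  }
})

test_that("features on a long variant imply the same features on its ancestors", {
  set.seed(77)
  index <- as.Date("2013-05-15")
  for (rep in 1:10) {
    ev <- random_history(sample.int(20, 1), index, c("I7319", "K5580"))
    vocab <- build_vocabulary(ev, 1)
    f <- subject_features(ev, vocab, index)
    for (variant in vocab$variant[nchar(vocab$variant) == 5]) {
      for (dim in predictor_dimensions()) {
        for (l in 2:4) {
          anc <- substr(variant, 1, l)
          if (anc %in% vocab$variant) {
            expect_true(
              f[[paste(anc, dim, sep = ".")]] >= f[[paste(variant, dim, sep = ".")]]
            )
          }
        }
      }
    }
  }
})

test_that("the matrix is invariant to a common shift of all dates", {
  set.seed(5)
  index <- as.Date("2012-03-01")
  subjects <- tibble::tibble(subject_id = "P1", index_date = index)
  ev <- random_history(15, index, c("I731", "J10"))
  vocab <- build_vocabulary(ev, 1)
  d1 <- build_design_matrix(ev, subjects, vocab)

  shift <- 1234L
  ev2 <- ev
  for (col in c("event_date", "admission_date", "discharge_date")) {
    ev2[[col]] <- ev2[[col]] + shift
  }
  subjects2 <- dplyr::mutate(subjects, index_date = index + shift)
  d2 <- build_design_matrix(ev2, subjects2, vocab)
  expect_equal(as.matrix(d1$matrix), as.matrix(d2$matrix))
})

test_that("events referencing unknown subjects are an error", {
  subjects <- tibble::tibble(subject_id = "known", index_date = as.Date("2012-01-01"))
  ev <- make_events("unknown", "I50", "2011-01-01")
  expect_error(build_design_matrix(ev, subjects, vocab_of("I50")), "absent")
})
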
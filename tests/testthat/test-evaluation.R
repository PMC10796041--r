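test_that("perfectly inverse-ordered scores give concordance 1, constants 0.5", {
  t <- c(5, 3, 8, 1, 9)
  e <- rep(1L, 5)
  expect_equal(harrell_cindex(-t, t, e), 1.0)
  expect_equal(harrell_cindex(t, t, e), 0.0)
  expect_equal(harrell_cindex(rep(2, 5), t, e), 0.5)
})

test_that("a mixed-censoring example matches the exhaustive pair oracle", {
  score <- c(2.1, 0.3, 1.7, 0.3, 2.9, 1.0)
  time <- c(100, 400, 150, 320, 90, 400)
  event <- c(1L, 0L, 1L, 1L, 0L, 0L)
  expect_equal(harrell_cindex(score, time, event),
               cindex_oracle(score, time, event))
})

test_that("concordance agrees with the oracle on random censored data", {
  set.seed(314)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    score <- round(rnorm(n), 1)          # induce score ties
    time <- sample.int(30, n, replace = TRUE)  # and time ties
    event <- rbinom(n, 1, 0.6)
    if (sum(event) == 0) event[1] <- 1L
    expect_equal(harrell_cindex(score, time, event),
                 cindex_oracle(score, time, event))
  }
})

test_that("concordance matches survival::concordance on tie-free data", {
  set.seed(99)
  n <- 400
  score <- rnorm(n)
  time <- rexp(n, exp(score) * 0.1)
  event <- rbinom(n, 1, 0.7)
  event[1] <- 1L
  ours <- harrell_cindex(score, time, event)
  ref <- survival::concordance(survival::Surv(time, event) ~ score, reverse = TRUE)
  expect_equal(ours, unname(ref$concordance), tolerance = 1e-12)
})

test_that("concordance symmetry and monotone-transform invariance", {
  set.seed(11)
  n <- 60
  score <- rnorm(n)  # continuous: no ties
  time <- rexp(n)
  event <- rbinom(n, 1, 0.5); event[1] <- 1L
  c1 <- harrell_cindex(score, time, event)
  expect_equal(c1 + harrell_cindex(-score, time, event), 1.0)
  expect_equal(harrell_cindex(exp(3 * score), time, event), c1)
  expect_equal(harrell_cindex(rank(score), time, event), c1)
})

test_that("concordance errors when no pair is usable", {
  expect_error(harrell_cindex(c(1, 2), c(5, 5), c(0L, 0L)), "usable")
})

test_that("bootstrap CI of a normal mean has the closed-form width", {
  set.seed(2)
  x <- rnorm(10000)
  ci <- bootstrap_ci(mean, x, n_boot = 500, seed = 7)
  expect_lt(ci[["low"]], 0)
  expect_gt(ci[["high"]], 0)
  width <- ci[["high"]] - ci[["low"]]
  expect_equal(width, 2 * 1.96 / sqrt(10000), tolerance = 0.15)
})

test_that("bootstrap is deterministic given the seed and degenerate on constants", {
  x <- rnorm(50)
  a <- bootstrap_ci(mean, x, n_boot = 100, seed = 3)
  b <- bootstrap_ci(mean, x, n_boot = 100, seed = 3)
  expect_identical(a[1:2], b[1:2])

  d <- bootstrap_ci(mean, rep(4, 30), n_boot = 50, seed = 1)
  expect_equal(unname(d[["high"]] - d[["low"]]), 0)
})

test_that("undefined resamples are redrawn and counted", {
  x <- c(rep(0, 19), 1)
  stat <- function(s) if (sum(s) == 0) NA_real_ else mean(s)
  ci <- bootstrap_ci(stat, x, n_boot = 200, seed = 5)
  expect_gte(attr(ci, "n_redrawn"), 1L)
  expect_true(all(attr(ci, "estimates") > 0))
})

test_that("Kaplan-Meier matches the hand product-limit computation", {
  km <- kaplan_meier(c(1, 2, 3), c(1L, 1L, 1L))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  all_cens <- kaplan_meier(c(4, 5, 6), c(0L, 0L, 0L))
  expect_true(all(all_cens$surv == 1))

  # without censoring the curve is the empirical survival fraction
  set.seed(6)
  t <- sample.int(100, 40, replace = TRUE)
  km2 <- kaplan_meier(t, rep(1L, 40))
  expect_equal(km2$surv, vapply(km2$time, function(s) mean(t > s), numeric(1)))

  expect_error(kaplan_meier(numeric(0), integer(0)), "Empty")
})

test_that("KM evaluation is right-continuous and NA beyond a censored tail", {
  km <- kaplan_meier(c(2, 4, 6), c(1L, 1L, 0L))
  expect_equal(km_survival_at(km, c(0, 1.99, 2, 3, 4)), c(1, 1, 2/3, 2/3, 1/3))
  expect_true(is.na(km_survival_at(km, 7)))
})

test_that("constant scores give a single calibration bin matching marginal KM", {
  set.seed(8)
  n <- 2000
  time <- rexp(n, 0.05) * 365.25
  event <- as.integer(time <= 3652)
  time <- pmin(time, 3652)
  cal <- calibration_curve(rep(1, n), time, event, horizon_years = 10,
                           bin_edges = c(0, 0.5, 1))
  expect_equal(nrow(cal), 1L)
  km <- kaplan_meier(time, event)
  expect_equal(cal$observed_km, km_survival_at(km, mdci:::lookback_days(10)))
  expect_equal(cal$mean_predicted, cal$observed_km, tolerance = 0.02)
})

test_that("degenerate bin edges partition the cohort", {
  set.seed(9)
  n <- 3000
  score <- rnorm(n)
  time <- rexp(n, 0.04 * exp(0.7 * score)) * 365.25
  event <- as.integer(time <= 3652)
  time <- pmin(time, 3652)
  cal <- calibration_curve(score, time, event, horizon_years = 10,
                           bin_edges = c(0, 0.5, 1))
  expect_lte(nrow(cal), 2L)
  expect_equal(sum(cal$n), n)
  expect_true(all(cal$mean_predicted >= 0 & cal$mean_predicted <= 1))
})

test_that("a well-specified model is well calibrated", {
  set.seed(10)
  n <- 8000
  score <- rnorm(n)
  time <- rexp(n, 0.03 * exp(0.6 * score)) * 365.25
  event <- as.integer(time <= 3652)
  time <- pmin(time, 3652)
  cal <- calibration_curve(score, time, event, horizon_years = 10)
  gaps <- abs(cal$observed_km - cal$mean_predicted)
  expect_lt(max(gaps, na.rm = TRUE), 0.05)
})

test_that("stratified hazard ratios recover a generator-known HR of 2", {
  set.seed(12)
  n <- 8000
  grp <- factor(rep(c("Q1", "Q4"), each = n / 2), levels = c("Q1", "Q4"))
  haz <- 0.25 * ifelse(grp == "Q4", 2, 1)
  time <- rexp(n, haz) * 365.25
  event <- as.integer(time <= 365)
  time <- pmin(time, 365)
  hr <- stratified_hazard_ratios(grp, rep("all", n), time, event,
                                 followup_years = 1)
  est <- hr[hr$contrast == "Q4 vs Q1", ]
  expect_equal(est$status, "estimated")
  expect_gt(est$hr, 1.8)
  expect_lt(est$hr, 2.2)
  expect_true(est$ci_low < 2 && 2 < est$ci_high)
})

test_that("strata with too few reference events are reported NA", {
  grp <- factor(c(rep("Q1", 30), rep("Q4", 30)), levels = c("Q1", "Q4"))
  time <- c(rep(3000, 30), rexp(30, 2) * 365.25)
  event <- c(rep(0L, 30), rep(1L, 30))  # zero events in Q1
  hr <- stratified_hazard_ratios(grp, rep("all", 60), time, event)
  expect_equal(hr$status, "NA")
  expect_true(is.na(hr$hr))
})

test_that("equal hazards give HRs near one", {
  set.seed(13)
  n <- 6000
  grp <- factor(sample(c("Q1", "Q2", "Q3", "Q4"), n, replace = TRUE))
  time <- rexp(n, 0.3) * 365.25
  event <- as.integer(time <= 365)
  time <- pmin(time, 365)
  hr <- stratified_hazard_ratios(grp, rep("all", n), time, event)
  expect_true(all(hr$status == "estimated"))
  expect_true(all(abs(log(hr$hr)) < 0.25))
})

test_that("index correlation handles the documented cases", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(index_correlation(x, x), 1.0)
  expect_equal(index_correlation(x, -x), -1.0)

  # hand rank computation (no ties): Spearman = Pearson on ranks
  a <- c(10, 20, 30, 40)
  b <- c(1, 3, 2, 4)
  hand <- cor(rank(a), rank(b))
  expect_equal(index_correlation(a, b), hand)
  expect_equal(index_correlation(a, b, method = "pearson"), cor(a, b))

  expect_error(index_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(index_correlation(1:2, 1:2), "length")
})
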
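make_toy_tables <- function() {
  # 15 subjects: one single-scan, one low MMSE, one extreme baseline MAP,
  # twelve clean (a 3-SD flag needs enough clean subjects to be possible:
  # the largest attainable |z| in a sample of n is (n - 1)/sqrt(n))
  n_sub <- 15
  subjects <- data.frame(
    subject_id = paste0("S", 1:n_sub),
    cohort = rep("MA", n_sub), sex = rep("male", n_sub),
    baseline_age = rep(45, n_sub),
    education = 14, diabetes = 0, bmi = 25, smoker = 0,
    depression_score = 1, physical_activity = 30, alcohol_intake = 1,
    apoe4 = 0, stringsAsFactors = FALSE)
  maps <- c(100, 100, 250, 96:107)       # S3 is the gross outlier
  rows <- list()
  for (i in 1:n_sub) {
    nv <- if (i == 1) 1L else 2L
    map_base <- maps[i]
    for (w in seq_len(nv) - 1L) {
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = paste0("S", i), wave = w,
        time_in_study = 4 * w, age_at_visit = 45 + 4 * w,
        sbp_reading_1 = map_base + 20, sbp_reading_2 = map_base + 20,
        dbp_reading_1 = map_base - 10, dbp_reading_2 = map_base - 10,
        mmse = if (i == 2) 24 else 29,
        neuro_flag = 0L, scan_available = 1L, on_bp_med = 0L)
    }
  }
  list(subjects = subjects, visits = do.call(rbind, rows))
}

test_that("eligibility stages exclude in order and report counts", {
  toy <- make_toy_tables()
  res <- apply_eligibility(toy$subjects, toy$visits)
  expect_equal(res$report$stages$n_excluded, c(1, 1, 1, 0))
  expect_equal(res$report$n_final, 12)
  expect_false(any(c("S1", "S2", "S3") %in% res$subjects$subject_id))
  expect_equal(res$report$stages$n_entering, c(15, 14, 13, 12))
  # re-running on the filtered output is idempotent
  res2 <- apply_eligibility(res$subjects, res$visits)
  expect_identical(res2$subjects, res$subjects)
  expect_equal(sum(res2$report$stages$n_excluded), 0)
})

test_that("MMSE boundary of exactly 25 is retained (rule is strict <)", {
  toy <- make_toy_tables()
  toy$visits$mmse[toy$visits$subject_id == "S2"] <- 25
  res <- apply_eligibility(toy$subjects, toy$visits)
  expect_true("S2" %in% res$subjects$subject_id)
})

test_that("clean four-scan cohorts pass through unfiltered", {
  cfg <- tiny_config(attrition = c(0, 0, 0), neuro_rate_oa = 0,
                     mmse_mean = 29, mmse_sd = 0.1)
  d <- simulate_cohort(cfg, seed = 19)
  res <- apply_eligibility(d$subjects, d$visits)
  # only possible exclusions are BP outliers; none should be neuro/scan-based
  expect_equal(res$report$stages$n_excluded[1:2], c(0, 0))
})

test_that("missing required columns raise a schema error naming the column", {
  toy <- make_toy_tables()
  v <- toy$visits; v$mmse <- NULL
  expect_error(apply_eligibility(toy$subjects, v), "mmse")
  v2 <- toy$visits; v2$sbp_reading_1 <- NULL
  expect_error(apply_eligibility(toy$subjects, v2), "map")
})

test_that("EM imputation returns complete data unchanged", {
  set.seed(1)
  df <- data.frame(a = rnorm(20), b = rnorm(20))
  out <- em_impute(df)
  expect_equal(out$a, df$a)
  expect_equal(out$b, df$b)
  expect_identical(attr(out, "iterations"), 0L)
})

test_that("EM imputation recovers an exact linear relation", {
  x <- seq(1, 20)
  y <- 2 * x
  y[7] <- NA
  out <- em_impute(data.frame(x = x, y = y), missing_cap = 0.5)
  expect_equal(out$y[7], 2 * x[7], tolerance = 1e-6)
  expect_equal(out$y[-7], y[-7])  # observed cells untouched
})

test_that("EM-imputed column mean stays close to the pre-deletion mean under MCAR", {
  set.seed(42)
  n <- 400
  z <- rnorm(n)
  df <- data.frame(a = z + rnorm(n, 0, 0.5),
                   b = 2 * z + rnorm(n, 0, 0.5),
                   c = -z + rnorm(n, 0, 0.5))
  full_mean <- mean(df$a)
  drop <- sample(n, n * 0.05)
  df$a[drop] <- NA
  out <- em_impute(df)
  se <- sd(out$a) / sqrt(n)
  expect_lt(abs(mean(out$a) - full_mean), 3 * se)
  expect_true(attr(out, "converged"))
})

test_that("EM objective is monotone non-decreasing over iterations", {
  set.seed(9)
  n <- 120
  z <- rnorm(n)
  df <- data.frame(a = z + rnorm(n, 0, 1), b = z + rnorm(n, 0, 1),
                   c = z + rnorm(n, 0, 1))
  for (col in names(df)) df[[col]][sample(n, 8)] <- NA
  out <- em_impute(df, tol = 1e-10, max_iter = 50)
  ll <- attr(out, "loglik")
  expect_true(all(diff(ll) > -1e-6))
})

test_that("EM imputation rejects degenerate missingness", {
  df <- data.frame(a = c(NA_real_, NA_real_, NA_real_), b = c(1, 2, 3))
  expect_error(em_impute(df), "entirely missing")
  df2 <- data.frame(a = c(NA, NA, 1, 2, 3), b = 1:5)
  expect_error(em_impute(df2, missing_cap = 0.1), "cap")
})

test_that("binary covariates are imputed onto {0,1}", {
  set.seed(5)
  n <- 200
  z <- rnorm(n)
  bin <- as.numeric(z > 0)
  bin[sample(n, 10)] <- NA
  out <- em_impute(data.frame(z = z, flag = bin))
  expect_true(all(out$flag %in% c(0, 1)))
})
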
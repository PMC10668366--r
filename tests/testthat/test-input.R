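test_that("raw-data summaries match an independent moment computation", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(sample(3:40, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 3))
    y <- rnorm(sample(3:40, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 3))
    s <- study_summary(x = x, y = y)
    # single-pass oracle: sums and sums of squares
    m_x <- sum(x) / length(x)
    v_x <- (sum(x^2) - length(x) * m_x^2) / (length(x) - 1)
    expect_equal(s$mean_x, m_x, tolerance = 1e-12)
    expect_equal(s$sd_x, sqrt(v_x), tolerance = 1e-10)
    expect_equal(s$n_y, length(y))
    expect_identical(s$mode, "raw")
  }
  s <- study_summary(x = c(1, 2, 3), y = c(4, 5, 6, 7))
  expect_equal(s$mean_x, 2)
  expect_equal(s$sd_x, 1)
})

test_that("degenerate and invalid inputs are rejected, never coerced", {
  expect_error(study_summary(x = c(1, 1, 1), y = c(2, 2, 2)),
               class = "bfdesign_invalid_input")
  # one constant group is representable but degenerate at the t reduction
  s <- study_summary(x = c(1, 1, 1), y = c(1, 2, 3))
  expect_equal(s$sd_x, 0)
  expect_error(t_statistic(s), class = "bfdesign_degenerate_data")
  expect_error(study_summary(x = c(1, NA, 2), y = c(1, 2)),
               class = "bfdesign_invalid_input")
  expect_error(study_summary(x = 1, y = c(1, 2)),
               class = "bfdesign_invalid_input")
  expect_error(study_summary(n_x = 1, n_y = 10, mean_x = 0, mean_y = 1,
                             sd_x = 1, sd_y = 1),
               class = "bfdesign_invalid_input")
  # percentage-style confidence levels get a hint, not a silent rescale
  err <- tryCatch(study_summary(n_x = 10, n_y = 10, mean_x = 0, mean_y = 1,
                                ci_margin = 0.5, ci_level = 95),
                  error = identity)
  expect_s3_class(err, "bfdesign_invalid_input")
  expect_match(conditionMessage(err), "fraction")
  expect_error(study_summary(n_x = 10, n_y = 10, mean_x = 0, mean_y = 1,
                             ci_margin = -0.1, ci_level = 0.95),
               class = "bfdesign_invalid_input")
})

test_that("outcome files are read strictly (header allowed, garbage not)", {
  vals <- c(1.5, -2, 3.25, 0)
  expect_equal(read_outcomes(write_outcome_file(vals)), vals)
  expect_equal(read_outcomes(write_outcome_file(vals, header = "outcome")),
               vals)
  # blank lines are ignored
  p <- write_outcome_file(c("1", "", "2", "   ", "3"))
  expect_equal(read_outcomes(p), c(1, 2, 3))
  # non-numeric content mid-file is an error
  expect_error(read_outcomes(write_outcome_file(c("1", "two", "3"))),
               class = "bfdesign_invalid_input")
  expect_error(read_outcomes(tempfile()), class = "bfdesign_invalid_input")
})

test_that("equivalence interval argument semantics", {
  s <- summary_from_t(0.5, 100)
  expect_equal(bf_equivalence(summary = s, interval = 0.2)$design$interval,
               c(-0.2, 0.2))
  expect_equal(bf_equivalence(summary = s,
                              interval = c(-0.3, 0.2))$design$interval,
               c(-0.3, 0.2))
  expect_true(bf_equivalence(summary = s, interval = 0)$design$point_null)
  expect_true(bf_equivalence(summary = s,
                             interval = c(0, 0))$design$point_null)
  expect_error(bf_equivalence(summary = s, interval = c(0.2, -0.3)),
               class = "bfdesign_invalid_input")
  expect_error(bf_equivalence(summary = s, interval = -0.2),
               class = "bfdesign_invalid_input")
})

test_that("canonicalization negates the difference once and only once", {
  s <- study_summary(x = c(1, 2, 3), y = c(2, 3, 5))
  c_high <- canonicalize(s, "high")
  expect_equal(c_high$mean_y - c_high$mean_x, s$mean_y - s$mean_x)
  c_low <- canonicalize(s, "low")
  expect_equal(c_low$mean_y - c_low$mean_x, -(s$mean_y - s$mean_x))
  expect_equal(c_low$x, -s$x)
  # applying again with the canonical direction changes nothing
  again <- canonicalize(c_low, "high")
  expect_equal(again$mean_x, c_low$mean_x)
  expect_equal(again$y, c_low$y)
})

test_that("raw data and identical summary statistics give the same BF", {
  set.seed(21)
  x <- rnorm(18, 0, 1.3)
  y <- rnorm(25, 0.7, 1.1)
  fit_raw <- bf_superiority(x = x, y = y)
  fit_sum <- bf_superiority(n_x = 18, n_y = 25,
                            mean_x = mean(x), mean_y = mean(y),
                            sd_x = sd(x), sd_y = sd(y))
  expect_equal(fit_raw$log_bf, fit_sum$log_bf, tolerance = 1e-12)
})
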
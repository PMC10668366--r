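test_that("Bayes factors are formatted by magnitude without overflow", {
  expect_identical(format_bf(log(24)), "24.00")
  expect_identical(format_bf(log(0.2)), "0.20")
  expect_identical(format_bf(log(1.234e7)), "1.23e+07")
  expect_identical(format_bf(-log(1.234e7)), "8.10e-08")
  # far beyond double-precision range of exp()
  expect_identical(format_bf(5000 * log(10)), "1.00e+5000")
  expect_identical(format_bf(log(8.558e17)), "8.56e+17")
})

test_that("evidence labels follow the 3/20/150 thresholds", {
  expect_identical(label_evidence(10), "positive (towards H1)")
  expect_identical(label_evidence(1), "not worth more than a bare mention")
  expect_identical(label_evidence(200, orientation = "BF01"),
                   "very strong (towards H0)")
  expect_identical(label_evidence(3),
                   "not worth more than a bare mention (towards H1)")
  expect_identical(label_evidence(20), "positive (towards H1)")
  expect_identical(label_evidence(150), "strong (towards H1)")
  expect_identical(label_evidence(0.5, orientation = "BF10"),
                   "not worth more than a bare mention (towards H0)")
  fit <- duty_hours_fit()
  expect_identical(label_evidence(fit), "very strong (towards H1)")
})

test_that("console reports are deterministic and complete", {
  fit <- duty_hours_fit()
  out1 <- capture.output(print(fit))
  out2 <- capture.output(print(fit))
  expect_identical(out1, out2)
  txt <- paste(out1, collapse = "\n")
  expect_match(txt, "non-inferiority test")
  expect_match(txt, "CI for the mean difference")
  expect_match(txt, "margin: 1.0000 \\(unstandardized\\) = 1.0378")
  expect_match(txt, "prior scale: 0.7071")
  expect_match(txt, "BF10", fixed = TRUE)
  expect_match(txt, "towards the alternative hypothesis")

  eq <- bf_equivalence(summary = summary_from_t(0.5, 100),
                       interval = c(-0.3, 0.2))
  eq_txt <- paste(capture.output(print(eq)), collapse = "\n")
  expect_match(eq_txt, "-0.3000, 0.2000")
  expect_match(eq_txt, "BF01", fixed = TRUE)
})

test_that("exported curves round-trip the Savage-Dickey ratio", {
  fit <- bf_equivalence(summary = summary_from_t(1.1, 80))
  cv <- posterior_curve(fit, n = 301)
  path <- withr::local_tempfile(fileext = ".csv")
  export_curves(cv, path)

  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key) {
    as.numeric(sub(paste0("# ", key, ": "), "",
                   grep(key, meta, value = TRUE), fixed = TRUE))
  }
  ratio <- get_meta("posterior_density_at_null") /
    get_meta("prior_density_at_null")
  expect_equal(log(ratio), log_bf01(fit), tolerance = 1e-10)

  tab <- read.csv(path, comment.char = "#")
  expect_identical(nrow(tab), nrow(cv))
  expect_identical(names(tab),
                   c("delta", "prior_density", "posterior_density"))
  expect_true(all(tab$prior_density >= 0))
  expect_true(all(tab$posterior_density >= 0))
})

test_that("frequentist companion honors the design decision rules", {
  # t = 0: the superiority p value is the null median
  st_zero <- summary_from_t(0, 40)
  expect_equal(frequentist_companion(
    bf_superiority(summary = st_zero))$p_values[["superiority"]], 0.5)
  # TOST rejects iff the larger p value is below alpha
  fit <- bf_equivalence(summary = summary_from_t(0.2, 200), interval = 0.4)
  fr <- frequentist_companion(fit)
  expect_identical(fr$decision,
                   if (max(fr$p_values) < 0.05) "reject" else "retain")
  loose <- frequentist_companion(fit, alpha = max(fr$p_values) + 1e-6)
  expect_identical(loose$decision, "reject")
  tight <- frequentist_companion(fit, alpha = max(fr$p_values) - 1e-6)
  expect_identical(tight$decision, "retain")
})

test_that("plot method draws and returns the curve invisibly", {
  fit <- bf_superiority(summary = summary_from_t(2, 30))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  cv <- plot(fit)
  grDevices::dev.off()
  expect_s3_class(cv, "density_curve")
  expect_true(file.exists(path))
})
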
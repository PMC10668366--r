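# Build a balanced means-and-SDs study summary whose pooled two-sample
# t statistic is exactly `t`, with df = n_x + n_y - 2 (df must be even).
summary_from_t <- function(t, df, sd = 1) {
  stopifnot(df %% 2 == 0)
  n <- df / 2 + 1
  se <- sd * sqrt(2 / n)
  study_summary(n_x = n, n_y = n, mean_x = 0, mean_y = t * se,
                sd_x = sd, sd_y = sd)
}

# the duty-hour reanalysis inputs (CI mode, low scores favorable)
duty_hours_fit <- function(...) {
  bf_noninferiority(n_x = 193, n_y = 205, mean_x = 4.7, mean_y = 4.8,
                    ci_margin = 0.19, ci_level = 0.95,
                    ni_margin = 1, ni_margin_std = FALSE,
                    direction = "low", prior_scale = 1 / sqrt(2), ...)
}

write_outcome_file <- function(values, header = NULL) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c(header, format(values, digits = 15)), path)
  path
}
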
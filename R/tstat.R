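#' Effective sample size of a two-group design
#'
#' The effective sample size \eqn{n_{\mathrm{eff}} = n_x n_y/(n_x + n_y)}
#' scales the standardized effect size to the noncentrality of the
#' two-sample t statistic: \eqn{t} has noncentrality
#' \eqn{\delta\sqrt{n_{\mathrm{eff}}}}.
#'
#' @param n_x,n_y Group sample sizes (each at least 2).
#' @return A positive number, never exceeding `min(n_x, n_y)`.
#' @examples
#' effective_sample_size(205, 193)
#' @export
effective_sample_size <- function(n_x, n_y) {
  .check_n(n_x, "n_x")
  .check_n(n_y, "n_y")
  n_x * n_y / (n_x + n_y)
}

#' Reduce a study summary to its two-sample t statistic
#'
#' Computes the pooled-variance two-sample t statistic for the
#' experimental-minus-control mean difference, together with the
#' quantities the Bayes factor engine needs: degrees of freedom
#' \eqn{n_x + n_y - 2}, effective sample size, the observed standardized
#' effect \eqn{d = t/\sqrt{n_{\mathrm{eff}}}}, the standard error of the
#' mean difference, and the pooled standard deviation.
#'
#' In confidence-interval mode the standard error is recovered as
#' `ci_margin / Q`, where `Q` is the central Student-t quantile at
#' probability `(1 + ci_level)/2` with `n_x + n_y - 2` degrees of
#' freedom, and the pooled standard deviation as
#' `se / sqrt(1/n_x + 1/n_y)` (used to standardize unstandardized
#' margins).
#'
#' @param summary A [study_summary()] object.
#' @return An object of class `"t_stat"`: a list with elements `t`,
#'   `df`, `n_eff`, `d_obs`, `se_diff`, `sd_pooled`, `n_x`, `n_y`.
#' @examples
#' s <- study_summary(n_x = 193, n_y = 205, mean_x = 4.7, mean_y = 4.8,
#'                    ci_margin = 0.19, ci_level = 0.95)
#' t_statistic(s)
#' @export
t_statistic <- function(summary) {
  stopifnot(inherits(summary, "study_summary"))
  n_x <- summary$n_x
  n_y <- summary$n_y
  df <- n_x + n_y - 2
  n_eff <- n_x * n_y / (n_x + n_y)
  diff <- summary$mean_y - summary$mean_x

  if (summary$mode %in% c("raw", "means_sds")) {
    if (summary$sd_x == 0 || summary$sd_y == 0) {
      stop_degenerate("zero standard deviation in a group: the pooled-",
                      "variance t statistic is degenerate")
    }
    sd_pooled <- sqrt(((n_x - 1) * summary$sd_x^2 +
                         (n_y - 1) * summary$sd_y^2) / df)
    se_diff <- sd_pooled * sqrt(1 / n_x + 1 / n_y)
  } else {
    q <- stats::qt((1 + summary$ci_level) / 2, df)
    se_diff <- summary$ci_margin / q
    sd_pooled <- se_diff / sqrt(1 / n_x + 1 / n_y)
  }
  if (se_diff <= 0 || !is.finite(se_diff)) {
    stop_degenerate("degenerate standard error of the mean difference")
  }
  t <- diff / se_diff
  structure(
    list(t = t, df = df, n_eff = n_eff, d_obs = t / sqrt(n_eff),
         se_diff = se_diff, sd_pooled = sd_pooled, n_x = n_x, n_y = n_y),
    class = "t_stat"
  )
}

#' @export
print.t_stat <- function(x, ...) {
  cat(sprintf("two-sample t = %.4f, df = %d, n_eff = %.3f, d = %.4f\n",
              x$t, x$df, x$n_eff, x$d_obs))
  invisible(x)
}
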
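# Companion frequentist tests. All work on the canonical
# (high-favorable) t statistic and standardized margins.

.freq_result <- function(p_values, alpha, reject, design) {
  structure(
    list(p_values = p_values, alpha = alpha,
         decision = if (reject) "reject" else "retain", design = design),
    class = "freq_result"
  )
}

.freq_superiority <- function(stat, alpha) {
  p <- stats::pt(stat$t, stat$df, lower.tail = FALSE)
  .freq_result(c(superiority = p), alpha, p < alpha, "superiority")
}

.freq_noninferiority <- function(stat, c_std, alpha) {
  t_c <- stat$t + c_std * sqrt(stat$n_eff)
  p <- stats::pt(t_c, stat$df, lower.tail = FALSE)
  .freq_result(c(noninferiority = p), alpha, p < alpha, "noninferiority")
}

# TOST: two one-sided tests against the interval bounds; equivalence is
# established iff max(p_lower, p_upper) < alpha
.freq_equivalence <- function(stat, bounds, alpha) {
  rootq <- sqrt(stat$n_eff)
  p_lower <- stats::pt(stat$t - bounds[1L] * rootq, stat$df,
                       lower.tail = FALSE)
  p_upper <- stats::pt(stat$t - bounds[2L] * rootq, stat$df,
                       lower.tail = TRUE)
  .freq_result(c(p_lower = p_lower, p_upper = p_upper), alpha,
               max(p_lower, p_upper) < alpha, "equivalence")
}

#' Companion frequentist test of a fitted Bayes factor test
#'
#' Returns the frequentist test matching the design of a fitted
#' [bftest]: a one-sided t test for superiority, the one-sided test
#' against the shifted null for non-inferiority, or the two one-sided
#' tests (TOST) against the equivalence bounds, whose decision rule
#' rejects non-equivalence iff the larger of the two p values is below
#' `alpha`.
#'
#' @param object A fitted [bftest] object.
#' @param alpha Optional significance level; when supplied, the test is
#'   re-evaluated at this level (p values are unchanged).
#' @return An object of class `"freq_result"` with elements `p_values`,
#'   `alpha`, `decision` (`"reject"` or `"retain"`), `design`.
#' @export
frequentist_companion <- function(object, alpha = NULL) {
  stopifnot(inherits(object, "bftest"))
  fr <- object$frequentist
  if (is.null(fr)) {
    stop_invalid("this result carries no frequentist companion")
  }
  if (!is.null(alpha)) {
    if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 ||
        alpha >= 1) {
      stop_invalid("'alpha' must lie strictly between 0 and 1")
    }
    reject <- if (fr$design == "equivalence") {
      max(fr$p_values) < alpha
    } else {
      fr$p_values[[1L]] < alpha
    }
    fr <- .freq_result(fr$p_values, alpha, reject, fr$design)
  }
  fr
}

#' @export
print.freq_result <- function(x, ...) {
  lbl <- switch(x$design,
                superiority = "One-sided t test (superiority)",
                noninferiority = "One-sided t test against the margin",
                equivalence = "Two one-sided tests (TOST)")
  cat(lbl, "\n", sep = "")
  for (nm in names(x$p_values)) {
    cat(sprintf("  %s: p = %s\n", nm, format.pval(x$p_values[[nm]],
                                                  digits = 4, eps = 1e-16)))
  }
  cat(sprintf("  decision at alpha = %g: %s\n", x$alpha, x$decision))
  invisible(x)
}
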
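#' Format a Bayes factor from its natural log
#'
#' Scientific notation with three significant digits when
#' \eqn{|\log_{10} BF| \ge 4}, otherwise fixed notation with two
#' decimals. The value is rendered from the log, so astronomically large
#' or small Bayes factors never overflow.
#'
#' @param log_bf Natural log of the Bayes factor.
#' @return A character string such as `"8.56e+17"` or `"0.25"`.
#' @export
format_bf <- function(log_bf) {
  l10 <- log_bf / log(10)
  if (abs(l10) >= 4) {
    e <- floor(l10)
    m <- 10^(l10 - e)
    if (round(m, 2) >= 10) {
      m <- m / 10
      e <- e + 1
    }
    sprintf("%.2fe%+03d", m, e)
  } else {
    sprintf("%.2f", exp(log_bf))
  }
}

#' Verbal evidence category of a Bayes factor
#'
#' Applies the conventional thresholds 3, 20, and 150 to the Bayes
#' factor in favor of whichever hypothesis it favors (i.e., to
#' \eqn{\max(BF_{10}, BF_{01})}): values up to 3 are "not worth more
#' than a bare mention", values in (3, 20] are "positive", values in
#' (20, 150] are "strong", and values above 150 are "very strong".
#'
#' @param bf A fitted [bftest] object, or a numeric Bayes factor.
#' @param orientation For numeric input, the orientation of `bf`
#'   (`"BF10"` or `"BF01"`), used only to name the favored hypothesis.
#' @return A string: the category, plus the favored hypothesis for
#'   fitted tests or oriented numeric input.
#' @examples
#' label_evidence(10)    # "positive (towards H1)"
#' label_evidence(200, orientation = "BF01")
#' @export
label_evidence <- function(bf, orientation = c("BF10", "BF01")) {
  if (inherits(bf, "bftest")) {
    lb10 <- log_bf10(bf)
  } else {
    orientation <- match.arg(orientation)
    if (!is.numeric(bf) || length(bf) != 1L || bf <= 0) {
      stop_invalid("'bf' must be a single positive number")
    }
    lb10 <- if (orientation == "BF10") log(bf) else -log(bf)
  }
  strength <- abs(lb10)
  category <- if (strength <= log(3)) {
    "not worth more than a bare mention"
  } else if (strength <= log(20)) {
    "positive"
  } else if (strength <= log(150)) {
    "strong"
  } else {
    "very strong"
  }
  favored <- if (lb10 > 0) "H1" else if (lb10 < 0) "H0" else "neither"
  if (favored == "neither") category
  else paste0(category, " (towards ", favored, ")")
}

.data_mode_text <- function(summary) {
  switch(summary$mode,
         raw = "raw outcome data",
         means_sds = "summary statistics (means and SDs)",
         means_ci = "summary statistics (means and CI for the mean difference)")
}

.design_title <- function(design) {
  switch(design,
         superiority = "Bayesian superiority test",
         equivalence = "Bayesian equivalence test",
         noninferiority = "Bayesian non-inferiority test",
         savage_dickey = "Savage-Dickey density-ratio test")
}

# Assemble the full console report as a character vector; a pure
# function of the fitted object, byte-stable across runs.
.report_lines <- function(x) {
  d <- x$design
  lines <- c(.design_title(d$design),
             strrep("-", nchar(.design_title(d$design))))
  if (!is.null(x$summary)) {
    lines <- c(lines, paste0("Data: ", .data_mode_text(x$summary)))
  }
  lines <- c(lines,
             paste0("H0: ", x$h0),
             paste0("H1: ", x$h1))
  if (!is.null(d$direction)) {
    lines <- c(lines, sprintf("Direction: %s scores are favorable",
                              d$direction))
  }
  if (identical(d$design, "noninferiority")) {
    lines <- c(lines, if (d$ni_margin_std_input) {
      sprintf("Non-inferiority margin: %.4f (standardized)", d$ni_margin)
    } else {
      sprintf("Non-inferiority margin: %.4f (unstandardized) = %.4f (standardized)",
              d$ni_margin_raw, d$ni_margin)
    })
  }
  if (identical(d$design, "equivalence")) {
    lines <- c(lines, if (d$point_null) {
      "Equivalence interval: point null at delta = 0"
    } else if (d$interval_std_input) {
      sprintf("Equivalence interval: [%.4f, %.4f] (standardized)",
              d$interval[1L], d$interval[2L])
    } else {
      sprintf("Equivalence interval: [%.4f, %.4f] (unstandardized) = [%.4f, %.4f] (standardized)",
              d$interval_raw[1L], d$interval_raw[2L],
              d$interval[1L], d$interval[2L])
    })
  }
  if (!is.null(d$prior_scale)) {
    lines <- c(lines, sprintf("Cauchy prior scale: %.4f", d$prior_scale))
  }
  towards <- if (x$log_bf > 0) {
    if (x$orientation == "BF10") "alternative" else "null"
  } else if (x$log_bf < 0) {
    if (x$orientation == "BF10") "null" else "alternative"
  } else {
    "neither"
  }
  note <- if (towards == "neither") {
    "(uninformative)"
  } else {
    sprintf("[evidence towards the %s hypothesis]", towards)
  }
  lines <- c(lines,
             sprintf("%s = %s  %s",
                     sub("BF10", "BF10", x$orientation), format_bf(x$log_bf),
                     note),
             paste0("Evidence: ", label_evidence(x)))
  lines
}

#' @export
print.bftest <- function(x, ...) {
  cat(.report_lines(x), sep = "\n")
  invisible(x)
}

#' @export
summary.bftest <- function(object, ...) {
  structure(list(fit = object), class = "summary.bftest")
}

#' @export
print.summary.bftest <- function(x, ...) {
  print(x$fit)
  s <- x$fit$stat
  if (!is.null(s)) {
    cat(sprintf("\nt = %.4f, df = %d, n_eff = %.3f, observed d = %.4f\n",
                s$t, s$df, s$n_eff, s$d_obs))
    cat(sprintf("SE(difference) = %.5f, pooled SD = %.5f\n",
                s$se_diff, s$sd_pooled))
  }
  if (!is.null(x$fit$frequentist)) {
    cat("\n")
    print(x$fit$frequentist)
  }
  invisible(x)
}

#' Savage-Dickey plot of a fitted test
#'
#' Draws the (possibly truncated) prior and posterior densities of the
#' standardized effect size, with dots at the null point whose height
#' ratio is the point-null Bayes factor.
#'
#' @param x A fitted [bftest] object.
#' @param n Grid resolution.
#' @param ... Passed to [graphics::plot()].
#' @return The [posterior_curve()] used, invisibly.
#' @export
plot.bftest <- function(x, n = 513L, ...) {
  cv <- posterior_curve(x, n = n)
  null_point <- attr(cv, "null_point")
  ymax <- max(cv$prior_density, cv$posterior_density)
  graphics::plot(cv$delta, cv$posterior_density, type = "l", lwd = 2,
                 xlab = expression(delta), ylab = "density",
                 ylim = c(0, ymax * 1.05),
                 main = .design_title(x$design$design), ...)
  graphics::lines(cv$delta, cv$prior_density, lty = 2)
  if (null_point >= min(cv$delta) && null_point <= max(cv$delta)) {
    st <- attr(cv, "stat")
    pr <- attr(cv, "prior")
    pr_at <- prior_density(pr, null_point)
    po_at <- exp(likelihood_t(st$t, st$df, null_point, st$n_eff,
                              log = TRUE) +
                   prior_density(pr, null_point, log = TRUE) -
                   attr(cv, "log_marginal"))
    graphics::points(c(null_point, null_point), c(pr_at, po_at),
                     pch = 19, col = c("grey40", "black"))
  }
  graphics::legend("topright", legend = c("posterior", "prior"),
                   lwd = c(2, 1), lty = c(1, 2), bty = "n")
  invisible(cv)
}
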
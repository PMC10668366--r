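#' Bayes factor tests for two-group superiority, equivalence, and
#' non-inferiority designs
#'
#' @description
#' The three fitting functions share one engine. Data may be supplied as
#' raw outcome vectors (`x`, `y`), as per-group summary statistics, or
#' as group means plus a confidence interval for the mean difference;
#' alternatively a prebuilt [study_summary()] can be passed via
#' `summary`. Inference is on the standardized effect size
#' \eqn{\delta = (\mu_e - \mu_c)/\sigma}; under the alternative,
#' \eqn{\delta} carries a Cauchy prior with scale `prior_scale`
#' (default \eqn{1/\sqrt 2}), and the nuisance variance is integrated
#' out analytically (Jeffreys prior), so every marginal likelihood is a
#' one-dimensional prior-weighted average of a noncentral-t density.
#'
#' * `bf_superiority()` tests \eqn{H_0\colon \delta = 0} against the
#'   one-sided \eqn{H_1\colon \delta > 0} (after direction
#'   canonicalization), with a half-Cauchy prior on the favorable side.
#'   The Bayes factor is reported as \eqn{BF_{10}}.
#' * `bf_noninferiority()` tests \eqn{H_0\colon \delta = -c} against
#'   \eqn{H_1\colon \delta > -c}, where \eqn{c \ge 0} is the
#'   standardized non-inferiority margin. Under \eqn{H_1} the Cauchy
#'   prior remains centered at \eqn{\delta = 0} and is truncated to
#'   \eqn{(-c, \infty)}; the Bayes factor equals the Savage-Dickey
#'   ratio of the truncated prior and posterior at the margin and is
#'   reported as \eqn{BF_{10}}.
#' * `bf_equivalence()` tests a point null \eqn{\delta = 0} (the
#'   default) via the Savage-Dickey density ratio under the full Cauchy
#'   model, or an interval null \eqn{\delta \in (l, u)} via the ratio of
#'   posterior to prior odds of the interval against its complement.
#'   The Bayes factor is reported as \eqn{BF_{01}}.
#'
#' Unstandardized margins are divided by the pooled standard deviation
#' (recovered from the standard error in confidence-interval mode). A
#' companion frequentist test (one-sided t, or TOST for equivalence) is
#' computed alongside and stored in the result.
#'
#' @param x,y,n_x,n_y,mean_x,mean_y,sd_x,sd_y,ci_margin,ci_level Data in
#'   one of the three input modes; see [study_summary()].
#' @param summary A prebuilt [study_summary()] (overrides the data
#'   arguments).
#' @param direction `"high"` if high outcome scores are favorable,
#'   `"low"` otherwise. Required concept for the directional designs;
#'   equivalence is unaffected by direction.
#' @param interval Equivalence interval: a single nonnegative value `v`
#'   expands to `(-v, v)`; a pair is taken verbatim; `0` (or `c(0, 0)`,
#'   the default) is the point null.
#' @param interval_std Are the interval bounds already standardized
#'   (\eqn{\delta} units)? If `FALSE` they are divided by the pooled SD.
#' @param ni_margin Non-inferiority margin \eqn{c \ge 0}.
#' @param ni_margin_std Is `ni_margin` in standardized units?
#' @param prior_scale Cauchy prior scale \eqn{r > 0}.
#' @param alpha Significance level for the companion frequentist test.
#'
#' @return An object of class `"bftest"`: a list with elements `log_bf`
#'   (natural log of the Bayes factor, in the stated orientation),
#'   `orientation` (`"BF10"` or `"BF01"`), `h0`/`h1` (hypothesis text),
#'   `design` (resolved design settings, margins in both unit systems
#'   where converted), `prior` (the [cauchy_prior()] used under
#'   \eqn{H_1}), `stat` (the [t_statistic()] reduction in canonical
#'   orientation), `summary` (the input echo), and `frequentist`.
#'
#' @examples
#' bf_noninferiority(n_x = 193, n_y = 205, mean_x = 4.7, mean_y = 4.8,
#'                   ci_margin = 0.19, ci_level = 0.95,
#'                   ni_margin = 1, ni_margin_std = FALSE,
#'                   direction = "low")
#' @name bftest
NULL

.assemble_summary <- function(x, y, n_x, n_y, mean_x, mean_y, sd_x, sd_y,
                              ci_margin, ci_level, summary) {
  if (!is.null(summary)) {
    stopifnot(inherits(summary, "study_summary"))
    return(summary)
  }
  study_summary(x = x, y = y, n_x = n_x, n_y = n_y,
                mean_x = mean_x, mean_y = mean_y,
                sd_x = sd_x, sd_y = sd_y,
                ci_margin = ci_margin, ci_level = ci_level)
}

.check_prior_scale <- function(prior_scale) {
  if (!is.numeric(prior_scale) || length(prior_scale) != 1L ||
      !is.finite(prior_scale) || prior_scale <= 0) {
    stop_invalid("'prior_scale' must be a single positive number")
  }
}

# one-sided point-null test: H0 at the (possibly zero) margin -c, H1 the
# center-0 Cauchy truncated to delta > -c; returns log BF10
.log_bf_onesided <- function(stat, margin_std, prior_scale) {
  prior <- cauchy_prior(0, prior_scale, support = "greater_than",
                        bound = -margin_std)
  log_num <- log_marginal_likelihood(stat, prior)
  log_den <- likelihood_t(stat$t, stat$df, -margin_std, stat$n_eff,
                          log = TRUE)
  list(log_bf10 = log_num - log_den, prior = prior)
}

#' @rdname bftest
#' @export
bf_superiority <- function(x = NULL, y = NULL, n_x = NULL, n_y = NULL,
                           mean_x = NULL, mean_y = NULL,
                           sd_x = NULL, sd_y = NULL,
                           ci_margin = NULL, ci_level = NULL,
                           direction = c("high", "low"),
                           prior_scale = 1 / sqrt(2), alpha = 0.05,
                           summary = NULL) {
  direction <- match.arg(direction)
  .check_prior_scale(prior_scale)
  input <- .assemble_summary(x, y, n_x, n_y, mean_x, mean_y, sd_x, sd_y,
                             ci_margin, ci_level, summary)
  canon <- canonicalize(input, direction)
  stat <- t_statistic(canon)
  fit <- .log_bf_onesided(stat, 0, prior_scale)
  freq <- .freq_superiority(stat, alpha)
  .bftest_result(
    log_bf = fit$log_bf10, orientation = "BF10",
    h0 = "delta = 0", h1 = "delta > 0 (favorable side)",
    design = list(design = "superiority", direction = direction,
                  prior_scale = prior_scale),
    prior = fit$prior, stat = stat, summary = input, frequentist = freq
  )
}

#' @rdname bftest
#' @export
bf_noninferiority <- function(x = NULL, y = NULL, n_x = NULL, n_y = NULL,
                              mean_x = NULL, mean_y = NULL,
                              sd_x = NULL, sd_y = NULL,
                              ci_margin = NULL, ci_level = NULL,
                              ni_margin, ni_margin_std = TRUE,
                              direction = c("high", "low"),
                              prior_scale = 1 / sqrt(2), alpha = 0.05,
                              summary = NULL) {
  direction <- match.arg(direction)
  .check_prior_scale(prior_scale)
  if (missing(ni_margin) || !is.numeric(ni_margin) ||
      length(ni_margin) != 1L || !is.finite(ni_margin) || ni_margin < 0) {
    stop_invalid("'ni_margin' must be a single nonnegative number")
  }
  input <- .assemble_summary(x, y, n_x, n_y, mean_x, mean_y, sd_x, sd_y,
                             ci_margin, ci_level, summary)
  canon <- canonicalize(input, direction)
  stat <- t_statistic(canon)
  if (ni_margin_std) {
    c_std <- ni_margin
    c_raw <- ni_margin * stat$sd_pooled
  } else {
    if (stat$sd_pooled == 0) {
      stop_degenerate("pooled SD is zero; cannot standardize the margin")
    }
    c_std <- ni_margin / stat$sd_pooled
    c_raw <- ni_margin
  }
  fit <- .log_bf_onesided(stat, c_std, prior_scale)
  freq <- .freq_noninferiority(stat, c_std, alpha)
  .bftest_result(
    log_bf = fit$log_bf10, orientation = "BF10",
    h0 = sprintf("delta = %.4g (worse by exactly the margin)", -c_std),
    h1 = sprintf("delta > %.4g (not worse than the margin)", -c_std),
    design = list(design = "noninferiority", direction = direction,
                  ni_margin = c_std, ni_margin_raw = c_raw,
                  ni_margin_std_input = ni_margin_std,
                  prior_scale = prior_scale),
    prior = fit$prior, stat = stat, summary = input, frequentist = freq
  )
}

#' @rdname bftest
#' @export
bf_equivalence <- function(x = NULL, y = NULL, n_x = NULL, n_y = NULL,
                           mean_x = NULL, mean_y = NULL,
                           sd_x = NULL, sd_y = NULL,
                           ci_margin = NULL, ci_level = NULL,
                           interval = 0, interval_std = TRUE,
                           prior_scale = 1 / sqrt(2), alpha = 0.05,
                           summary = NULL) {
  .check_prior_scale(prior_scale)
  bounds_in <- .expand_interval(interval)
  input <- .assemble_summary(x, y, n_x, n_y, mean_x, mean_y, sd_x, sd_y,
                             ci_margin, ci_level, summary)
  stat <- t_statistic(input)
  if (interval_std) {
    bounds <- bounds_in
    bounds_raw <- bounds_in * stat$sd_pooled
  } else {
    if (stat$sd_pooled == 0) {
      stop_degenerate("pooled SD is zero; cannot standardize the interval")
    }
    bounds <- bounds_in / stat$sd_pooled
    bounds_raw <- bounds_in
  }
  prior <- cauchy_prior(0, prior_scale)
  point_null <- bounds[1L] == 0 && bounds[2L] == 0

  if (point_null) {
    log_marg <- log_marginal_likelihood(stat, prior)
    log_bf01 <- likelihood_t(stat$t, stat$df, 0, stat$n_eff, log = TRUE) -
      log_marg
    h0 <- "delta = 0"
    h1 <- "delta != 0"
  } else {
    log_in <- .log_weighted_region(stat, prior, bounds[1L], bounds[2L])
    log_out <- .logsumexp2(
      .log_weighted_region(stat, prior, -Inf, bounds[1L]),
      .log_weighted_region(stat, prior, bounds[2L], Inf)
    )
    if (!is.finite(log_in) || !is.finite(log_out)) {
      stop_numerical("equivalence interval lies outside the numerical ",
                     "support of the posterior",
                     diagnostics = list(bounds = bounds))
    }
    p_in <- interval_mass(prior, bounds[1L], bounds[2L])
    log_prior_odds <- log(p_in) - log1p(-p_in)
    log_bf01 <- (log_in - log_out) - log_prior_odds
    h0 <- sprintf("delta in (%.4g, %.4g)", bounds[1L], bounds[2L])
    h1 <- sprintf("delta outside (%.4g, %.4g)", bounds[1L], bounds[2L])
  }
  freq <- .freq_equivalence(stat, bounds, alpha)
  .bftest_result(
    log_bf = log_bf01, orientation = "BF01",
    h0 = h0, h1 = h1,
    design = list(design = "equivalence",
                  interval = bounds, interval_raw = bounds_raw,
                  interval_std_input = interval_std,
                  point_null = point_null, prior_scale = prior_scale),
    prior = prior, stat = stat, summary = input, frequentist = freq
  )
}

.bftest_result <- function(log_bf, orientation, h0, h1, design, prior,
                           stat, summary, frequentist) {
  if (!is.finite(log_bf)) {
    stop_numerical("Bayes factor computation returned a non-finite log BF",
                   diagnostics = list(log_bf = log_bf, design = design))
  }
  structure(
    list(log_bf = log_bf, orientation = orientation, h0 = h0, h1 = h1,
         design = design, prior = prior, stat = stat, summary = summary,
         frequentist = frequentist),
    class = "bftest"
  )
}

#' Extract Bayes factor values and update odds
#'
#' `bf10()` and `bf01()` return the Bayes factor of a fitted test in the
#' requested orientation (converting orientation negates the log Bayes
#' factor, since \eqn{BF_{10} = 1/BF_{01}}); `log_bf10()`/`log_bf01()`
#' return the natural logs, which never overflow. `update_odds()`
#' multiplies prior odds by a Bayes factor to give posterior odds.
#'
#' @param object A fitted [bftest] object.
#' @param prior_odds Prior odds (a positive number).
#' @param bf A Bayes factor: a positive number or a `bftest` object (its
#'   value in its stated orientation).
#' @return A single number.
#' @examples
#' update_odds(2, 24)  # posterior odds 48
#' @name bf-extract
NULL

#' @rdname bf-extract
#' @export
log_bf10 <- function(object) {
  stopifnot(inherits(object, "bftest"))
  if (object$orientation == "BF10") object$log_bf else -object$log_bf
}

#' @rdname bf-extract
#' @export
log_bf01 <- function(object) -log_bf10(object)

#' @rdname bf-extract
#' @export
bf10 <- function(object) exp(log_bf10(object))

#' @rdname bf-extract
#' @export
bf01 <- function(object) exp(log_bf01(object))

#' @rdname bf-extract
#' @export
update_odds <- function(prior_odds, bf) {
  if (inherits(bf, "bftest")) bf <- exp(bf$log_bf)
  if (!is.numeric(prior_odds) || prior_odds <= 0 || !is.numeric(bf) ||
      bf <= 0) {
    stop_invalid("'prior_odds' and 'bf' must be positive numbers")
  }
  prior_odds * bf
}
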
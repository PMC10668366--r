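#' Matched prior and posterior density curves for Savage-Dickey plots
#'
#' Evaluates the (possibly truncated) prior and the corresponding
#' normalized posterior of the standardized effect size \eqn{\delta} on
#' a grid. The default grid covers the central 99.9% of the prior mass
#' within its support, widened to include the posterior bulk around the
#' observed effect.
#'
#' @param object A fitted [bftest] object, or a [t_statistic()] object
#'   (in which case `prior` is required).
#' @param prior A [cauchy_prior()]; taken from `object` when it is a
#'   fitted test.
#' @param range Optional length-2 grid range in \eqn{\delta} units
#'   (clipped to the prior support).
#' @param n Number of grid points.
#' @return A data frame of class `"density_curve"` with columns `delta`,
#'   `prior_density`, `posterior_density`, and attributes `stat`,
#'   `prior`, `log_marginal`, `null_point`, `truncation_bound`.
#' @export
posterior_curve <- function(object, prior = NULL, range = NULL, n = 1025L) {
  null_point <- 0
  if (inherits(object, "bftest")) {
    stat <- object$stat
    prior <- object$prior
    if (identical(object$design$design, "noninferiority")) {
      null_point <- -object$design$ni_margin
    }
  } else if (inherits(object, "t_stat")) {
    stat <- object
    if (is.null(prior)) stop_invalid("'prior' is required")
  } else {
    stop_invalid("'object' must be a 'bftest' or 't_stat' object")
  }
  stopifnot(inherits(prior, "cauchy_prior"))

  if (is.null(range)) {
    # non-uniform default grid: a dense core under the prior peak and
    # the posterior bulk, plus geometrically spaced tails reaching the
    # central 99.9% prior mass within the support (Cauchy tails are far
    # too heavy for a uniform grid of practical size)
    pl <- stats::pcauchy(prior$lower, prior$center, prior$scale)
    ph <- stats::pcauchy(prior$upper, prior$center, prior$scale)
    qtr <- function(p) stats::qcauchy(pl + p * (ph - pl),
                                      prior$center, prior$scale)
    half_w <- 12 / sqrt(stat$n_eff)
    core_lo <- max(prior$lower,
                   min(prior$center - 12 * prior$scale,
                       stat$d_obs - half_w))
    core_hi <- min(prior$upper,
                   max(prior$center + 12 * prior$scale,
                       stat$d_obs + half_w))
    tail_lo <- max(prior$lower, qtr(5e-4))
    tail_hi <- min(prior$upper, qtr(1 - 5e-4))
    n_tail <- ceiling(n / 10)
    h0 <- (core_hi - core_lo) / n
    geom_tail <- function(from, to) {
      # from the core edge outward, spacing growing geometrically
      if (abs(to - from) <= h0) return(numeric(0))
      from + sign(to - from) *
        exp(seq(log(h0), log(abs(to - from)), length.out = n_tail))
    }
    grid <- sort(unique(c(
      seq(core_lo, core_hi, length.out = n),
      geom_tail(core_lo, tail_lo),
      geom_tail(core_hi, tail_hi)
    )))
  } else {
    if (length(range) != 2L || range[1L] >= range[2L]) {
      stop_invalid("'range' must be an increasing pair")
    }
    lo <- max(prior$lower, range[1L])
    hi <- min(prior$upper, range[2L])
    if (lo >= hi) stop_invalid("'range' lies outside the prior support")
    grid <- seq(lo, hi, length.out = n)
  }
  log_marg <- log_marginal_likelihood(stat, prior)
  pr <- prior_density(prior, grid)
  po <- exp(likelihood_t(stat$t, stat$df, grid, stat$n_eff, log = TRUE) +
              prior_density(prior, grid, log = TRUE) - log_marg)
  if (!all(is.finite(po))) {
    stop_numerical("posterior normalization failed on the grid")
  }
  out <- data.frame(delta = grid, prior_density = pr,
                    posterior_density = po)
  class(out) <- c("density_curve", "data.frame")
  attr(out, "stat") <- stat
  attr(out, "prior") <- prior
  attr(out, "log_marginal") <- log_marg
  attr(out, "null_point") <- null_point
  attr(out, "truncation_bound") <-
    if (is.finite(prior$lower)) prior$lower
    else if (is.finite(prior$upper)) prior$upper
    else NA_real_
  out
}

#' Savage-Dickey density-ratio Bayes factor
#'
#' For a point null nested in the alternative, the Bayes factor in favor
#' of the null equals the ratio of the posterior to the prior density of
#' \eqn{\delta} at the null value. When the input carries the fitted
#' model (a [bftest] or a [posterior_curve()] built from one), the two
#' densities are evaluated directly at the point; for a bare curve the
#' densities are interpolated linearly on the grid.
#'
#' @param object A [bftest], a [posterior_curve()] result, or a data
#'   frame with columns `delta`, `prior_density`, `posterior_density`.
#' @param point The null value of \eqn{\delta}; defaults to the curve's
#'   null point (0, or the non-inferiority margin).
#' @return A `"bftest"` object with orientation `BF01`.
#' @export
savage_dickey <- function(object, point = NULL) {
  if (inherits(object, "bftest")) {
    stat <- object$stat
    prior <- object$prior
    log_marg <- NULL
    if (is.null(point)) {
      point <- if (identical(object$design$design, "noninferiority")) {
        -object$design$ni_margin
      } else 0
    }
  } else if (inherits(object, "density_curve") &&
             !is.null(attr(object, "stat"))) {
    stat <- attr(object, "stat")
    prior <- attr(object, "prior")
    log_marg <- attr(object, "log_marginal")
    if (is.null(point)) point <- attr(object, "null_point")
  } else if (is.data.frame(object)) {
    if (is.null(point)) stop_invalid("'point' is required for a bare curve")
    if (point < min(object$delta) || point > max(object$delta)) {
      stop_invalid("'point' lies outside the curve's grid range")
    }
    pr <- stats::approx(object$delta, object$prior_density, xout = point)$y
    po <- stats::approx(object$delta, object$posterior_density,
                        xout = point)$y
    if (!is.finite(pr) || pr <= 0) {
      stop_invalid("prior density is zero at 'point' (outside support)")
    }
    return(.savage_dickey_result(log(po) - log(pr), point))
  } else {
    stop_invalid("unsupported input to savage_dickey()")
  }
  # direct evaluation: the prior densities cancel, leaving
  # log f(t | point) - log marginal
  lpr <- prior_density(prior, point, log = TRUE)
  if (!is.finite(lpr)) {
    stop_invalid("prior density is zero at 'point' (outside support)")
  }
  if (is.null(log_marg)) log_marg <- log_marginal_likelihood(stat, prior)
  log_bf01 <- likelihood_t(stat$t, stat$df, point, stat$n_eff,
                           log = TRUE) - log_marg
  .savage_dickey_result(log_bf01, point)
}

.savage_dickey_result <- function(log_bf01, point) {
  structure(
    list(log_bf = log_bf01, orientation = "BF01",
         h0 = sprintf("delta = %.4g", point),
         h1 = sprintf("delta != %.4g (within the prior support)", point),
         design = list(design = "savage_dickey", point = point),
         prior = NULL, stat = NULL, summary = NULL, frequentist = NULL),
    class = "bftest"
  )
}

#' Export a density curve to CSV
#'
#' Writes the grid and densities as a CSV with columns `delta`,
#' `prior_density`, `posterior_density`. The densities at the null point
#' are appended as `#`-prefixed metadata comment lines at the top of the
#' file, so the Savage-Dickey ratio can be recomputed from the file
#' alone.
#'
#' @param curve A [posterior_curve()] result.
#' @param path Output file path.
#' @param point Null point for the metadata densities; defaults to the
#'   curve's null point.
#' @return `path`, invisibly.
#' @export
export_curves <- function(curve, path, point = NULL) {
  stopifnot(inherits(curve, "density_curve"))
  if (is.null(point)) point <- attr(curve, "null_point")
  stat <- attr(curve, "stat")
  prior <- attr(curve, "prior")
  pr_at <- prior_density(prior, point)
  po_at <- exp(likelihood_t(stat$t, stat$df, point, stat$n_eff,
                            log = TRUE) +
                 prior_density(prior, point, log = TRUE) -
                 attr(curve, "log_marginal"))
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop_invalid("cannot write to ", path))
  on.exit(close(con))
  tb <- attr(curve, "truncation_bound")
  writeLines(c(
    sprintf("# null_point: %.17g", point),
    sprintf("# prior_density_at_null: %.17g", pr_at),
    sprintf("# posterior_density_at_null: %.17g", po_at),
    sprintf("# truncation_bound: %s",
            if (is.na(tb)) "none" else sprintf("%.17g", tb))
  ), con)
  utils::write.table(as.data.frame(curve), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
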
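#' Brute-force (delta, sigma^2) integration oracle
#'
#' @description
#' Independent certification of the Bayes factor engine by direct
#' two-dimensional numerical integration of the raw-data normal
#' likelihood over the standardized effect size \eqn{\delta} and the
#' nuisance variance \eqn{\sigma^2} (on the \eqn{\log\sigma^2} scale,
#' where the Jeffreys prior \eqn{p(\sigma^2) \propto 1/\sigma^2} is the
#' flat measure). The grand mean carries a flat prior and is integrated
#' analytically; nothing else is shared with the engine, which instead
#' reduces to a one-dimensional noncentral-t integral. Both routes must
#' agree, which is the point of this module: it exists for desk-scale
#' certification in the test suite, not for performance.
#'
#' Because the nuisance priors are improper, individual log marginals
#' are defined only up to one common additive constant; differences
#' (log Bayes factors) are exact.
#'
#' `oracle_log_marginal()` integrates the likelihood against a point
#' hypothesis or a [cauchy_prior()]; `oracle_log_bf()` composes the
#' marginals per design (for interval nulls, posterior and prior masses
#' are computed by direct grid summation).
#'
#' @param summary A [study_summary()] in raw or means-and-SDs mode,
#'   already in canonical (high-favorable) orientation.
#' @param point Null value of \eqn{\delta} for a point hypothesis.
#' @param prior A [cauchy_prior()] for a composite hypothesis (exactly
#'   one of `point`/`prior` must be given).
#' @param design One of `"superiority"`, `"noninferiority"`,
#'   `"equivalence"`.
#' @param margin Standardized non-inferiority margin \eqn{c \ge 0}.
#' @param interval Standardized equivalence interval (length 2), or
#'   `c(0, 0)` for the point null.
#' @param prior_scale Cauchy prior scale.
#' @param resolution Grid-resolution multiplier; doubling it should not
#'   change a log Bayes factor by more than about `1e-4` (this
#'   self-convergence is asserted in the tests).
#'
#' @return `oracle_log_marginal()`: a log marginal likelihood (up to the
#'   improper-prior constant). `oracle_log_bf()`: a log Bayes factor in
#'   the engine's orientation for that design (`BF10` for superiority
#'   and non-inferiority, `BF01` for equivalence).
#' @name oracle
NULL

# sufficient statistics for the normal likelihood
.oracle_suff <- function(summary) {
  stopifnot(inherits(summary, "study_summary"))
  if (summary$mode == "means_ci") {
    stop_invalid("the oracle needs per-group SDs (raw or means_sds mode)")
  }
  n_x <- summary$n_x
  n_y <- summary$n_y
  list(
    n = n_x + n_y,
    q = n_x * n_y / (n_x + n_y),
    d = summary$mean_y - summary$mean_x,
    SS = (n_x - 1) * summary$sd_x^2 + (n_y - 1) * summary$sd_y^2
  )
}

# log likelihood of (delta, s = log sigma^2), grand mean integrated out
# under a flat prior:
#   -((n-1)/2) (log 2pi + s) - log(n)/2 - (SS + q (d - e^{s/2} delta)^2) / (2 e^s)
.oracle_ll <- function(suff, delta, s) {
  sigma <- exp(s / 2)
  outer(delta, seq_along(s), function(dd, j) {
    -((suff$n - 1) / 2) * (log(2 * pi) + s[j]) - log(suff$n) / 2 -
      (suff$SS + suff$q * (suff$d - sigma[j] * dd)^2) / (2 * exp(s[j]))
  })
}

.oracle_sgrid <- function(suff, resolution) {
  s_hat <- log((suff$SS + suff$q * suff$d^2) / suff$n)
  seq(s_hat - 14, s_hat + 16, length.out = round(761 * resolution))
}

# non-uniform delta grid: wide coverage of the Cauchy body, log-spaced
# coverage of its far tails (so grid-summed prior masses are accurate),
# dense refinement under the prior peak and under the likelihood ridge
# (conditional center d/sigma, width 1/sqrt(q) for every sigma), and the
# support boundary and hypothesis anchors included exactly
.oracle_dgrid <- function(suff, prior, resolution, anchors = numeric(0)) {
  r <- prior$scale
  w <- 1 / sqrt(suff$q)
  s_hat <- log((suff$SS + suff$q * suff$d^2) / suff$n)
  centers <- suff$d / exp(s_hat / 2) * exp(c(-1.25, 0, 1.25))
  lo_l <- min(centers) - 14 * w
  hi_l <- max(centers) + 14 * w
  n_like <- max(1001, min(6001, round((hi_l - lo_l) / (w / 50))))
  tail <- exp(seq(log(60), log(1e6), length.out = round(401 * resolution)))
  # at a support bound or interval anchor away from the likelihood
  # center the integrand falls on its Gaussian flank, with local decay
  # length w^2 / |focus - center|; resolve each such window finely
  d_hat <- suff$d / exp(s_hat / 2)
  focus <- c(anchors,
             prior$lower[is.finite(prior$lower)],
             prior$upper[is.finite(prior$upper)])
  focus_pieces <- lapply(focus, function(f) {
    lam <- w^2 / max(w, abs(f - d_hat))
    seq(f - 30 * lam, f + 30 * lam,
        length.out = 2L * round(900 * resolution) + 1L)
  })
  grid <- sort(unique(c(
    seq(-60, 60, length.out = 2L * round(600 * resolution) + 1L),
    seq(prior$center - 12 * r, prior$center + 12 * r,
        length.out = 2L * round(600 * resolution) + 1L),
    seq(lo_l, hi_l, length.out = round(n_like * resolution) + 1L),
    tail, -tail,
    0, prior$center, anchors, focus,
    unlist(focus_pieces)
  )))
  grid[grid >= prior$lower & grid <= prior$upper]
}

# trapezoid weights on a non-uniform grid
.trapz_weights <- function(x) {
  n <- length(x)
  wt <- numeric(n)
  dx <- diff(x)
  wt[1L] <- dx[1L] / 2
  wt[n] <- dx[n - 1L] / 2
  if (n > 2L) wt[2:(n - 1L)] <- (dx[-1L] + dx[-(n - 1L)]) / 2
  wt
}

.log_trapz <- function(x, logy) {
  wt <- .trapz_weights(x)
  M <- max(logy[is.finite(logy)])
  M + log(sum(exp(logy - M) * wt))
}

#' @rdname oracle
#' @export
oracle_log_marginal <- function(summary, point = NULL, prior = NULL,
                                resolution = 1) {
  suff <- .oracle_suff(summary)
  s <- .oracle_sgrid(suff, resolution)
  if (!is.null(point) && is.null(prior)) {
    ll <- .oracle_ll(suff, point, s)[1L, ]
    return(.log_trapz(s, ll))
  }
  if (is.null(prior) || !is.null(point)) {
    stop_invalid("give exactly one of 'point' or 'prior'")
  }
  delta <- .oracle_dgrid(suff, prior, resolution)
  ll <- .oracle_ll(suff, delta, s)
  lw <- ll + prior_density(prior, delta, log = TRUE)
  wd <- .trapz_weights(delta)
  ws <- .trapz_weights(s)
  M <- max(lw)
  M + log(sum(exp(lw - M) * outer(wd, ws)))
}

#' @rdname oracle
#' @export
oracle_log_bf <- function(summary,
                          design = c("superiority", "noninferiority",
                                     "equivalence"),
                          margin = 0, interval = NULL,
                          prior_scale = 1 / sqrt(2), resolution = 1) {
  design <- match.arg(design)
  if (design == "superiority") margin <- 0
  if (design %in% c("superiority", "noninferiority")) {
    if (margin < 0) stop_invalid("'margin' must be nonnegative")
    prior <- cauchy_prior(0, prior_scale, support = "greater_than",
                          bound = -margin)
    m1 <- oracle_log_marginal(summary, prior = prior,
                              resolution = resolution)
    m0 <- oracle_log_marginal(summary, point = -margin,
                              resolution = resolution)
    return(m1 - m0)                                   # log BF10
  }
  # equivalence
  if (is.null(interval)) interval <- c(0, 0)
  prior <- cauchy_prior(0, prior_scale)
  if (interval[1L] == 0 && interval[2L] == 0) {
    m0 <- oracle_log_marginal(summary, point = 0, resolution = resolution)
    m1 <- oracle_log_marginal(summary, prior = prior,
                              resolution = resolution)
    return(m0 - m1)                                   # log BF01
  }
  suff <- .oracle_suff(summary)
  s <- .oracle_sgrid(suff, resolution)
  delta <- .oracle_dgrid(suff, prior, resolution, anchors = interval)
  lw <- .oracle_ll(suff, delta, s) +
    prior_density(prior, delta, log = TRUE)
  ws <- .trapz_weights(s)
  M <- max(lw)
  row_int <- drop(exp(lw - M) %*% ws)   # sigma^2 integrated, per delta
  # the interval bounds are grid points (anchors); masses inside are
  # summed on the sub-grid so boundary half-cells land on the right side
  wd <- .trapz_weights(delta)
  inside <- delta >= interval[1L] & delta <= interval[2L]
  wd_in <- .trapz_weights(delta[inside])
  m_total <- sum(wd * row_int)
  m_in <- sum(wd_in * row_int[inside])
  m_out <- m_total - m_in
  pd <- exp(prior_density(prior, delta, log = TRUE))
  p_in <- sum(wd_in * pd[inside])
  p_out <- sum(wd * pd) - p_in
  (log(m_in) - log(m_out)) - (log(p_in) - log(p_out)) # log BF01
}
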
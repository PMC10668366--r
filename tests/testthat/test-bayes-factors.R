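test_that("orientation conversion is an exact sign flip of the log BF", {
  s <- summary_from_t(2.2, 50)
  for (fit in list(bf_superiority(summary = s),
                   bf_noninferiority(summary = s, ni_margin = 0.5),
                   bf_equivalence(summary = s, interval = 0.3),
                   bf_equivalence(summary = s))) {
    expect_identical(log_bf10(fit) + log_bf01(fit), 0)
    expect_equal(bf10(fit) * bf01(fit), 1, tolerance = 1e-12)
  }
})

test_that("superiority evidence is strictly increasing in t", {
  ts <- c(-4, -1, 0, 0.5, 1.5, 3, 6)
  lbs <- vapply(ts, function(t) {
    log_bf10(bf_superiority(summary = summary_from_t(t, 40)))
  }, numeric(1))
  expect_true(all(diff(lbs) > 0))
})

test_that("flipping direction together with the data leaves BFs unchanged", {
  set.seed(51)
  for (i in 1:4) {
    n1 <- sample(5:40, 1)
    n2 <- sample(5:40, 1)
    m <- runif(1, -2, 2)
    s_hi <- study_summary(n_x = n1, n_y = n2, mean_x = 0, mean_y = m,
                          sd_x = 1.1, sd_y = 0.9)
    s_lo <- study_summary(n_x = n1, n_y = n2, mean_x = 0, mean_y = -m,
                          sd_x = 1.1, sd_y = 0.9)
    a <- bf_superiority(summary = s_hi, direction = "high")
    b <- bf_superiority(summary = s_lo, direction = "low")
    expect_identical(a$log_bf, b$log_bf)
    a <- bf_noninferiority(summary = s_hi, ni_margin = 0.7,
                           direction = "high")
    b <- bf_noninferiority(summary = s_lo, ni_margin = 0.7,
                           direction = "low")
    expect_identical(a$log_bf, b$log_bf)
  }
})

test_that("a zero margin reduces non-inferiority to superiority", {
  for (t in c(-1, 0.3, 2.5)) {
    s <- summary_from_t(t, 30)
    expect_equal(log_bf10(bf_noninferiority(summary = s, ni_margin = 0)),
                 log_bf10(bf_superiority(summary = s)),
                 tolerance = 1e-10)
  }
})

test_that("averaging the two one-sided BFs gives the two-sided BF", {
  # the symmetric center-0 Cauchy splits into two equal-mass halves, so
  # (BF10 for delta>0 + BF10 for delta<0)/2 equals the two-sided BF10,
  # whose reciprocal is the point-null equivalence BF01
  for (t in c(-2, 0.8, 4)) {
    s <- summary_from_t(t, 80)
    up <- bf10(bf_superiority(summary = s, direction = "high"))
    # direction = "low" negates the data internally, so this is the BF
    # for the delta < 0 side of the original data
    dn <- bf10(bf_superiority(summary = s, direction = "low"))
    two_sided <- 1 / bf01(bf_equivalence(summary = s))
    expect_equal((up + dn) / 2, two_sided,
                 tolerance = 1e-6 * abs(two_sided))
  }
})

test_that("shrinking interval nulls converge to the Savage-Dickey value", {
  s <- summary_from_t(0.5, 198)
  point <- log_bf01(bf_equivalence(summary = s, interval = 0))
  gaps <- vapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    abs(log_bf01(bf_equivalence(summary = s, interval = eps)) - point)
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-3)
})

test_that("Savage-Dickey density ratio agrees with the marginal route", {
  for (t in c(-1.4, 0.6, 2.8)) {
    fit <- bf_equivalence(summary = summary_from_t(t, 100))
    sd_direct <- savage_dickey(fit, point = 0)
    expect_equal(sd_direct$log_bf, log_bf01(fit), tolerance = 1e-6)
    # interpolation route on an exported fine grid
    cv <- posterior_curve(fit, n = 4097)
    bare <- as.data.frame(cv)
    sd_interp <- savage_dickey(bare, point = 0)
    expect_equal(sd_interp$log_bf, log_bf01(fit), tolerance = 1e-4)
  }
})

test_that("a curve with posterior equal to prior gives BF01 = 1", {
  grid <- seq(-4, 4, length.out = 801)
  dens <- dcauchy(grid, 0, 1 / sqrt(2))
  curve <- data.frame(delta = grid, prior_density = dens,
                      posterior_density = dens)
  expect_equal(savage_dickey(curve, point = 0)$log_bf, 0, tolerance = 1e-12)
  expect_error(savage_dickey(curve, point = 10),
               class = "bfdesign_invalid_input")
})

test_that("posterior curves are normalized with mode near the data", {
  st <- t_statistic(study_summary(n_x = 1000, n_y = 1000, mean_x = 0,
                                  mean_y = 0.3, sd_x = 1, sd_y = 1))
  expect_equal(st$n_eff, 500)
  cv <- posterior_curve(st, prior = cauchy_prior(), n = 4001)
  expect_equal(bfdesign:::.trapz(cv$delta, cv$posterior_density), 1,
               tolerance = 1e-3)
  expect_equal(bfdesign:::.trapz(cv$delta, cv$prior_density), 1,
               tolerance = 5e-3)
  mode_at <- cv$delta[which.max(cv$posterior_density)]
  expect_lt(abs(mode_at - st$d_obs), 0.05)
})

test_that("truncated posterior curves renormalize over the support", {
  fit <- bf_noninferiority(summary = summary_from_t(1, 60), ni_margin = 0.8)
  cv <- posterior_curve(fit, n = 4001)
  expect_equal(attr(cv, "truncation_bound"), -0.8)
  expect_true(all(cv$delta >= -0.8))
  expect_equal(bfdesign:::.trapz(cv$delta, cv$posterior_density), 1,
               tolerance = 1e-3)
})

test_that("posterior interval masses behave like probabilities", {
  fit <- bf_equivalence(summary = summary_from_t(1.2, 90), interval = 0.25)
  cv <- posterior_curve(fit, n = 4001)
  m_in <- interval_mass(cv, -0.25, 0.25)
  m_out <- interval_mass(cv, -Inf, -0.25) + interval_mass(cv, 0.25, Inf)
  expect_gt(m_in, 0)
  expect_lt(m_in, 1)
  expect_equal(m_in + m_out, 1, tolerance = 5e-3)
  # quadrature route on the fitted model agrees with the curve trapezoid
  expect_equal(interval_mass(fit, -0.25, 0.25), m_in, tolerance = 1e-3)
  expect_equal(interval_mass(fit, -Inf, Inf), 1, tolerance = 1e-8)
  # regions outside a truncated support carry no mass
  ni <- bf_noninferiority(summary = summary_from_t(1, 60), ni_margin = 0.8)
  expect_identical(interval_mass(ni, -5, -0.8), 0)
})

test_that("odds updating and reciprocals follow the definition", {
  expect_identical(update_odds(2, 24), 48)
  fit <- bf_equivalence(summary = summary_from_t(0.4, 50))
  expect_equal(update_odds(1, fit), bf01(fit))
  expect_error(update_odds(-1, 3), class = "bfdesign_invalid_input")
})
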
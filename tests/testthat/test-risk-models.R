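test_that("linear relative risk reproduces the published point and CI values", {
  r <- relative_risk(10.45)
  expect_equal(round(r$rr, 2), 7.27)
  r0 <- relative_risk(0)
  expect_equal(c(r0$rr, r0$rr_lower, r0$rr_upper), c(1, 1, 1))
  expect_equal(round(relative_risk(12.28)$rr_upper, 2), 31.70)
  expect_error(relative_risk(-1), "non-negative")
  # RR >= 1 and monotone in dose
  rr <- relative_risk(seq(0, 50, by = 5))$rr
  expect_true(all(rr >= 1))
  expect_true(all(diff(rr) > 0))
})

test_that("Poisson response has D50 at half-probability and correct limits", {
  p <- hodgkin_params()
  expect_equal(poisson_response(70.3, p), 0.5)
  # scalar hand evaluation at zero dose
  expect_equal(poisson_response(0, p), 2^(-exp(exp(1) * 0.96)))
  expect_lt(poisson_response(0, rs_params(70.3, 2, 1)), 1e-6)
  expect_gt(poisson_response(1e4, p), 1 - 1e-12)
  d <- seq(0, 150, by = 2)
  expect_true(all(diff(poisson_response(d, p)) > 0))
})

test_that("relative-seriality NTCP collapses to P(D) under uniform irradiation", {
  for (s in c(0.1, 0.5, 0.87, 1)) {
    pars <- rs_params(70.3, 0.96, s)
    u <- uniform_dvh(70.3)
    expect_equal(ntcp_relative_seriality(u, pars), 0.5, tolerance = 1e-12)
    u2 <- uniform_dvh(40)
    expect_equal(ntcp_relative_seriality(u2, pars),
                 poisson_response(40, pars), tolerance = 1e-12)
  }
})

test_that("relative-seriality NTCP matches direct two-bin evaluation", {
  pars <- hodgkin_params()
  d <- dvh_differential(c(35.15, 70.3), c(0.5, 0.5), bin_width = 35.15)
  # direct scalar evaluation of the product form (independent arithmetic)
  p1 <- 2^(-exp(exp(1) * 0.96 * (1 - 35.15 / 70.3)))
  p2 <- 2^(-exp(exp(1) * 0.96 * (1 - 70.3 / 70.3)))
  direct <- (1 - (1 - p1)^0.5 * (1 - p2)^0.5)
  expect_equal(ntcp_relative_seriality(d, pars), direct, tolerance = 1e-12)
})

test_that("log-space relative-seriality evaluation agrees with the naive product", {
  d <- random_dvh(30, bin_width = 2)
  for (s in c(0.3, 0.7, 1)) {
    pars <- rs_params(40, 1.1, s)
    p <- poisson_response(d$dose, pars)
    naive <- (1 - prod((1 - p^s)^d$volume))^(1 / s)
    expect_equal(ntcp_relative_seriality(d, pars), naive, tolerance = 1e-12)
  }
})

test_that("serial organs are dominated by hot subvolumes", {
  # small hot subvolume: a serial organ (s = 1) must respond more strongly
  # than a near-parallel one (s = 0.1)
  hot <- dvh_differential(c(2, 80), c(0.95, 0.05), bin_width = 78)
  n1 <- ntcp_relative_seriality(hot, rs_params(60, 1.5, 1))
  n0 <- ntcp_relative_seriality(hot, rs_params(60, 1.5, 0.1))
  expect_gte(n1, n0)
})

test_that("Lyman partial-volume tolerance dose follows the power law", {
  expect_equal(td50_partial(48, 1, 0.35), 48)
  expect_equal(td50_partial(48, 0.5, 0.35), 48 / 0.5^0.35)
  expect_equal(td50_partial(50.6, 1, 0.64), 50.6)
  expect_error(td50_partial(48, 0, 0.35), "\\(0, 1\\]")
})

test_that("Lyman NTCP is the normal CDF of the standardized dose", {
  pars <- lyman_params(48, 0.35, 0.1)
  expect_equal(ntcp_lyman_uniform(48, 1, pars), 0.5)
  expect_equal(ntcp_lyman_uniform(td50_partial(48, 0.4, 0.35), 0.4, pars), 0.5)
  # independent CDF oracle via the error function
  skip_if_not_installed("pracma")
  t <- (60 - 48) / (0.1 * 48)  # 2.5
  expect_equal(ntcp_lyman_uniform(60, 1, pars),
               (1 + pracma::erf(t / sqrt(2))) / 2, tolerance = 1e-12)
  expect_lt(ntcp_lyman_uniform(0, 1, lyman_params(48, 0.35, 0.2)), 1e-6)
})

test_that("Lyman DVH reduction matches partial-volume and brute-force oracles", {
  pars <- lyman_params(48, 0.35, 0.15)
  # uniform DVH reduces to the full-volume formula
  expect_equal(ntcp_lyman_dvh(uniform_dvh(30), pars),
               ntcp_lyman_uniform(30, 1, pars))
  # two-level DVH with one irradiated level equals the partial-volume formula
  two <- dvh_differential(c(0, 40), c(0.5, 0.5), bin_width = 40)
  expect_equal(ntcp_lyman_dvh(two, pars), ntcp_lyman_uniform(40, 0.5, pars))
  # brute-force re-implementation of the effective-volume reduction
  d <- random_dvh(20, bin_width = 2.5)
  dmax <- max(d$dose)
  veff <- 0
  for (i in seq_along(d$dose))
    veff <- veff + d$volume[i] * (d$dose[i] / dmax)^(1 / pars$n_vol)
  expect_equal(ntcp_lyman_dvh(d, pars),
               stats::pnorm((dmax - 48 / veff^0.35) / (0.15 * 48 / veff^0.35)),
               tolerance = 1e-12)
  # gEUD alternative agrees for uniform irradiation
  expect_equal(ntcp_lyman_dvh(uniform_dvh(30), pars, reduction = "geud"),
               ntcp_lyman_uniform(30, 1, pars))
})

test_that("both NTCP models are monotone under dose scaling and bounded in [0, 1]", {
  d <- random_dvh(25, bin_width = 2)
  rs <- rs_params(55, 1.1, 0.8)
  ly <- lyman_params(50, 0.5, 0.2)
  ks <- c(0.5, 0.8, 1, 1.3, 2)
  vals_rs <- vals_ly <- numeric(length(ks))
  for (i in seq_along(ks)) {
    scaled <- dvh_differential(d$dose * ks[i], d$volume,
                               bin_width = d$bin_width * ks[i])
    vals_rs[i] <- ntcp_relative_seriality(scaled, rs)
    vals_ly[i] <- ntcp_lyman_dvh(scaled, ly)
  }
  expect_true(all(diff(vals_rs) > 0))
  expect_true(all(diff(vals_ly) > 0))
  expect_true(all(vals_rs >= 0 & vals_rs <= 1))
  expect_true(all(vals_ly >= 0 & vals_ly <= 1))
})

test_that("least-squares fitting recovers the generating dose-response parameters", {
  true <- hodgkin_params()
  d <- seq(5, 120, by = 5)
  y <- poisson_response(d, true)
  fit <- optim(c(60, 1.2), function(p) {
    if (p[1] <= 0 || p[2] <= 0) return(1e6)
    sum((poisson_response(d, rs_params(p[1], p[2], 1)) - y)^2)
  }, method = "BFGS", control = list(reltol = 1e-16, maxit = 2000))
  expect_equal(fit$par[1], 70.3, tolerance = 1e-6)
  expect_equal(fit$par[2], 0.96, tolerance = 1e-6)
})
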
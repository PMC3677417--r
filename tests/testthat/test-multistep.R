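test_that("subterminal GDP probability has the two stated forms", {
  expect_equal(subterminal_gdp_prob(0.12, 2.9538), 0.03904, tolerance = 1e-4)
  expect_equal(subterminal_gdp_prob(0, 5), 0)
  expect_equal(subterminal_gdp_prob(0.12, 2.9538, "small_h"), 0.040625,
               tolerance = 1e-4)
  expect_error(subterminal_gdp_prob(0.12, 0, "small_h"), "r_pf > 0")
  expect_error(subterminal_gdp_prob(0, 0), "both be zero")
})

test_that("step time is the inverse step rate", {
  expect_equal(step_time(0.015385, 0.03904), 1665, tolerance = 1e-3)
  expect_equal(step_time(0.25, 1), 4)
  expect_equal(step_time(0.02, 1), 50)  # zeroth-order dilution step time
  expect_identical(step_time(0.02, 0), Inf)   # no catastrophe
  expect_identical(step_time(0, 0.5), Inf)
})

test_that("lifetime pdf matches the order-statistic closed form", {
  Tp <- 123.4
  msp <- multistep_params(3, 13, Tp)
  # multistep model: zero density at t = 0 (the aging signature)
  expect_equal(lifetime_pdf(0, msp), 0)
  # combinatorial factor 858 for 3-of-13
  expect_equal(lifetime_pdf(0.1 * Tp, msp), 2.5864 / Tp, tolerance = 1e-4)
  # exponential reduction at n = N = 1
  m1 <- multistep_params(1, 1, Tp)
  expect_equal(lifetime_pdf(Tp, m1), exp(-1) / Tp)
  expect_equal(lifetime_pdf(0, m1), 1 / Tp)
  expect_error(lifetime_pdf(-1, msp), ">= 0")
})

test_that("pdf integrates to one and cdf is its integral, across (n, N)", {
  for (N in c(1L, 2L, 5L, 13L)) for (n in seq_len(N)) {
    msp <- multistep_params(n, N, 37.5)
    expect_equal(stats::integrate(lifetime_pdf, 0, Inf, msp = msp,
                                  rel.tol = 1e-10)$value, 1,
                 tolerance = 1e-8)
    t0 <- 25
    expect_equal(stats::integrate(lifetime_pdf, 0, t0, msp = msp,
                                  rel.tol = 1e-10)$value,
                 lifetime_cdf(t0, msp), tolerance = 1e-8)
  }
})

test_that("only n = 1 gives an exponential (memoryless) lifetime law", {
  Tp <- 100
  m1 <- multistep_params(1, 13, Tp)
  ts <- c(1, 5, 20, 80)
  expect_equal(lifetime_cdf(ts, m1), pexp(ts, rate = 13 / Tp))
  for (n in 2:4) {
    expect_equal(lifetime_pdf(0, multistep_params(n, 13, Tp)), 0)
    expect_gt(lifetime_pdf(0.5 * Tp, multistep_params(n, 13, Tp)), 0)
  }
})

test_that("mean lifetime equals the harmonic-sum closed form", {
  expect_equal(mean_lifetime(multistep_params(3, 13, 1580)), 396.8,
               tolerance = 1e-3)
  expect_equal(mean_lifetime(multistep_params(1, 1, 777)), 777)
  # quadrature oracle to 6 digits, over several (n, N)
  for (nn in list(c(1, 1), c(3, 13), c(2, 5), c(13, 13))) {
    msp <- multistep_params(nn[1], nn[2], 412)
    expect_equal(mean_lifetime(msp), quad_mean(nn[1], nn[2], 412),
                 tolerance = 1e-6)
  }
})

test_that("mean lifetime vs concentration reproduces the fitted curve", {
  p <- fig5d()
  expect_equal(mean_lifetime_vs_concentration(p, 12, approx = TRUE), 401.9,
               tolerance = 1e-3)
  expect_equal(mean_lifetime_vs_concentration(p, 12, approx = FALSE), 418.2,
               tolerance = 1e-3)
  # monotone: increasing in c, decreasing in h and k_T
  cs <- c(6, 8, 10, 12, 14)
  expect_true(all(diff(mean_lifetime_vs_concentration(p, cs)) > 0))
  hs <- c(0.05, 0.12, 0.2, 0.3)
  Th <- vapply(hs, function(h)
    mean_lifetime_vs_concentration(rate_params(3.2, 0.2, h = h), 12),
    numeric(1))
  expect_true(all(diff(Th) < 0))
  ks <- c(0.1, 0.2, 0.4)
  Tk <- vapply(ks, function(k)
    mean_lifetime_vs_concentration(rate_params(3.2, k, h = 0.12), 12),
    numeric(1))
  expect_true(all(diff(Tk) < 0))
  expect_error(mean_lifetime_vs_concentration(p, 0), "> 0")
})

test_that("hydrolysis-rate inversion solves the mean-lifetime relation", {
  h <- solve_hydrolysis_rate(232, r_pf = 3.75, k_pf = 0.02)
  expect_equal(h, 0.2146, tolerance = 1e-3)
  # inverse identity to 8 digits
  for (h0 in c(0.05, 0.12, 0.26, 1.5)) {
    Tm <- 0.2511655 * (h0 + 3.75) / (0.02 * h0)
    expect_equal(solve_hydrolysis_rate(Tm, 3.75, 0.02), h0, tolerance = 1e-8)
  }
  # below the h -> Inf infimum H/k_pf = 12.56 s there is no solution
  expect_error(solve_hydrolysis_rate(5, 3.75, 0.02), "12.5")
})

test_that("inversion is the identity on the analytic concentration curve", {
  p <- fig5d()
  for (conc in c(8, 12, 16)) {
    Tm <- mean_lifetime_vs_concentration(p, conc)
    dr <- derive_rates(p, conc)
    expect_equal(solve_hydrolysis_rate(Tm, dr$r_pf, dr$k_pf), p$h,
                 tolerance = 1e-8)
  }
})

test_that("pre-dilution state distribution is dwell-time weighted", {
  P <- dilution_state_distribution(3, 13)
  expect_equal(unname(P), c(0.3063, 0.3318, 0.3619), tolerance = 1e-3)
  expect_equal(sum(P), 1)
  expect_equal(unname(dilution_state_distribution(1, 13)), 1)
  for (n in 1:5) expect_equal(sum(dilution_state_distribution(n, 13)), 1)
})

test_that("post-dilution mean time averages the remaining waits", {
  p <- rate_params(3.2, k_T = 0.26, h = 0.12)  # k_pf = 0.02 s^-1
  expect_equal(dilution_mean_time(p, c_post = 0), 8.382, tolerance = 1e-3)
  # conditioning on two accrued steps leaves a single 1/(11 s) wait
  expect_equal(dilution_mean_time(p, 0, from_state = 2), 1 / (11 * 0.02),
               tolerance = 1e-10)
  # halving k_pf doubles the mean exactly
  p2 <- rate_params(3.2, k_T = 0.13, h = 0.12)
  expect_equal(dilution_mean_time(p2, 0), 2 * dilution_mean_time(p, 0))
  # finite post-dilution concentration slows the steps
  expect_gt(dilution_mean_time(p, 2), dilution_mean_time(p, 0))
})
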
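test_that("log-likelihood reduces to the exponential log-density at n = N = 1", {
  d <- lifetime_sample(57.3)
  msp <- multistep_params(1, 1, 200)
  expect_equal(lifetime_loglik(d, msp), -log(200) - 57.3 / 200)
})

test_that("log-likelihood is the sum of elementwise log terms", {
  set.seed(8)
  msp <- multistep_params(3, 13, 800)
  d <- sample_lifetimes(msp, 50, censor_time = 500, seed = 8)
  manual <- sum(log(lifetime_pdf(d$lifetime_s[!d$censored], msp))) +
    sum(log(1 - lifetime_cdf(d$lifetime_s[d$censored], msp)))
  expect_equal(lifetime_loglik(d, msp), manual)
  expect_error(lifetime_loglik(d[0, ], msp), "empty")
})

test_that("the likelihood peaks near the generating step time", {
  d <- sample_lifetimes(multistep_params(3, 13, 1580), 5000, seed = 21)
  expect_gt(lifetime_loglik(d, multistep_params(3, 13, 1580)),
            lifetime_loglik(d, multistep_params(3, 13, 3000)))
})

test_that("the MLE recovers n and T' from synthetic lifetimes", {
  d <- sample_lifetimes(multistep_params(3, 13, 1580), 2000, seed = 31)
  f <- fit_mle(d)
  expect_equal(f$n_hat, 3L)
  expect_lt(abs(f$T_step_hat / 1580 - 1), 0.05)
  expect_equal(nrow(f$profile), 3L)
  expect_true(all(f$profile$loglik <= f$log_likelihood))
})

test_that("with n = 1 the step-time MLE is the sample mean", {
  d <- sample_lifetimes(multistep_params(1, 1, 100), 500, seed = 2)
  f <- fit_mle(d, n_candidates = 1, N = 1)
  expect_equal(f$T_step_hat, mean(d$lifetime_s), tolerance = 1e-6)
})

test_that("model selection identifies the generating n", {
  sel <- vapply(1:100, function(i) {
    d <- sample_lifetimes(multistep_params(2, 13, 1000), 2000,
                          seed = 1000 + i)
    fit_mle(d)$n_hat
  }, integer(1))
  expect_gte(mean(sel == 2L), 0.95)
})

test_that("estimator bias shrinks with sample size", {
  bias_at <- function(size, nrep) {
    mean(vapply(seq_len(nrep), function(i) {
      d <- sample_lifetimes(multistep_params(3, 13, 1580), size,
                            seed = 500 + i)
      fit_mle(d, n_candidates = 3)$T_step_hat
    }, numeric(1))) / 1580 - 1
  }
  b3 <- bias_at(1e3, 20)
  b4 <- bias_at(1e4, 20)
  expect_lt(abs(b4), 0.01)
  expect_lt(abs(b4), abs(b3) + 0.01)
})

test_that("fits are scale-equivariant", {
  d <- sample_lifetimes(multistep_params(3, 13, 900), 1000, seed = 77)
  f1 <- fit_mle(d)
  d2 <- d
  d2$lifetime_s <- d2$lifetime_s * 3.7
  f2 <- fit_mle(d2)
  expect_identical(f2$n_hat, f1$n_hat)
  expect_equal(f2$T_step_hat, 3.7 * f1$T_step_hat, tolerance = 1e-6)
})

test_that("heavy right-censoring below the median still recovers T'", {
  msp <- multistep_params(3, 13, 1580)   # median lifetime ~353 s
  d <- sample_lifetimes(msp, 3000, censor_time = 300, seed = 1)
  expect_gt(mean(d$censored), 0.5)
  f <- fit_mle(d)
  boot <- parametric_bootstrap_se(f, reps = 100, seed = 2,
                                  n_candidates = f$n_hat, censor_time = 300)
  expect_lt(abs(f$T_step_hat - 1580), 3 * boot$T_step_se)
})

test_that("fit preconditions are enforced", {
  d <- sample_lifetimes(multistep_params(3, 13, 100), 5, seed = 1)
  expect_error(fit_mle(d), "at least 10")
  dc <- sample_lifetimes(multistep_params(3, 13, 1000), 20,
                         censor_time = 1e-3, seed = 1)
  expect_error(fit_mle(dc), "censored")
  expect_error(fit_mle(sample_lifetimes(multistep_params(3, 13, 100), 50,
                                        seed = 1), n_candidates = 20),
               "1..N")
})

test_that("bootstrap SE scales as one over the square root of the sample size", {
  d <- sample_lifetimes(multistep_params(3, 13, 1580), 2000, seed = 41)
  f <- fit_mle(d, n_candidates = 3)
  se <- vapply(c(500, 2000, 8000), function(sz)
    parametric_bootstrap_se(f, data_size = sz, reps = 100, seed = 5,
                            n_candidates = 3)$T_step_se, numeric(1))
  expect_lt(abs(se[1] / se[2] / 2 - 1), 0.25)
  expect_lt(abs(se[2] / se[3] / 2 - 1), 0.25)
  # at n = 5000 the relative SE is small
  se5k <- parametric_bootstrap_se(f, data_size = 5000, reps = 100, seed = 6,
                                  n_candidates = 3)$T_step_se
  expect_lt(se5k / f$T_step_hat, 0.04)
  # reproducible under a fixed seed
  again <- parametric_bootstrap_se(f, data_size = 5000, reps = 100, seed = 6,
                                   n_candidates = 3)$T_step_se
  expect_identical(se5k, again)
  expect_error(parametric_bootstrap_se(f, reps = 50), ">= 100")
})
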
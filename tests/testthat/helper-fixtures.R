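# Shared fixtures: the fitted-model parameter set and a tiny independent
# oracle for order-statistic means by numerical quadrature.

fig5d <- function() preset_params("fig5d")

# independent quadrature mean of the n-of-N order-statistic lifetime law
quad_mean <- function(n, N, T_step) {
  f <- function(t) {
    p <- 1 - exp(-t / T_step)
    t * exp(lgamma(N + 1) - lgamma(n) - lgamma(N - n + 1)) *
      p^(n - 1) * (1 - p)^(N - n) * exp(-t / T_step) / T_step
  }
  stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
}

# observed (uncensored) mean of a lifetime sample
obs_mean <- function(s) mean(s$lifetime_s[!s$censored])
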
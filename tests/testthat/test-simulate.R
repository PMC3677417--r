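test_that("a fixed seed reproduces a trajectory bit-identically", {
  p <- fig5d()
  a <- simulate_protofilament(p, 10, "coupled_random", "none", t_max = 50,
                              seed = 42)
  b <- simulate_protofilament(p, 10, "coupled_random", "none", t_max = 50,
                              seed = 42)
  expect_identical(a$times, b$times)
  expect_identical(a$lengths, b$lengths)
  expect_identical(a$final_state, b$final_state)
  c <- simulate_protofilament(p, 10, "coupled_random", "none", t_max = 50,
                              seed = 43)
  expect_false(identical(a$times, c$times))
})

test_that("trajectories satisfy the structural invariants", {
  p <- fig5d()
  tr <- simulate_protofilament(p, 10, "coupled_random", "none", t_max = 100,
                               seed = 7)
  expect_true(all(diff(tr$times) > 0))          # no cascades with finite k_D
  expect_true(all(tr$lengths >= 0))
  # addition/dissociation move the tip by one subunit; hydrolysis does not
  dl <- diff(tr$lengths)
  hyd <- tr$events[-1] == "hydrolysis"
  expect_true(all(abs(dl[!hyd]) == 1))
  expect_true(all(dl[hyd] == 0))
  expect_true(tr$status %in% c("catastrophe", "censored_time", "censored_length"))
})

test_that("coupled-mechanism lifetimes are exponential(k_T) and concentration-independent", {
  p <- preset_params("table1-gtp")  # k_T = 0.1
  s1 <- simulate_lifetime_ensemble(p, 10, "coupled", "terminal_gdp", 2000,
                                   seed = 1)
  expect_true(all(!s1$censored))
  ks <- stats::ks.test(s1$lifetime_s, "pexp", rate = p$k_T)
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(s1$lifetime_s) - 10), 3 * stats::sd(s1$lifetime_s) / sqrt(2000))
  # a different concentration: statistically indistinguishable means
  s2 <- simulate_lifetime_ensemble(p, 20, "coupled", "terminal_gdp", 2000,
                                   seed = 2)
  expect_gt(stats::t.test(s1$lifetime_s, s2$lifetime_s)$p.value, 0.01)
})

test_that("with hydrolysis off, filament length drifts at r - k_T", {
  p <- rate_params(3.2, 0.1, h = 0)
  t_end <- 100
  tr <- simulate_protofilament(p, 10, "random", "none", t_max = t_end,
                               seed = 4, length_max = 1e6, record = FALSE)
  drift <- (3.2 * 10 - 0.1) * t_end
  # birth-death chain: sd of the endpoint is sqrt((r + k) t)
  expect_lt(abs(tr$length_end - drift), 4 * sqrt((32 + 0.1) * t_end))
})

test_that("random hydrolysis with h = 0 never creates GDP", {
  p <- rate_params(3.2, 0.1, h = 0)
  s <- simulate_lifetime_ensemble(p, 5, "random", "terminal_gdp", 30, seed = 3,
                                  t_max = 50, length_max = 1e4)
  expect_true(all(s$censored))
})

test_that("vectorial boundedness criterion is h > r - k, strictly", {
  expect_true(vectorial_bounded(42.1, 0.1, 43.5))
  expect_false(vectorial_bounded(42.1, 0.1, 40))
  expect_false(vectorial_bounded(42.1, 0.1, 42))  # boundary: not bounded
  expect_error(vectorial_bounded(-1, 0.1, 2), ">= 0")
})

test_that("vectorial filaments catastrophe iff the front can catch the tip", {
  # h = 43.5 > r - k = 42.14 at 13.2 uM: every filament loses its cap
  pv <- preset_params("fig5a-vectorial")
  sb <- simulate_lifetime_ensemble(pv, 13.2, "vectorial", "cap_loss", 50,
                                   seed = 1, t_max = 3000, length_max = 2e4)
  expect_true(all(!sb$censored))
  # h = 10 well below r - k: most filaments outrun the front and hit the
  # length cap (the minority that die young lose the nascent cap by chance)
  pu <- rate_params(3.2, 0.1, h = 10)
  su <- simulate_lifetime_ensemble(pu, 13.2, "vectorial", "cap_loss", 50,
                                   seed = 2, t_max = 3000, length_max = 2e4)
  expect_gt(mean(su$censored), 0.5)
})

test_that("coupled-random keeps a GTP terminal whenever time advances", {
  # with instantaneous GDP-terminal removal, any transient GDP tip is
  # stripped in zero time: the last record at each event time is GTP/empty
  p <- rate_params(3.2, 0.2, h = 0.5, k_D_infinite = TRUE)
  tr <- simulate_protofilament(p, 2, "coupled_random", "none", t_max = 300,
                               seed = 5)
  last_at_time <- !duplicated(tr$times, fromLast = TRUE)
  expect_true(all(tr$tip_gtp[last_at_time] != 0))
})

test_that("mechanism/rule mismatches and bad caps are rejected", {
  p <- fig5d()
  expect_error(simulate_protofilament(p, 10, "coupled", "cap_loss"), "cap_loss")
  expect_error(simulate_protofilament(p, 10, "random", "terminal_gdp",
                                      t_max = 0), "t_max")
  expect_error(simulate_protofilament(p, 10, "random", "n_terminal_gdp",
                                      rule_N = 0), "rule_N")
  expect_error(simulate_multipf_lifetimes(p, 12, n_steps = 14,
                                          n_replicates = 2, seed = 1),
               "between 1 and")
  expect_error(simulate_protofilament(preset_params("table1-gtp"), 10,
                                      "random", "terminal_gdp"), "unset")
})

test_that("mechanistic multi-protofilament lifetimes match the analytic model", {
  p <- fig5d()
  s <- simulate_multipf_lifetimes(p, 12, n_replicates = 500, seed = 9)
  expect_lt(mean(s$censored), 0.01)
  m <- obs_mean(s)
  expect_lt(abs(m / mean_lifetime_vs_concentration(p, 12) - 1), 0.1)
})

test_that("one protofilament, one step reduces to a single-step process", {
  # n_pf = 1: step rate k_pf * p_D, with a small O(k'/r') lattice correction
  p1 <- rate_params(3.2, 0.1, h = 0.3, n_pf = 1)
  s <- simulate_multipf_lifetimes(p1, 1, n_steps = 1, n_replicates = 400,
                                  seed = 11, t_max = 2000)
  pd <- subterminal_gdp_prob(0.3, 3.2)
  expect_lt(abs(obs_mean(s) - 1 / (0.1 * pd)),
            3 * stats::sd(s$lifetime_s) / sqrt(sum(!s$censored)) +
              0.1 * 1 / (0.1 * pd))
})

test_that("mechanistic dilution to zero tubulin matches the analytic mean up to the hydrolysis lag", {
  # the zeroth-order analytic result treats subterminal hydrolysis as
  # instantaneous; the lattice adds a lag of order 1/h to the early steps
  p <- rate_params(3.2, k_T = 0.26, h = 0.12)  # k_pf = 0.02 s^-1
  s <- simulate_multipf_dilution(p, c_pre = 10, c_post = 0,
                                 n_replicates = 400, seed = 12)
  expect_true(all(!s$censored))
  analytic <- dilution_mean_time(p, 0)
  expect_lt(abs(obs_mean(s) - analytic), 1 / p$h)
  # still "within several seconds", the experimental signature
  expect_lt(obs_mean(s), 20)
  expect_error(simulate_multipf_dilution(p, 1, 5, n_replicates = 2, seed = 1),
               "below")
})

test_that("ensemble seeds are reproducible and order-independent", {
  p <- fig5d()
  a <- simulate_multipf_lifetimes(p, 12, n_replicates = 20, seed = 5,
                                  t_max = 2000)
  b <- simulate_multipf_lifetimes(p, 12, n_replicates = 20, seed = 5,
                                  t_max = 2000)
  expect_identical(a$lifetime_s, b$lifetime_s)
})
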
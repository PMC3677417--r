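#' Parameters of the multistep catastrophe model
#'
#' The analytic multi-protofilament model treats catastrophe as the `n`-th of
#' `N` protofilament destabilization events. Each of the `N` independent
#' protofilaments destabilizes after an exponential step time with mean
#' `T_step`; the microtubule lifetime is then the `n`-th order statistic of
#' `N` iid exponentials.
#'
#' @param n number of destabilizing events to catastrophe (default 3).
#' @param N protofilament count (default 13).
#' @param T_step mean step time per protofilament, T' (s), strictly positive.
#' @return Object of class `multistep_params`.
#' @examples
#' msp <- multistep_params(n = 3, N = 13, T_step = 1580)
#' mean_lifetime(msp)
#' @export
multistep_params <- function(n = 3L, N = 13L, T_step) {
  n <- as.integer(n); N <- as.integer(N)
  stopifnot(length(n) == 1L, length(N) == 1L,
            is.numeric(T_step), length(T_step) == 1L)
  if (is.na(n) || is.na(N) || n < 1L || n > N)
    stop("need 1 <= n <= N (catastrophe is the n-th of N destabilizations)")
  if (is.na(T_step) || T_step <= 0) stop("'T_step' must be > 0")
  structure(list(n = n, N = N, T_step = as.numeric(T_step)),
            class = "multistep_params")
}

#' @export
print.multistep_params <- function(x, ...) {
  cat(sprintf("Multistep catastrophe model: n = %d of N = %d, T' = %g s\n",
              x$n, x$N, x$T_step))
  cat(sprintf("  mean lifetime T = %g s\n", mean_lifetime(x)))
  invisible(x)
}

# Harmonic tail sum H(n, N) = sum_{i=N-n+1}^{N} 1/i; the mean of the n-th
# order statistic of N unit exponentials.
harmonic_tail <- function(n, N) sum(1 / seq.int(N - n + 1L, N))

#' Steady-state probability that the subterminal subunit is GDP
#'
#' For a growing protofilament under coupled-random hydrolysis, the
#' subterminal occupancy p_D obeys dp_D/dt = h (1 - p_D) - r_pf p_D:
#' hydrolysis converts a GTP subterminal at rate `h`, while each subunit
#' addition (rate `r_pf`) buries the previous terminal — which is always GTP,
#' since the terminal subunit cannot hydrolyze — as the new subterminal.
#' The stationary solution is h / (h + r_pf); for small h this is
#' approximately h / r_pf.
#'
#' @param h hydrolysis rate constant (s^-1).
#' @param r_pf per-protofilament association rate (s^-1).
#' @param mode `"steady_state"` for h / (h + r_pf), `"small_h"` for h / r_pf.
#' @return Probability p_D.
#' @examples
#' subterminal_gdp_prob(0.12, 2.9538)            # ~0.039
#' subterminal_gdp_prob(0.12, 2.9538, "small_h") # ~0.041
#' @export
subterminal_gdp_prob <- function(h, r_pf, mode = c("steady_state", "small_h")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(h), is.numeric(r_pf))
  if (any(is.na(h)) || any(h < 0)) stop("'h' must be >= 0 (is it unset in the preset?)")
  if (any(is.na(r_pf)) || any(r_pf < 0)) stop("'r_pf' must be >= 0")
  if (mode == "small_h") {
    if (any(r_pf == 0)) stop("small-h approximation requires r_pf > 0")
    return(h / r_pf)
  }
  if (any(h == 0 & r_pf == 0)) stop("h and r_pf cannot both be zero")
  h / (h + r_pf)
}

#' Mean step time of one protofilament
#'
#' A destabilizing event requires the terminal subunit to dissociate (rate
#' `k_pf`) while the subterminal subunit is GDP (probability `p_D`), so steps
#' occur at rate `k_pf * p_D` and the mean step time is
#' `T' = 1 / (k_pf * p_D)`. Step times are exponential with this mean.
#'
#' @param k_pf per-protofilament dissociation rate of the terminal stably
#'   incorporated subunit (s^-1).
#' @param p_D probability the subterminal subunit is GDP.
#' @return T' in seconds; `Inf` (no catastrophe) when the step rate is zero.
#' @examples
#' step_time(0.2 / 13, subterminal_gdp_prob(0.12, 3.2 * 12 / 13))  # ~1665 s
#' @export
step_time <- function(k_pf, p_D) {
  stopifnot(is.numeric(k_pf), is.numeric(p_D))
  if (any(is.na(k_pf)) || any(k_pf < 0)) stop("'k_pf' must be >= 0")
  if (any(is.na(p_D)) || any(p_D < 0) || any(p_D > 1))
    stop("'p_D' must be a probability in [0, 1]")
  ifelse(k_pf * p_D > 0, 1 / (k_pf * p_D), Inf)
}

#' Lifetime distribution of the multistep model
#'
#' Density and distribution function of the microtubule lifetime: the `n`-th
#' order statistic of `N` iid exponential step times with mean `T_step`. With
#' p(t) = 1 - exp(-t/T'),
#' \deqn{f(t) = \frac{N!}{(n-1)!(N-n)!} p(t)^{n-1} (1-p(t))^{N-n} e^{-t/T'}/T'}
#' and the cdf is the upper binomial tail P(at least n of N steps by t).
#' For (n = 3, N = 13) the combinatorial factor is 858.
#'
#' @param t time (s), vectorized, non-negative.
#' @param msp a [multistep_params] object.
#' @return Density (s^-1) or probability.
#' @examples
#' msp <- multistep_params(3, 13, T_step = 1580)
#' integrate(lifetime_pdf, 0, Inf, msp = msp)  # 1
#' @export
lifetime_pdf <- function(t, msp) {
  stopifnot(inherits(msp, "multistep_params"), is.numeric(t))
  if (any(is.na(t)) || any(t < 0)) stop("'t' must be >= 0")
  n <- msp$n; N <- msp$N; Tp <- msp$T_step
  lfac <- lgamma(N + 1) - lgamma(n) - lgamma(N - n + 1)
  p <- -expm1(-t / Tp)  # 1 - exp(-t/T'), accurate for small t
  lp <- if (n > 1L) (n - 1) * log(p) else 0  # avoid 0 * log(0) at n = 1
  exp(lfac + lp - (N - n + 1) * t / Tp) / Tp
}

#' @rdname lifetime_pdf
#' @export
lifetime_cdf <- function(t, msp) {
  stopifnot(inherits(msp, "multistep_params"), is.numeric(t))
  if (any(is.na(t)) || any(t < 0)) stop("'t' must be >= 0")
  stats::pbinom(msp$n - 1L, msp$N, -expm1(-t / msp$T_step), lower.tail = FALSE)
}

#' Mean microtubule lifetime
#'
#' Closed-form mean of the `n`-th order statistic of `N` iid exponentials:
#' `T = T' * H(n, N)` with `H(n, N) = sum_{i=N-n+1}^{N} 1/i`. For
#' (n = 3, N = 13), `H = 1/13 + 1/12 + 1/11 = 0.2512`.
#'
#' @param msp a [multistep_params] object.
#' @return Mean lifetime (s).
#' @examples
#' mean_lifetime(multistep_params(3, 13, 1580))  # ~397 s
#' @export
mean_lifetime <- function(msp) {
  stopifnot(inherits(msp, "multistep_params"))
  msp$T_step * harmonic_tail(msp$n, msp$N)
}

#' Mean lifetime as a function of tubulin concentration
#'
#' Combines the steady-state (or small-h) subterminal GDP probability with the
#' step time and the order-statistic mean:
#' `T(c) = H(n, N) * (h + r_pf) / (k_pf * h)` (exact steady state), or
#' `T(c) = H(n, N) * r_pf / (k_pf * h)` (small-h approximation), with
#' `r_pf = k_on * c / N` and `k_pf = k_T / N`. Lifetime grows with the
#' association rate and falls with both the hydrolysis and dissociation rates.
#'
#' @param params a [rate_params] object with `h` set.
#' @param conc tubulin concentration (uM), vectorized, strictly positive.
#' @param n destabilizing events to catastrophe (default 3).
#' @param approx logical; use the small-h form of p_D.
#' @return Mean lifetime(s) in seconds.
#' @examples
#' mean_lifetime_vs_concentration(preset_params("fig5d"), 12)  # ~418 s
#' @export
mean_lifetime_vs_concentration <- function(params, conc, n = 3L, approx = FALSE) {
  stopifnot(inherits(params, "rate_params"), is.numeric(conc))
  if (is.na(params$h)) stop("'h' is unset in these parameters")
  if (any(is.na(conc)) || any(conc <= 0)) stop("'conc' must be > 0")
  N <- params$n_pf
  k_pf <- params$k_T / N
  r_pf <- params$k_on * conc / N
  if (approx && any(r_pf == 0)) stop("small-h approximation requires r_pf > 0")
  H <- harmonic_tail(as.integer(n), N)
  p_D <- subterminal_gdp_prob(params$h, r_pf,
                              mode = if (approx) "small_h" else "steady_state")
  H * step_time(k_pf, pmin(p_D, 1))
}

#' Invert the mean-lifetime relation for the hydrolysis rate
#'
#' Solves `T(h) = H(n, N) * (h + r_pf) / (k_pf * h) = T_obs` for `h` by
#' bracketed root-finding. `T(h)` decreases from infinity (h -> 0) to the
#' infimum `H(n, N) / k_pf` (h -> Inf), so a unique root exists iff
#' `T_obs` exceeds that infimum.
#'
#' @param T_obs observed mean lifetime (s).
#' @param r_pf per-protofilament association rate (s^-1).
#' @param k_pf per-protofilament dissociation rate (s^-1).
#' @param n,N multistep parameters (defaults 3 of 13).
#' @return Hydrolysis rate h (s^-1).
#' @examples
#' solve_hydrolysis_rate(232, r_pf = 3.75, k_pf = 0.02)  # ~0.215 s^-1
#' @export
solve_hydrolysis_rate <- function(T_obs, r_pf, k_pf, n = 3L, N = 13L) {
  stopifnot(is.numeric(T_obs), length(T_obs) == 1L,
            is.numeric(r_pf), length(r_pf) == 1L,
            is.numeric(k_pf), length(k_pf) == 1L)
  if (k_pf <= 0) stop("'k_pf' must be > 0")
  if (r_pf < 0) stop("'r_pf' must be >= 0")
  H <- harmonic_tail(as.integer(n), as.integer(N))
  inf_T <- H / k_pf
  if (T_obs <= inf_T)
    stop(sprintf(paste0("no solution: T_obs = %g s is at or below the h -> Inf ",
                        "limit H(n,N)/k_pf = %g s"), T_obs, inf_T))
  f <- function(h) H * (h + r_pf) / (k_pf * h) - T_obs
  lo <- 1e-6; hi <- 1e3
  while (f(lo) < 0 && lo > 1e-300) lo <- lo / 10   # f(lo) > 0 for small h
  while (f(hi) > 0 && hi < 1e300) hi <- hi * 10
  stats::uniroot(f, c(lo, hi), tol = 1e-10 * min(1, hi))$root
}

#' Steady-state distribution of accrued destabilizations
#'
#' For a population of long-growing microtubules observed at a random time
#' before catastrophe, the probability of having accrued `m` destabilizations
#' (m = 0, ..., n-1) is proportional to the mean dwell time in state m,
#' `1 / ((N - m) s)`, giving `P(m) = (1 / (N - m)) / H(n, N)`.
#'
#' @param n,N multistep parameters.
#' @return Numeric vector `P(0), ..., P(n-1)` summing to 1.
#' @examples
#' dilution_state_distribution(3, 13)  # 0.306 0.332 0.362
#' @export
dilution_state_distribution <- function(n = 3L, N = 13L) {
  n <- as.integer(n); N <- as.integer(N)
  if (n < 1L || n > N) stop("need 1 <= n <= N")
  m <- 0:(n - 1L)
  p <- (1 / (N - m)) / harmonic_tail(n, N)
  names(p) <- paste0("m=", m)
  p
}

#' Mean time to catastrophe after dilution
#'
#' On dilution to `c_post`, the per-protofilament step rate becomes
#' `s_post = k_pf * p_D(c_post)` with `p_D = h / (h + k_on c_post / N)`; at
#' `c_post = 0` this is simply `k_pf` (every terminal dissociation of a
#' hydrolyzed-subterminal protofilament counts, and with h >> k_pf the
#' subterminal hydrolyzes long before the terminal leaves). Averaging the
#' remaining order-statistic waiting times over the steady-state distribution
#' of already-accrued destabilizations gives
#' \deqn{E[T_{dil}] = \sum_{m=0}^{n-1} P(m) \sum_{j=m}^{n-1} \frac{1}{(N-j)\,s_{post}}.}
#'
#' @param params a [rate_params] object with `h` set.
#' @param c_post post-dilution tubulin concentration (uM), may be 0.
#' @param n,N multistep parameters (`N` defaults to `params$n_pf`).
#' @param from_state optionally condition on a fixed number of accrued
#'   destabilizations instead of averaging over the steady state.
#' @return Mean post-dilution lifetime (s); `Inf` if the post-dilution step
#'   rate is zero (no catastrophe).
#' @examples
#' p <- rate_params(k_on = 3.2, k_T = 0.26, h = 0.12)  # k_pf = 0.02 s^-1
#' dilution_mean_time(p, c_post = 0)                    # ~8.4 s
#' @export
dilution_mean_time <- function(params, c_post = 0, n = 3L, N = params$n_pf,
                               from_state = NULL) {
  stopifnot(inherits(params, "rate_params"), is.numeric(c_post),
            length(c_post) == 1L, c_post >= 0)
  if (is.na(params$h)) stop("'h' is unset in these parameters")
  n <- as.integer(n); N <- as.integer(N)
  k_pf <- params$k_T / N
  r_pf_post <- params$k_on * c_post / N
  s_post <- k_pf * subterminal_gdp_prob(params$h, r_pf_post)
  if (s_post == 0) return(Inf)
  remaining <- function(m) sum(1 / ((N - (m:(n - 1L))) * s_post))
  if (!is.null(from_state)) {
    m0 <- as.integer(from_state)
    if (m0 < 0L || m0 >= n) stop("'from_state' must be in 0..n-1")
    return(remaining(m0))
  }
  P <- dilution_state_distribution(n, N)
  sum(P * vapply(0:(n - 1L), remaining, numeric(1)))
}
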
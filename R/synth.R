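#' Sample lifetimes from the multistep model
#'
#' Draws each lifetime as the `n`-th smallest of `N` iid exponential step
#' times with mean `T_step` (all `N` exponentials drawn, the `n`-th selected
#' by partial sort — distribution-exact, no discretization). Optional
#' administrative right-censoring at a fixed time truncates observations the
#' way an imaging run would.
#'
#' @param msp a [multistep_params] object.
#' @param size sample size (>= 1).
#' @param censor_time optional censoring time (s, > 0): lifetimes beyond it
#'   are recorded at `censor_time` with `censored = TRUE`.
#' @param concentration concentration label (uM) carried as metadata.
#' @param seed optional integer seed.
#' @return A [lifetime_sample].
#' @examples
#' s <- sample_lifetimes(multistep_params(3, 13, 1000), size = 1000, seed = 1)
#' mean(s$lifetime_s)  # ~ 251 s = H(3,13) * 1000
#' @export
sample_lifetimes <- function(msp, size, censor_time = NULL,
                             concentration = NA_real_, seed = NULL) {
  stopifnot(inherits(msp, "multistep_params"))
  size <- as.integer(size)
  if (size < 1L) stop("'size' must be >= 1")
  if (!is.null(censor_time) && censor_time <= 0)
    stop("'censor_time' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- msp$n; N <- msp$N
  draws <- matrix(stats::rexp(size * N, rate = 1 / msp$T_step), nrow = size)
  lt <- apply(draws, 1L, function(x) sort(x, partial = n)[n])
  cens <- rep(FALSE, size)
  if (!is.null(censor_time)) {
    cens <- lt > censor_time
    lt[cens] <- censor_time
  }
  lifetime_sample(lt, censored = cens, concentration = concentration,
                  source = sprintf("synth:n=%d,N=%d,T'=%g", n, N, msp$T_step))
}

#' Synthetic lifetime datasets across a concentration series
#'
#' For each concentration, computes the model step time
#' `T'(c) = 1 / (k_pf * p_D(c))` from the kinetic constants (steady-state
#' subterminal GDP probability) and samples lifetimes from the multistep law.
#'
#' @param params a [rate_params] object with `h` set.
#' @param concentrations tubulin concentrations (uM, all > 0); an empty
#'   vector yields an empty sample.
#' @param n destabilizations to catastrophe (default 3).
#' @param sizes sample size per concentration (recycled).
#' @param seed master seed.
#' @param censor_time optional censoring time (s).
#' @return A single [lifetime_sample] with rows tagged by
#'   `concentration_uM`; the generating step times are attached as attribute
#'   `"T_step"` (named by concentration).
#' @export
make_concentration_series <- function(params, concentrations, n = 3L, sizes,
                                      seed = 1, censor_time = NULL) {
  stopifnot(inherits(params, "rate_params"))
  if (length(concentrations) == 0L) {
    out <- lifetime_sample(numeric(0) + 1, source = "synth:series")[0, ]
    class(out) <- c("lifetime_sample", "data.frame")
    attr(out, "T_step") <- numeric(0)
    return(out)
  }
  if (any(concentrations <= 0)) stop("all concentrations must be > 0")
  if (is.na(params$h)) stop("'h' is unset in these parameters")
  sizes <- rep_len(as.integer(sizes), length(concentrations))
  N <- params$n_pf
  parts <- vector("list", length(concentrations))
  Tsteps <- numeric(length(concentrations))
  for (i in seq_along(concentrations)) {
    dr <- derive_rates(params, concentrations[i])
    Tp <- step_time(dr$k_pf, subterminal_gdp_prob(params$h, dr$r_pf))
    Tsteps[i] <- Tp
    parts[[i]] <- sample_lifetimes(multistep_params(n, N, Tp), sizes[i],
                                   censor_time = censor_time,
                                   concentration = concentrations[i],
                                   seed = substream_seed(seed, i))
  }
  out <- do.call(rbind, parts)
  attr(out, "source") <- "synth:series"
  attr(out, "T_step") <- stats::setNames(Tsteps, concentrations)
  class(out) <- c("lifetime_sample", "data.frame")
  out
}

#' Synthetic dilution experiment
#'
#' Draws, for each replicate, the number of destabilizations already accrued
#' at the moment of dilution from the steady-state distribution
#' [dilution_state_distribution()], then samples the remaining
#' order-statistic waiting times at the post-dilution step rate
#' `s_post = k_pf * p_D(c_post)` (which is `k_pf` at `c_post = 0`). The
#' sample mean matches [dilution_mean_time()] exactly in expectation.
#'
#' @param params a [rate_params] object with `h` set.
#' @param c_pre,c_post pre-/post-dilution concentrations (uM),
#'   `c_post < c_pre`.
#' @param n_replicates number of replicates.
#' @param seed integer seed.
#' @param n,N multistep parameters (`N` defaults to `params$n_pf`).
#' @return A [lifetime_sample] of post-dilution catastrophe delays.
#' @examples
#' p <- rate_params(k_on = 3.2, k_T = 0.26, h = 0.12)
#' s <- simulate_dilution_experiment(p, c_pre = 10, c_post = 0,
#'                                   n_replicates = 1000, seed = 1)
#' mean(s$lifetime_s)  # ~ 8.4 s
#' @export
simulate_dilution_experiment <- function(params, c_pre, c_post = 0,
                                         n_replicates, seed = NULL,
                                         n = 3L, N = params$n_pf) {
  stopifnot(inherits(params, "rate_params"))
  if (c_post >= c_pre) stop("'c_post' must be below 'c_pre'")
  if (is.na(params$h)) stop("'h' is unset in these parameters")
  n <- as.integer(n); N <- as.integer(N)
  k_pf <- params$k_T / N
  s_post <- k_pf * subterminal_gdp_prob(params$h, params$k_on * c_post / N)
  if (s_post <= 0) stop("post-dilution step rate is zero: no catastrophe")
  if (!is.null(seed)) set.seed(seed)
  P <- dilution_state_distribution(n, N)
  m0 <- sample.int(n, n_replicates, replace = TRUE, prob = P) - 1L
  lt <- vapply(m0, function(m) {
    j <- m:(n - 1L)
    sum(stats::rexp(length(j), rate = (N - j) * s_post))
  }, numeric(1))
  lifetime_sample(lt, concentration = c_post,
                  source = sprintf("synth:dilution %g->%g uM", c_pre, c_post))
}
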
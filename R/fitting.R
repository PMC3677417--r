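#' Log-likelihood of lifetime data under the multistep model
#'
#' Sum of log densities [lifetime_pdf()] over uncensored records plus log
#' survival `log(1 - cdf)` over right-censored records.
#'
#' @param data a [lifetime_sample] (or data frame with `lifetime_s`,
#'   `censored`).
#' @param msp a [multistep_params] object.
#' @return Log-likelihood (scalar).
#' @export
lifetime_loglik <- function(data, msp) {
  stopifnot(is.data.frame(data), inherits(msp, "multistep_params"))
  if (nrow(data) == 0L) stop("empty lifetime data")
  t <- data$lifetime_s
  if (any(is.na(t)) || any(t <= 0)) stop("all lifetimes must be positive")
  cens <- if (is.null(data$censored)) rep(FALSE, nrow(data)) else data$censored
  ll <- 0
  if (any(!cens)) ll <- ll + sum(log(lifetime_pdf(t[!cens], msp)))
  if (any(cens)) ll <- ll + sum(log1p(-lifetime_cdf(t[cens], msp)))
  ll
}

#' Maximum-likelihood fit of the multistep catastrophe model
#'
#' For each candidate `n`, maximizes the likelihood over the step time `T'`
#' by bracketed one-dimensional search, then selects the `n` with the highest
#' maximized likelihood (ties broken toward smaller `n` — no information
#' criterion, the candidates are a discrete grid at fixed dimension). The
#' search bracket is auto-scaled from the observed mean via the harmonic
#' factor: the first guess is `mean / H(n, N)`.
#'
#' @param data a [lifetime_sample]; needs >= 10 uncensored records.
#' @param n_candidates integer candidates for `n` (default 2:4).
#' @param N protofilament count (default 13).
#' @return Object of class `mt_fit`: `n_hat`, `T_step_hat`, `log_likelihood`,
#'   `T_step_se` (`NA` until [parametric_bootstrap_se()] is run), `N`,
#'   `profile` (data frame n / T_step / loglik), `n_data`, `n_censored`.
#' @examples
#' set.seed(1)
#' d <- sample_lifetimes(multistep_params(3, 13, 1580), size = 500)
#' fit_mle(d)
#' @export
fit_mle <- function(data, n_candidates = 2:4, N = 13L) {
  stopifnot(is.data.frame(data))
  N <- as.integer(N)
  n_candidates <- sort(unique(as.integer(n_candidates)))
  if (any(n_candidates < 1L) || any(n_candidates > N))
    stop("all candidate n must lie in 1..N")
  cens <- if (is.null(data$censored)) rep(FALSE, nrow(data)) else data$censored
  if (all(cens)) stop("all records are censored; cannot fit")
  if (sum(!cens) < 10L) stop("need at least 10 uncensored lifetimes")
  mean_obs <- mean(data$lifetime_s[!cens])

  prof <- data.frame(n = n_candidates, T_step = NA_real_, loglik = NA_real_)
  for (j in seq_along(n_candidates)) {
    n <- n_candidates[j]
    T0 <- mean_obs / harmonic_tail(n, N)
    obj <- function(logT) {
      lifetime_loglik(data, multistep_params(n, N, exp(logT)))
    }
    opt <- stats::optimize(obj, interval = log(T0) + c(-log(50), log(50)),
                           maximum = TRUE, tol = 1e-8)
    if (!is.finite(opt$objective))
      stop("likelihood maximization failed for n = ", n,
           " (objective not finite at optimum)")
    prof$T_step[j] <- exp(opt$maximum)
    prof$loglik[j] <- opt$objective
  }
  best <- which.max(prof$loglik)  # which.max takes the first (smallest n) on ties
  structure(
    list(n_hat = prof$n[best], T_step_hat = prof$T_step[best],
         log_likelihood = prof$loglik[best], T_step_se = NA_real_,
         N = N, profile = prof,
         n_data = nrow(data), n_censored = sum(cens)),
    class = "mt_fit")
}

#' @export
print.mt_fit <- function(x, ...) {
  cat(sprintf("Multistep-model MLE (%d lifetimes, %d censored, N = %d)\n",
              x$n_data, x$n_censored, x$N))
  cat(sprintf("  n_hat = %d, T'_hat = %.4g s%s, logL = %.4f\n",
              x$n_hat, x$T_step_hat,
              if (is.na(x$T_step_se)) "" else sprintf(" (SE %.3g s)", x$T_step_se),
              x$log_likelihood))
  cat("  profile over n:\n")
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' Parametric-bootstrap standard errors for the multistep fit
#'
#' Resamples `reps` datasets of size `data_size` at the fitted
#' `(n_hat, T_step_hat)`, refits each with the same candidate set, and
#' reports the spread of the refitted step times and the selection frequency
#' of each `n`.
#'
#' @param fit an `mt_fit` object.
#' @param data_size size of each bootstrap dataset (defaults to the fitted
#'   data size).
#' @param reps bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param n_candidates candidate set for the refits (defaults to the fit's
#'   profile grid).
#' @param censor_time optional administrative censoring time applied to each
#'   bootstrap dataset, to mirror how the fitted data were truncated.
#' @return List: `T_step_se`, `T_step_boot` (vector), `n_select_freq`
#'   (named table), `reps`; also returns the input `fit` with `T_step_se`
#'   filled, as attribute `"fit"`.
#' @export
parametric_bootstrap_se <- function(fit, data_size = fit$n_data, reps = 200,
                                    seed = 1, n_candidates = fit$profile$n,
                                    censor_time = NULL) {
  stopifnot(inherits(fit, "mt_fit"))
  if (reps < 100) stop("'reps' must be >= 100 for stable bootstrap SEs")
  msp <- multistep_params(fit$n_hat, fit$N, fit$T_step_hat)
  Tb <- numeric(reps); nb <- integer(reps)
  for (b in seq_len(reps)) {
    d <- sample_lifetimes(msp, size = data_size, censor_time = censor_time,
                          seed = substream_seed(seed, b))
    f <- fit_mle(d, n_candidates = n_candidates, N = fit$N)
    Tb[b] <- f$T_step_hat; nb[b] <- f$n_hat
  }
  fit$T_step_se <- stats::sd(Tb)
  out <- list(T_step_se = fit$T_step_se, T_step_boot = Tb,
              n_select_freq = table(factor(nb, levels = sort(unique(c(nb, fit$n_hat))))) / reps,
              reps = reps)
  attr(out, "fit") <- fit
  out
}
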
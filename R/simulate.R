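#' @useDynLib mtkinetics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.mechanisms <- c(coupled = 0L, vectorial = 1L, random = 2L, coupled_random = 3L)
.rules <- c(terminal_gdp = 0L, n_terminal_gdp = 1L, total_depolymerization = 2L,
            cap_loss = 3L, none = 4L)
.term_labels <- c("catastrophe", "censored_time", "censored_length")

# Order-independent per-replicate substream seeds derived from one master
# seed by a fixed counter formula (values stay within R's 32-bit seed range).
substream_seed <- function(seed, i) {
  (as.numeric(seed) %% 2147483647 + i * 62869) %% 2147483646 + 1
}

#' Simulate one protofilament under a chosen hydrolysis mechanism
#'
#' Exact continuous-time (Gillespie) simulation of a single filament growing
#' from a stable, non-hydrolyzable seed. Enabled events and their rates:
#' subunit addition at `r = k_on * c` (helical mapping, the convention of the
#' single-protofilament literature) or `r / n_pf` (per-protofilament mapping);
#' terminal dissociation at `k_T` (GTP tip) or `k_D` (GDP tip; instantaneous
#' removal cascade if `k_D_infinite`); hydrolysis according to the mechanism:
#' \describe{
#'   \item{coupled}{a subunit hydrolyzes deterministically the moment it is
#'     buried by a new addition; no hydrolysis clock.}
#'   \item{vectorial}{rate `h` at the single GDP/GTP interface.}
#'   \item{random}{rate `h` at every GTP subunit.}
#'   \item{coupled_random}{rate `h` at every GTP subunit except the terminal.}
#' }
#' The run terminates at the catastrophe rule's condition, at `t_max`
#' (`censored_time`) or at `length_max` (`censored_length`).
#'
#' @param params a [rate_params] object (`h` must be set unless
#'   `mechanism = "coupled"`).
#' @param conc tubulin concentration (uM).
#' @param mechanism one of `"coupled"`, `"vectorial"`, `"random"`,
#'   `"coupled_random"`.
#' @param rule catastrophe rule: `"terminal_gdp"`, `"n_terminal_gdp"` (with
#'   `rule_N`), `"total_depolymerization"` (length returns to the seed),
#'   `"cap_loss"` (the terminal GTP run vanishes), or `"none"` (censor only).
#' @param rule_N threshold for `"n_terminal_gdp"` (>= 1).
#' @param t_max,length_max censoring caps (defaults 5000 s, 1e5 dimers).
#' @param seed integer seed; fixed seed gives a bit-identical trajectory.
#' @param mapping `"helical"` (whole-microtubule rates; default, as in the
#'   single-protofilament literature) or `"per_protofilament"` (rates / n_pf).
#' @param record keep the per-event history (set `FALSE` for big ensembles).
#' @return An object of class `mt_trajectory`: list with `times`, `lengths`,
#'   `events` (factor: addition/dissociation/hydrolysis/cascade), `tip_gtp`,
#'   `status` (catastrophe / censored_time / censored_length), `t_end`,
#'   `length_end`, `final_state` (tip-first 1/0 = GTP/GDP), and the call
#'   metadata (`seed`, rates).
#' @examples
#' p <- preset_params("table1-gtp")
#' tr <- simulate_protofilament(p, conc = 10, mechanism = "coupled",
#'                              rule = "terminal_gdp", seed = 1)
#' tr$status; tr$t_end
#' @export
simulate_protofilament <- function(params, conc,
                                   mechanism = c("coupled_random", "coupled",
                                                 "vectorial", "random"),
                                   rule = c("terminal_gdp", "n_terminal_gdp",
                                            "total_depolymerization",
                                            "cap_loss", "none"),
                                   rule_N = 2L, t_max = 5000, length_max = 1e5,
                                   seed = NULL,
                                   mapping = c("helical", "per_protofilament"),
                                   record = TRUE) {
  stopifnot(inherits(params, "rate_params"))
  mechanism <- match.arg(mechanism)
  rule <- match.arg(rule)
  mapping <- match.arg(mapping)
  if (!is.numeric(t_max) || t_max <= 0) stop("'t_max' must be > 0")
  if (!is.numeric(length_max) || length_max <= 0) stop("'length_max' must be > 0")
  if (rule == "n_terminal_gdp" && (!is.numeric(rule_N) || rule_N < 1))
    stop("'rule_N' must be an integer >= 1")
  if (mechanism == "coupled" && rule == "cap_loss")
    stop("rule 'cap_loss' is meaningless under coupled hydrolysis ",
         "(the cap is pinned at one subunit); use 'terminal_gdp'")
  if (mechanism != "coupled" && is.na(params$h))
    stop("'h' is unset in these parameters")

  dr <- derive_rates(params, conc)
  scale <- if (mapping == "per_protofilament") params$n_pf else 1
  r <- dr$r / scale
  kT <- params$k_T / scale
  kD <- params$k_D / scale
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_sim_filament(r, kT, kD, params$k_D_infinite,
                          if (is.na(params$h)) 0 else params$h,
                          .mechanisms[[mechanism]], .rules[[rule]],
                          as.integer(rule_N), t_max, as.integer(length_max),
                          isTRUE(record))
  structure(
    list(times = res$times, lengths = res$lengths,
         events = factor(c("addition", "dissociation", "hydrolysis",
                           "cascade")[res$events],
                         levels = c("addition", "dissociation", "hydrolysis",
                                    "cascade")),
         tip_gtp = res$tip_gtp, status = .term_labels[res$status + 1L],
         t_end = res$t_end, length_end = res$length_end,
         final_state = res$state,
         mechanism = mechanism, rule = rule, mapping = mapping,
         conc = conc, seed = seed, params = params),
    class = "mt_trajectory")
}

#' @export
print.mt_trajectory <- function(x, ...) {
  cat(sprintf("Protofilament trajectory (%s hydrolysis, rule %s, %g uM)\n",
              x$mechanism, x$rule, x$conc))
  cat(sprintf("  %d events over %.4g s; final length %d dimers; outcome: %s\n",
              length(x$times), x$t_end, x$length_end, x$status))
  invisible(x)
}

#' @export
as.data.frame.mt_trajectory <- function(x, ...) {
  data.frame(time_s = x$times, length_dimers = x$lengths,
             event = as.character(x$events),
             tip_state = c("empty", "GDP", "GTP")[x$tip_gtp + 2L])
}

#' Ensemble of single-filament catastrophe lifetimes
#'
#' Runs `n_replicates` independent [simulate_protofilament()] runs (each on
#' its own seed substream derived from `seed`) and collects lifetimes and
#' censoring flags.
#'
#' @inheritParams simulate_protofilament
#' @param n_replicates ensemble size.
#' @param seed master seed for the replicate substreams.
#' @return A `lifetime_sample` (see [lifetime_sample()]); censored replicates
#'   carry their last observed time and `censored = TRUE`.
#' @export
simulate_lifetime_ensemble <- function(params, conc, mechanism, rule,
                                       n_replicates, seed,
                                       rule_N = 2L, t_max = 5000,
                                       length_max = 1e5,
                                       mapping = c("helical", "per_protofilament")) {
  mapping <- match.arg(mapping)
  lt <- numeric(n_replicates)
  cens <- logical(n_replicates)
  for (i in seq_len(n_replicates)) {
    tr <- simulate_protofilament(params, conc, mechanism, rule,
                                 rule_N = rule_N, t_max = t_max,
                                 length_max = length_max,
                                 seed = substream_seed(seed, i),
                                 mapping = mapping, record = FALSE)
    lt[i] <- tr$t_end
    cens[i] <- tr$status != "catastrophe"
  }
  lifetime_sample(lt, censored = cens, concentration = conc,
                  source = sprintf("simulate:%s/%s", mechanism, rule))
}

#' Is the vectorial mechanism bounded?
#'
#' In the vectorial model the hydrolysis front (speed `h`) must catch the tip
#' (mean speed `r - k`) for the cap — and hence the filament — to stay
#' bounded: returns `TRUE` iff `h > r - k` (strictly).
#'
#' @param r association rate (s^-1).
#' @param k GTP-tubulin dissociation rate (s^-1).
#' @param h hydrolysis front rate (s^-1).
#' @return Logical.
#' @examples
#' vectorial_bounded(42.1, 0.1, 43.5)  # TRUE
#' @export
vectorial_bounded <- function(r, k, h) {
  stopifnot(is.numeric(r), is.numeric(k), is.numeric(h))
  if (any(is.na(c(r, k, h))) || any(c(r, k, h) < 0)) stop("rates must be >= 0")
  h > r - k
}

#' Monte-Carlo estimate of the subterminal GDP probability
#'
#' Long single-protofilament coupled-random simulation at per-protofilament
#' rates; returns the time-weighted fraction of the run during which the
#' subterminal subunit is GDP. This is the mechanistic counterpart of the
#' analytic [subterminal_gdp_prob()] and includes the small O(k'/r')
#' correction that the analytic master equation neglects. A filament that
#' shrinks back to the seed continues from a fresh GTP seed (restarts are
#' counted).
#'
#' @param params a [rate_params] object with `h` set.
#' @param conc tubulin concentration (uM).
#' @param t_total total simulated time (s); should cover >= 1e4 events.
#' @param seed integer seed.
#' @param init_len initial all-GTP filament length (dimers); the default 0
#'   starts from the bare seed, which requires `conc > 0` to grow.
#' @return List with `p_gdp`, `n_events`, `n_restarts`.
#' @export
estimate_subterminal_gdp_prob <- function(params, conc, t_total = 2e4, seed = NULL,
                                          init_len = 0L) {
  stopifnot(inherits(params, "rate_params"))
  if (is.na(params$h)) stop("'h' is unset in these parameters")
  dr <- derive_rates(params, conc)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_subterminal_occupancy(dr$r_pf, dr$k_pf, params$k_D / params$n_pf,
                                   params$k_D_infinite, params$h, t_total,
                                   as.integer(init_len))
  if (res$n_events < 1e4)
    warning("fewer than 1e4 events simulated; increase 't_total'")
  res
}

#' GTP-cap statistics from stationary growth snapshots
#'
#' Simulates independent coupled-random protofilaments at per-protofilament
#' rates to a fixed snapshot time, then summarizes the tip structure across
#' snapshots: the uninterrupted terminal GTP run length (the GTP cap), the
#' GTP fraction as a function of depth below the tip, and GTP-island counts
#' (maximal GTP runs not touching the tip — hydrolysis remnants in the
#' lattice).
#'
#' @param params a [rate_params] object with `h` set.
#' @param conc tubulin concentration (uM); growth-dominated (`r_pf > k_pf`)
#'   is the intended regime — a shrink-dominated call is flagged with a
#'   warning but still summarized.
#' @param n_snapshots number of independent snapshots.
#' @param seed master seed.
#' @param t_snapshot snapshot time (s); default `10 / h`, long enough for the
#'   tip-region nucleotide profile to reach stationarity.
#' @return List of class `cap_statistics`: `cap_mean`, `cap_lengths`,
#'   `gtp_fraction_by_depth` (data frame depth/fraction), `efold_depth_fit`
#'   (fitted e-fold decay depth, theory `r_pf / h`), `island_count_mean`,
#'   `islands_per_dimer`, `mean_length`, `shrink_dominated`.
#' @export
cap_statistics <- function(params, conc, n_snapshots = 200, seed = NULL,
                           t_snapshot = NULL) {
  stopifnot(inherits(params, "rate_params"))
  if (is.na(params$h)) stop("'h' is unset in these parameters")
  dr <- derive_rates(params, conc)
  shrink <- dr$r_pf <= dr$k_pf
  if (shrink) warning("shrink-dominated regime (r_pf <= k_pf); ",
                      "cap statistics reflect transient filaments")
  if (is.null(t_snapshot))
    t_snapshot <- if (params$h > 0) 10 / params$h else 100
  kD_pf <- params$k_D / params$n_pf
  caps <- integer(n_snapshots)
  islands <- integer(n_snapshots)
  lens <- integer(n_snapshots)
  maxdepth <- 0L
  states <- vector("list", n_snapshots)
  for (i in seq_len(n_snapshots)) {
    set.seed(substream_seed(if (is.null(seed)) 0 else seed, i))
    res <- cpp_sim_filament(dr$r_pf, dr$k_pf, kD_pf, params$k_D_infinite,
                            params$h, .mechanisms[["coupled_random"]],
                            .rules[["none"]], 1L, t_snapshot, 1e6L, FALSE)
    s <- res$state  # tip first
    states[[i]] <- s
    lens[i] <- length(s)
    run <- 0L
    while (run < length(s) && s[run + 1L] == 1L) run <- run + 1L
    caps[i] <- run
    # GTP islands: maximal GTP runs strictly below the cap
    below <- if (run < length(s)) s[(run + 1L):length(s)] else integer(0)
    islands[i] <- if (length(below)) sum(diff(c(0L, below)) == 1L) else 0L
    maxdepth <- max(maxdepth, length(s))
  }
  depth_n <- integer(maxdepth); depth_gtp <- integer(maxdepth)
  for (s in states) {
    d <- length(s)
    if (d > 0) {
      depth_n[1:d] <- depth_n[1:d] + 1L
      depth_gtp[1:d] <- depth_gtp[1:d] + s
    }
  }
  prof <- data.frame(depth = seq_len(maxdepth),
                     fraction = ifelse(depth_n > 0, depth_gtp / depth_n, NA),
                     n = depth_n)
  # e-fold depth from the log-linear part of the profile, weighted by the
  # binomial information of each depth (var(log f_hat) ~ (1-f)/(n f))
  ok <- prof$n >= n_snapshots / 2 & prof$fraction > 0.1 & prof$fraction < 0.95
  efold <- NA_real_
  if (sum(ok) >= 3) {
    d <- prof[ok, ]
    w <- d$n * d$fraction / (1 - d$fraction)
    fit <- stats::lm(log(fraction) ~ depth, data = d, weights = w)
    efold <- -1 / stats::coef(fit)[["depth"]]
  }
  structure(
    list(cap_mean = mean(caps), cap_lengths = caps,
         gtp_fraction_by_depth = prof, efold_depth_fit = efold,
         efold_depth_theory = if (params$h > 0) dr$r_pf / params$h else Inf,
         island_count_mean = mean(islands),
         islands_per_dimer = mean(islands) / max(mean(lens), 1),
         mean_length = mean(lens), shrink_dominated = shrink,
         conc = conc, n_snapshots = n_snapshots),
    class = "cap_statistics")
}

#' @export
print.cap_statistics <- function(x, ...) {
  cat(sprintf("GTP-cap statistics at %g uM (%d snapshots)\n", x$conc, x$n_snapshots))
  cat(sprintf("  mean cap       : %.2f dimers (uninterrupted terminal GTP)\n",
              x$cap_mean))
  cat(sprintf("  e-fold depth   : %.1f dimers (theory r_pf/h = %.1f)\n",
              x$efold_depth_fit, x$efold_depth_theory))
  cat(sprintf("  GTP islands    : %.2f per filament (%.4f per dimer)\n",
              x$island_count_mean, x$islands_per_dimer))
  invisible(x)
}

#' Mechanistic multi-protofilament lifetime simulation
#'
#' Simulates `n_pf` independent coupled-random protofilaments at
#' per-protofilament rates (`r_pf = k_on c / n_pf`, `k_pf = k_T / n_pf`,
#' hydrolysis `h` at every non-terminal GTP subunit). A protofilament
#' destabilizes permanently the first time its terminal subunit dissociates
#' while the subunit below it is GDP; destabilized protofilaments are frozen
#' (destabilization is absorbing, so this choice cannot affect the lifetime).
#' The microtubule lifetime is the time of the `n_steps`-th destabilization.
#' This is the mechanistic validator of the analytic order-statistic model.
#'
#' @param params a [rate_params] object with `h` set.
#' @param conc tubulin concentration (uM).
#' @param n_steps destabilizations to catastrophe (default 3; must be
#'   <= `params$n_pf`).
#' @param n_replicates ensemble size.
#' @param seed master seed (replicates use order-independent substreams).
#' @param t_max censoring time per replicate (s).
#' @return A `lifetime_sample`.
#' @examples
#' \donttest{
#' s <- simulate_multipf_lifetimes(preset_params("fig5d"), conc = 12,
#'                                 n_replicates = 200, seed = 1)
#' mean(s$lifetime_s[!s$censored])  # ~ analytic 418 s
#' }
#' @export
simulate_multipf_lifetimes <- function(params, conc, n_steps = 3L,
                                       n_replicates, seed, t_max = 5000) {
  stopifnot(inherits(params, "rate_params"))
  if (is.na(params$h)) stop("'h' is unset in these parameters")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L || n_steps > params$n_pf)
    stop("'n_steps' must be between 1 and n_pf = ", params$n_pf)
  dr <- derive_rates(params, conc)
  kD_pf <- params$k_D / params$n_pf
  lt <- numeric(n_replicates); cens <- logical(n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(substream_seed(seed, i))
    res <- cpp_sim_multipf(dr$r_pf, dr$k_pf, kD_pf, params$k_D_infinite,
                           params$h, params$n_pf, n_steps, t_max, 0, 0, 0L)
    cens[i] <- isTRUE(res$censored)
    lt[i] <- if (cens[i]) t_max else res$lifetime
  }
  lifetime_sample(lt, censored = cens, concentration = conc,
                  source = sprintf("simulate:multipf n=%d", n_steps))
}

#' Mechanistic dilution experiment
#'
#' Emulates a rapid-dilution assay on the mechanistic lattice: for each
#' replicate, the number of destabilizations already accrued before dilution
#' is drawn from the steady-state distribution [dilution_state_distribution()],
#' the surviving protofilaments are grown at `c_pre` for `t_grow` seconds to
#' reach a stationary tip lattice, then the free-tubulin concentration drops
#' to `c_post` and the simulation runs until the remaining destabilizations
#' complete catastrophe.
#'
#' @inheritParams simulate_multipf_lifetimes
#' @param c_pre,c_post pre- and post-dilution concentrations (uM),
#'   `c_post < c_pre`.
#' @param t_grow pre-dilution growth time (s), default 50.
#' @return A `lifetime_sample` of post-dilution catastrophe delays.
#' @export
simulate_multipf_dilution <- function(params, c_pre, c_post = 0, n_steps = 3L,
                                      n_replicates, seed, t_grow = 50,
                                      t_max = 5000) {
  stopifnot(inherits(params, "rate_params"))
  if (is.na(params$h)) stop("'h' is unset in these parameters")
  if (c_post >= c_pre) stop("'c_post' must be below 'c_pre'")
  n_steps <- as.integer(n_steps)
  dr_pre <- derive_rates(params, c_pre)
  dr_post <- derive_rates(params, c_post)
  kD_pf <- params$k_D / params$n_pf
  P <- dilution_state_distribution(n_steps, params$n_pf)
  lt <- numeric(n_replicates); cens <- logical(n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(substream_seed(seed, i))
    m0 <- sample.int(n_steps, 1L, prob = P) - 1L
    res <- cpp_sim_multipf(dr_post$r_pf, dr_post$k_pf, kD_pf,
                           params$k_D_infinite, params$h, params$n_pf,
                           n_steps, t_max, dr_pre$r_pf, t_grow, m0)
    cens[i] <- isTRUE(res$censored)
    lt[i] <- if (cens[i]) t_max else res$lifetime
  }
  lifetime_sample(lt, censored = cens, concentration = c_post,
                  source = sprintf("simulate:dilution %g->%g uM", c_pre, c_post))
}
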
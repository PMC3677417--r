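#' Kinetic rate constants for microtubule plus-end dynamics
#'
#' Bundles the rate constants of the kinetic models: the second-order
#' association rate constant `k_on`, the GTP-tubulin and GDP-tubulin
#' dissociation rate constants `k_T` and `k_D`, the hydrolysis rate constant
#' `h`, and the protofilament count `n_pf`. Units are seconds and micromolar
#' throughout; lengths are tubulin dimers (8 nm per lattice layer).
#'
#' The GDP-tubulin off-rate is so large (290 s^-1) that it is often idealized
#' as infinite; set `k_D_infinite = TRUE` to make an exposed GDP terminal
#' dissociate instantaneously (a removal cascade down to the first GTP
#' subunit, or to the seed).
#'
#' @param k_on association rate constant (uM^-1 s^-1).
#' @param k_T GTP-tubulin dissociation rate constant (s^-1).
#' @param k_D GDP-tubulin dissociation rate constant (s^-1); ignored by the
#'   simulators when `k_D_infinite` is `TRUE`.
#' @param h hydrolysis rate constant (s^-1). May be `NA` when a parameter set
#'   does not fix it (e.g. the `"fig5c"` preset, where the step time is fitted
#'   directly); operations that need `h` then signal an error.
#' @param n_pf number of protofilaments (default 13).
#' @param k_D_infinite logical; treat the GDP off-rate as infinite.
#' @return An object of class `rate_params`.
#' @seealso [preset_params()], [derive_rates()]
#' @examples
#' p <- rate_params(k_on = 3.2, k_T = 0.2, h = 0.12)
#' derive_rates(p, conc = 12)
#' @export
rate_params <- function(k_on, k_T, k_D = 290, h = NA_real_, n_pf = 13L,
                        k_D_infinite = FALSE) {
  stopifnot(is.numeric(k_on), length(k_on) == 1L,
            is.numeric(k_T), length(k_T) == 1L,
            is.numeric(k_D), length(k_D) == 1L,
            is.numeric(h), length(h) == 1L,
            is.numeric(n_pf), length(n_pf) == 1L)
  n_pf <- as.integer(n_pf)
  if (is.na(k_on) || k_on < 0) stop("'k_on' must be a non-negative number")
  if (is.na(k_T) || k_T < 0) stop("'k_T' must be a non-negative number")
  if (is.na(k_D) || k_D < 0) stop("'k_D' must be a non-negative number")
  if (!is.na(h) && h < 0) stop("'h' must be non-negative (or NA if unset)")
  if (is.na(n_pf) || n_pf < 1L) stop("'n_pf' must be an integer >= 1")
  if (!k_D_infinite && k_D < k_T)
    stop("'k_D' must be >= 'k_T' when finite (GDP-tubulin dissociates faster)")
  structure(
    list(k_on = as.numeric(k_on), k_T = as.numeric(k_T),
         k_D = as.numeric(k_D), h = as.numeric(h), n_pf = n_pf,
         k_D_infinite = isTRUE(k_D_infinite)),
    class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Microtubule kinetic rate constants\n")
  cat(sprintf("  k_on : %g uM^-1 s^-1\n", x$k_on))
  cat(sprintf("  k_T  : %g s^-1 (GTP-tubulin off-rate)\n", x$k_T))
  cat(sprintf("  k_D  : %s s^-1 (GDP-tubulin off-rate)\n",
              if (x$k_D_infinite) "Inf" else format(x$k_D)))
  cat(sprintf("  h    : %s s^-1 (hydrolysis)\n",
              if (is.na(x$h)) "unset" else format(x$h)))
  cat(sprintf("  n_pf : %d protofilaments\n", x$n_pf))
  invisible(x)
}

# Named parameter sets used throughout: Table 1 rate constants and the
# simulation/fit presets of the model-comparison figures.
.preset_table <- function() {
  list(
    `table1-gtp` = list(k_on = 3.2, k_T = 0.1, k_D = 290, h = NA_real_,
      note = "GTP-tubulin column; off-rate is the GMPCPP value (footnote a)"),
    `fig5c` = list(k_on = 3.2, k_T = 0.2, k_D = 290, h = NA_real_,
      note = "multistep-fit preset; h left free (step time fitted directly)"),
    `fig5d` = list(k_on = 3.2, k_T = 0.2, k_D = 290, h = 0.12,
      note = "analytic multistep model fit"),
    `fig5a-vectorial` = list(k_on = 3.2, k_T = 0.1, k_D = 290, h = 43.5,
      note = "vectorial mechanism, h chosen just above r - k at 13.2 uM"),
    `fig5b-sim1` = list(k_on = 3.2, k_T = 1, k_D = 290, h = 1.43,
      note = "random-hydrolysis simulation 1"),
    `fig5b-sim2` = list(k_on = 3.2, k_T = 24, k_D = 290, h = 0.26,
      note = "random-hydrolysis simulation 2"))
}

#' Named kinetic parameter presets
#'
#' Returns one of the parameter sets shipped with the package:
#' \describe{
#'   \item{`"table1-gtp"`}{GTP-tubulin constants (k_on = 3.2 uM^-1 s^-1,
#'     k_T = 0.1 s^-1 assuming the GMPCPP off-rate, k_D = 290 s^-1); `h` unset.}
#'   \item{`"fig5c"`}{k_on = 3.2, k_T = 0.2; `h` free (the multistep fit
#'     estimates the step time directly).}
#'   \item{`"fig5d"`}{k_on = 3.2, k_T = 0.2, h = 0.12 — the analytic
#'     multi-protofilament model's fitted constants.}
#'   \item{`"fig5a-vectorial"`}{k_on = 3.2, k_T = 0.1, h = 43.5 — vectorial
#'     mechanism with h just above r - k.}
#'   \item{`"fig5b-sim1"`, `"fig5b-sim2"`}{random-hydrolysis simulation
#'     parameter sets (k = 1, h = 1.43; k = 24, h = 0.26).}
#' }
#'
#' @param name preset name.
#' @return A [rate_params] object.
#' @export
preset_params <- function(name) {
  tab <- .preset_table()
  if (!is.character(name) || length(name) != 1L || is.na(match(name, names(tab))))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available: ", paste(names(tab), collapse = ", "))
  p <- tab[[name]]
  rate_params(k_on = p$k_on, k_T = p$k_T, k_D = p$k_D, h = p$h)
}

#' Concentration-dependent rates
#'
#' Computes the whole-microtubule association rate `r = k_on * c` and the
#' per-protofilament rates `r_pf = r / n_pf`, `k_pf = k_T / n_pf` used by the
#' 13-independent-protofilament mapping of the multi-protofilament model.
#'
#' @param params a [rate_params] object.
#' @param conc free tubulin concentration (uM), non-negative scalar.
#' @return An object of class `derived_rates`: list with `r`, `r_pf`, `k_pf`,
#'   `conc` (all s^-1 except `conc` in uM).
#' @examples
#' derive_rates(preset_params("fig5d"), conc = 12)
#' @export
derive_rates <- function(params, conc) {
  stopifnot(inherits(params, "rate_params"),
            is.numeric(conc), length(conc) == 1L)
  if (is.na(conc) || conc < 0) stop("'conc' must be a non-negative concentration (uM)")
  r <- params$k_on * conc
  structure(
    list(r = r, r_pf = r / params$n_pf, k_pf = params$k_T / params$n_pf,
         conc = conc),
    class = "derived_rates")
}

#' @export
print.derived_rates <- function(x, ...) {
  cat(sprintf("At %g uM tubulin:\n", x$conc))
  cat(sprintf("  r    = %g s^-1 (microtubule association rate)\n", x$r))
  cat(sprintf("  r_pf = %g s^-1 (per-protofilament association rate)\n", x$r_pf))
  cat(sprintf("  k_pf = %g s^-1 (per-protofilament GTP off-rate)\n", x$k_pf))
  invisible(x)
}

#' Critical concentration
#'
#' The dissociation constant `k_off / k_on`, i.e. the free-tubulin
#' concentration above which there is net polymer growth.
#'
#' @param k_off dissociation rate constant (s^-1).
#' @param k_on association rate constant (uM^-1 s^-1), strictly positive.
#' @return Critical concentration (uM).
#' @examples
#' critical_concentration(0.1, 3.2)   # GTP-tubulin, ~0.03 uM
#' critical_concentration(290, 3.2)   # GDP-tubulin, ~90 uM
#' @export
critical_concentration <- function(k_off, k_on) {
  stopifnot(is.numeric(k_off), is.numeric(k_on))
  if (any(is.na(k_on)) || any(k_on <= 0)) stop("'k_on' must be > 0")
  if (any(is.na(k_off)) || any(k_off < 0)) stop("'k_off' must be >= 0")
  k_off / k_on
}

#' GTP-tubulin decay length
#'
#' Depth (in dimers) over which the GTP-tubulin fraction behind a growing tip
#' decays e-fold: a subunit at depth d has age d / (v / a) where a is the
#' layer spacing, so the GTP fraction is exp(-h d a / v) and the e-fold depth
#' is (v / a) / h.
#'
#' @param v_growth tip growth velocity (nm s^-1).
#' @param h hydrolysis rate constant (s^-1), strictly positive.
#' @param layer_spacing lattice spacing per dimer layer (nm), default 8.
#' @return Decay length in dimers.
#' @examples
#' gtp_decay_length(160, 0.2)  # 100 dimers, typical in-cell growth
#' @export
gtp_decay_length <- function(v_growth, h, layer_spacing = 8) {
  stopifnot(is.numeric(v_growth), is.numeric(h), is.numeric(layer_spacing))
  if (any(is.na(v_growth)) || any(v_growth < 0)) stop("'v_growth' must be >= 0")
  if (any(is.na(h)) || any(h <= 0))
    stop("'h' must be > 0 (h = 0 means the GTP region never decays: ",
         "the decay length is infinite, not a number)")
  (v_growth / layer_spacing) / h
}

#' Poisson raggedness of the microtubule end
#'
#' If each protofilament grows as an independent Poisson process, protofilament
#' lengths at a given time are Poisson-distributed, so the standard deviation
#' of protofilament length is the square root of the mean.
#'
#' @param mean_length mean protofilament length (dimers), non-negative.
#' @param dimer_length dimer length (nm), default 8.
#' @return List with `sd_dimers` and `sd_nm`.
#' @examples
#' poisson_length_sd(1000)  # ~31.6 dimers, ~253 nm
#' @export
poisson_length_sd <- function(mean_length, dimer_length = 8) {
  stopifnot(is.numeric(mean_length), length(mean_length) == 1L)
  if (is.na(mean_length) || mean_length < 0) stop("'mean_length' must be >= 0")
  sd_dimers <- sqrt(mean_length)
  list(sd_dimers = sd_dimers, sd_nm = sd_dimers * dimer_length)
}

#' Lattice spacing per added subunit
#'
#' The two standard mappings of a 13-protofilament microtubule onto linear
#' filament models: viewed as one helically growing filament, each added
#' subunit advances the tip by 8/13 nm (~0.6 nm); viewed as 13 independent
#' protofilaments, each added subunit advances its protofilament by 8 nm.
#'
#' @param mapping `"per_protofilament"` (8 nm) or `"helical"` (8/13 nm).
#' @return Subunit spacing in nm.
#' @export
subunit_spacing_nm <- function(mapping = c("per_protofilament", "helical")) {
  mapping <- match.arg(mapping)
  if (mapping == "helical") 8 / 13 else 8
}

#' Read / write kinetic parameters as flat JSON
#'
#' Serializes a [rate_params] object to the flat JSON schema
#' `{"k_on":3.2,"k_T":0.1,"k_D":290,"h":0.12,"n_pf":13}` (plus
#' `"k_D_infinite"` when set) and back.
#'
#' @param params a [rate_params] object.
#' @param path file path.
#' @return `read_params_json` returns a [rate_params]; `write_params_json`
#'   returns `path` invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "rate_params"))
  x <- unclass(params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path)
  need <- c("k_on", "k_T")
  if (!all(need %in% names(x)))
    stop("parameter JSON must contain at least fields: ", paste(need, collapse = ", "))
  num <- function(v, default) if (is.null(v)) default else as.numeric(v)
  rate_params(k_on = num(x$k_on, NA), k_T = num(x$k_T, NA),
              k_D = num(x$k_D, 290), h = num(x$h, NA_real_),
              n_pf = if (is.null(x$n_pf)) 13L else as.integer(x$n_pf),
              k_D_infinite = isTRUE(as.logical(x$k_D_infinite)))
}
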
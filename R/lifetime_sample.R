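#' A sample of single-microtubule lifetimes
#'
#' Tidy container for observed or simulated catastrophe times: a data frame
#' with columns `lifetime_s` (positive), `censored` (logical; `TRUE` rows
#' carry the last observed time, not a catastrophe) and `concentration_uM`
#' (metadata, may be `NA`). A free-text `source` attribute records provenance.
#'
#' @param lifetimes positive times (s).
#' @param censored logical, recycled.
#' @param concentration tubulin concentration label (uM), recycled.
#' @param source free-text provenance.
#' @return Data frame of class `lifetime_sample`.
#' @export
lifetime_sample <- function(lifetimes, censored = FALSE,
                            concentration = NA_real_, source = "") {
  stopifnot(is.numeric(lifetimes))
  if (any(is.na(lifetimes)) || any(lifetimes <= 0))
    stop("lifetimes must be positive")
  n <- length(lifetimes)
  out <- data.frame(lifetime_s = as.numeric(lifetimes),
                    censored = rep_len(as.logical(censored), n),
                    concentration_uM = rep_len(as.numeric(concentration), n))
  attr(out, "source") <- source
  class(out) <- c("lifetime_sample", "data.frame")
  out
}

#' @export
print.lifetime_sample <- function(x, ...) {
  nc <- sum(x$censored)
  cat(sprintf("Lifetime sample: %d records (%d censored)%s\n",
              nrow(x), nc,
              if (nzchar(attr(x, "source") %||% "")) paste0(" [", attr(x, "source"), "]")
              else ""))
  obs <- x$lifetime_s[!x$censored]
  if (length(obs))
    cat(sprintf("  observed lifetimes: mean %.4g s, median %.4g s, range [%.4g, %.4g]\n",
                mean(obs), stats::median(obs), min(obs), max(obs)))
  if (length(unique(x$concentration_uM)) > 1L)
    cat("  concentrations (uM): ",
        paste(sort(unique(x$concentration_uM)), collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
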
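#' Read and write lifetime CSV files
#'
#' The lifetime CSV schema is UTF-8, comma-separated, decimal point, header
#' `concentration_uM,lifetime_s,censored`. Leading lines starting with `#`
#' are a provenance header (parameters, seed) and are skipped on read but
#' parsed into the `"header"` attribute. Unknown extra columns are accepted
#' and preserved. `write_lifetime_csv` writes values at full precision so a
#' write/read round trip is exact.
#'
#' @param path file path.
#' @param sample a [lifetime_sample] (extra columns allowed).
#' @param header named character vector/list written as `# key: value` lines
#'   (a `source` entry is added from the sample automatically).
#' @return `read_lifetime_csv`: a [lifetime_sample] (extra columns preserved;
#'   provenance lines in `attr(, "header")`). `write_lifetime_csv`: `path`,
#'   invisibly.
#' @export
read_lifetime_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty file: ", path)
  is_comment <- grepl("^#", lines)
  n_skip <- match(FALSE, is_comment) - 1L
  if (is.na(n_skip)) stop("no data rows in ", path)
  body <- lines[!seq_along(lines) %in% seq_len(n_skip)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("concentration_uM", "lifetime_s", "censored")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  # physical file line = data row + header row + skipped comment lines
  file_line <- function(i) i + 1L + n_skip
  bad <- which(is.na(df$lifetime_s) | df$lifetime_s <= 0)
  if (length(bad))
    stop("non-positive or missing lifetime_s on line(s) ",
         paste(file_line(bad), collapse = ", "))
  cens <- df$censored
  if (!is.logical(cens)) {
    cens <- tolower(as.character(cens)) %in% c("true", "t", "1", "yes")
  }
  bad_c <- which(is.na(df$censored))
  if (length(bad_c))
    stop("malformed censored flag on line(s) ",
         paste(file_line(bad_c), collapse = ", "))
  out <- lifetime_sample(df$lifetime_s, censored = cens,
                         concentration = df$concentration_uM,
                         source = path)
  extra <- setdiff(names(df), need)
  for (nm in extra) out[[nm]] <- df[[nm]]
  if (n_skip > 0L) {
    hdr <- sub("^#\\s*", "", lines[seq_len(n_skip)])
    attr(out, "header") <- hdr
  }
  out
}

#' @rdname read_lifetime_csv
#' @export
write_lifetime_csv <- function(sample, path, header = NULL) {
  stopifnot(is.data.frame(sample))
  need <- c("concentration_uM", "lifetime_s", "censored")
  if (!all(need %in% names(sample)))
    stop("sample lacks required column(s): ",
         paste(setdiff(need, names(sample)), collapse = ", "))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  hdr <- c(list(package = paste0("mtkinetics ",
                                 as.character(utils::packageVersion("mtkinetics"))),
                source = attr(sample, "source") %||% ""),
           as.list(header))
  for (nm in names(hdr))
    if (nzchar(as.character(hdr[[nm]])))
      writeLines(sprintf("# %s: %s", nm, as.character(hdr[[nm]])), con)
  df <- sample[, c(need, setdiff(names(sample), need)), drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), "NA", sprintf("%.17g", x)))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a trajectory to tidy CSV
#'
#' Writes the per-event record of an `mt_trajectory` with columns
#' `time_s,length_dimers,event,tip_state`, preceded by a provenance header
#' (mechanism, rule, concentration, seed).
#'
#' @param trajectory an `mt_trajectory` from [simulate_protofilament()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "mt_trajectory"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  p <- trajectory$params
  writeLines(sprintf("# %s: %s",
                     c("mechanism", "rule", "mapping", "conc_uM", "seed",
                       "k_on", "k_T", "k_D", "h", "n_pf", "status"),
                     c(trajectory$mechanism, trajectory$rule, trajectory$mapping,
                       trajectory$conc,
                       if (is.null(trajectory$seed)) "NA" else trajectory$seed,
                       p$k_on, p$k_T,
                       if (p$k_D_infinite) "Inf" else p$k_D, p$h, p$n_pf,
                       trajectory$status)), con)
  utils::write.csv(as.data.frame(trajectory), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
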
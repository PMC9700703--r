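#' Round half up
#'
#' Rounds to `digits` decimal places with halves always rounded away from
#' zero, matching the formatting convention of published cohort tables
#' (base R's `round()` rounds halves to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count within a total
#'
#' Computes `100 * count / total` rounded half-up to two decimals, the
#' convention used throughout the cohort summary tables. A zero total
#' yields `NA`.
#'
#' @param count numeric numerator(s).
#' @param total numeric denominator(s).
#' @param digits decimal places (default 2).
#' @return numeric vector of percentages.
#' @export
pct <- function(count, total, digits = 2) {
  out <- ifelse(total > 0, round_half_up(100 * count / total, digits), NA_real_)
  out
}

# Coerce a column to Date, accepting Date or ISO-8601 strings.
as_event_date <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  if (anyNA(d) & !anyNA(x)) {
    stop(sprintf("unparseable %s value(s), expected YYYY-MM-DD: %s",
                 what, paste(utils::head(unique(x[is.na(d)]), 5), collapse = ", ")),
         call. = FALSE)
  }
  d
}

# Require columns in a data.frame, with a stage-qualified error.
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Read a delimited table (TSV by default), never coercing to factors.
read_table_file <- function(path, sep = "\t") {
  utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

write_table_file <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
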
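exclusion_reasons <- c(
  no_fda_approval = "no FDA approval",
  post_cutoff     = "approved after cutoff",
  non_pharma      = "non-pharmaceutical or biological product",
  hiv_only        = "HIV-only indication",
  no_repro_females = "no reproductive-age female participants")

#' Read an annotated candidate-drug table
#'
#' @param path tab-delimited file with columns `name`, `fda_approved`,
#'   `approval_year`, `hiv_only_indication`,
#'   `pharmaceutical_or_biological`,
#'   `trial_includes_reproductive_age_females`.
#' @return validated data.frame.
#' @export
read_candidates <- function(path) {
  df <- read_table_file(path)
  validate_candidates(df)
}

validate_candidates <- function(df) {
  req <- c("name", "fda_approved", "approval_year", "hiv_only_indication",
           "pharmaceutical_or_biological",
           "trial_includes_reproductive_age_females")
  check_columns(df, req, "candidate drugs")
  for (cn in setdiff(req, c("name", "approval_year"))) {
    df[[cn]] <- as.logical(df[[cn]])
    if (anyNA(df[[cn]])) {
      stop(sprintf("candidate record(s) %s: missing field '%s'",
                   paste(df$name[is.na(df[[cn]])], collapse = ", "), cn),
           call. = FALSE)
    }
  }
  df$approval_year <- suppressWarnings(as.integer(df$approval_year))
  bad <- df$fda_approved & is.na(df$approval_year)
  if (any(bad)) {
    stop(sprintf("candidate record(s) %s: approval_year required when FDA approved",
                 paste(df$name[bad], collapse = ", ")), call. = FALSE)
  }
  df
}

#' Apply candidate-drug exclusion rules
#'
#' Rule engine for the screened-medication list: each candidate is tested
#' against the exclusion rules in a fixed documented order and, if
#' excluded, carries exactly the first matching reason —
#' (1) no FDA approval, (2) approved after the cutoff year, (3) not a
#' pharmaceutical or biological product, (4) sole approved indication is
#' HIV treatment, (5) trials without reproductive-age female participants.
#' Kept records preserve input order.
#'
#' @param drugs candidate data.frame (see [read_candidates()]).
#' @param cutoff_year drugs approved strictly after this year are excluded
#'   (default 2017).
#' @return list with `kept` (data.frame) and `excluded` (data.frame with a
#'   `reason` column).
#' @export
apply_exclusions <- function(drugs, cutoff_year = 2017) {
  drugs <- validate_candidates(drugs)
  reason <- rep(NA_character_, nrow(drugs))
  rule <- function(open, hit, label) ifelse(open & hit, label, reason)
  reason <- rule(is.na(reason), !drugs$fda_approved,
                 exclusion_reasons[["no_fda_approval"]])
  reason <- rule(is.na(reason),
                 !is.na(drugs$approval_year) & drugs$approval_year > cutoff_year,
                 exclusion_reasons[["post_cutoff"]])
  reason <- rule(is.na(reason), !drugs$pharmaceutical_or_biological,
                 exclusion_reasons[["non_pharma"]])
  reason <- rule(is.na(reason), drugs$hiv_only_indication,
                 exclusion_reasons[["hiv_only"]])
  reason <- rule(is.na(reason), !drugs$trial_includes_reproductive_age_females,
                 exclusion_reasons[["no_repro_females"]])
  excluded <- drugs[!is.na(reason), , drop = FALSE]
  excluded$reason <- reason[!is.na(reason)]
  rownames(excluded) <- NULL
  kept <- drugs[is.na(reason), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, excluded = excluded)
}

#' Exclusion reason counts
#'
#' @param exclusions an [apply_exclusions()] result.
#' @return data.frame of reasons (in rule order) with counts.
#' @export
exclusion_report <- function(exclusions) {
  counts <- vapply(unname(exclusion_reasons),
                   function(r) sum(exclusions$excluded$reason == r), integer(1))
  data.frame(reason = unname(exclusion_reasons), n = counts,
             stringsAsFactors = FALSE)
}
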
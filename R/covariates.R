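#' Covariate lookback window test
#'
#' A diagnosis qualifies a delivery for a comorbidity flag when it occurred
#' within the 2-year pre-delivery lookback but not on the delivery day
#' itself (delivery-day diagnoses usually describe the delivery, not a
#' pre-existing condition): `delivery - 730 <= diagnosis <= delivery - 1`.
#' The 2 years are implemented as 730 whole days for determinism across
#' leap years.
#'
#' @param diag_date,delivery_date Date vectors (recycled).
#' @param lookback_days lookback length in days (default 730).
#' @return logical vector.
#' @export
in_lookback <- function(diag_date, delivery_date, lookback_days = 730) {
  d <- as.numeric(as.Date(delivery_date) - as.Date(diag_date))
  d >= 1 & d <= lookback_days
}

# Whole years between two dates, floored; 365.25-day years for determinism.
age_in_years <- function(birth_date, at_date) {
  floor(as.numeric(as.Date(at_date) - as.Date(birth_date)) / 365.25)
}

#' Build the covariate adjustment matrix
#'
#' One row per delivery: a 0/1 flag per configured comorbidity code set
#' (1 iff at least one matching diagnosis inside the lookback window) plus
#' `maternal_age` in whole years (floor) at delivery. Absence of a
#' diagnosis yields 0, never a missing value.
#'
#' @param cohort a [build_cohort()] result.
#' @param diagnoses data.frame with columns `patient_id`, `date`, `code`.
#' @param vocab an `icd_vocabulary`; its COVARIATE sets define the flags.
#' @param patients data.frame with `patient_id`, `birth_date`, used for
#'   maternal age.
#' @param lookback_days see [in_lookback()].
#' @param missing_birth_date policy when a patient lacks a birth date:
#'   `"fail"` (default) or `"impute"` cohort mean age with a warning.
#' @return numeric matrix of class `covariate_matrix` (rownames =
#'   delivery_id): one column per covariate plus `maternal_age`.
#' @export
build_covariates <- function(cohort, diagnoses, vocab, patients,
                             lookback_days = 730,
                             missing_birth_date = c("fail", "impute")) {
  missing_birth_date <- match.arg(missing_birth_date)
  stopifnot(inherits(vocab, "icd_vocabulary"))
  check_columns(diagnoses, c("patient_id", "date", "code"), "diagnoses")
  check_columns(patients, c("patient_id", "birth_date"), "patients")
  cov_sets <- vocab_by_role(vocab, "COVARIATE")
  if (length(cov_sets) == 0) {
    stop("vocabulary contains no COVARIATE code sets", call. = FALSE)
  }
  delivery_date <- as_event_date(cohort$delivery_date, "delivery_date")
  birth <- as_event_date(patients$birth_date, "birth_date")
  bidx <- match(cohort$patient_id, patients$patient_id)
  if (anyNA(bidx)) {
    stop("cohort references patient(s) absent from the patients table",
         call. = FALSE)
  }
  age <- age_in_years(birth[bidx], delivery_date)
  if (anyNA(age)) {
    if (missing_birth_date == "fail") {
      stop(sprintf("missing birth_date for patient(s): %s",
                   paste(utils::head(unique(cohort$patient_id[is.na(age)]), 10),
                         collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("imputed cohort mean age for %d deliveries lacking birth_date",
                    sum(is.na(age))), call. = FALSE)
    age[is.na(age)] <- round(mean(age, na.rm = TRUE))
  }

  out <- matrix(0L, nrow(cohort), length(cov_sets) + 1,
                dimnames = list(cohort$delivery_id,
                                c(vapply(cov_sets, `[[`, character(1), "name"),
                                  "maternal_age")))
  if (nrow(diagnoses) > 0) {
    diagnoses$date <- as_event_date(diagnoses$date, "diagnosis date")
    norm <- normalize_icd(diagnoses$code)$normalized
    dl <- data.frame(row = seq_len(nrow(cohort)),
                     patient_id = cohort$patient_id,
                     delivery_date = delivery_date)
    for (cs in cov_sets) {
      hit <- code_matches(norm, cs)
      if (!any(hit)) next
      j <- merge(dl, data.frame(patient_id = diagnoses$patient_id[hit],
                                date = diagnoses$date[hit]),
                 by = "patient_id")
      j <- j[in_lookback(j$date, j$delivery_date, lookback_days), , drop = FALSE]
      out[unique(j$row), cs$name] <- 1L
    }
  }
  out[, "maternal_age"] <- age
  class(out) <- c("covariate_matrix", class(out))
  out
}
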
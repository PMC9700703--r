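#' Assemble the delivery cohort with outcome flags
#'
#' Builds one delivery event per input delivery and derives binary outcome
#' flags (cesarean section, preterm birth, stillbirth) from diagnosis codes
#' dated ON the delivery date: a flag is 1 iff at least one diagnosis record
#' for that patient, dated exactly on the delivery date (or within
#' `outcome_window_days` of it), matches the outcome's code set. Duplicate
#' `(patient_id, delivery_date)` rows are collapsed to a single delivery
#' with a warning (a same-day multiple birth is one delivery event).
#'
#' @param deliveries data.frame with columns `patient_id`, `delivery_id`,
#'   `delivery_date`.
#' @param diagnoses data.frame with columns `patient_id`, `date`, `code`.
#' @param vocab an `icd_vocabulary`; its OUTCOME sets define the flags.
#' @param patients optional data.frame with `patient_id`; when supplied,
#'   deliveries referencing unknown patients raise a validation error
#'   listing the offenders.
#' @param outcome_window_days days before delivery a diagnosis may fall and
#'   still count as an outcome code; default 0 (delivery day only).
#' @return data.frame of class `delivery_cohort`: `patient_id`,
#'   `delivery_id`, `delivery_date`, plus one 0/1 column per outcome set.
#' @export
build_cohort <- function(deliveries, diagnoses, vocab, patients = NULL,
                         outcome_window_days = 0) {
  check_columns(deliveries, c("patient_id", "delivery_id", "delivery_date"),
                "deliveries")
  check_columns(diagnoses, c("patient_id", "date", "code"), "diagnoses")
  stopifnot(inherits(vocab, "icd_vocabulary"))
  outcome_sets <- vocab_by_role(vocab, "OUTCOME")
  if (length(outcome_sets) == 0) {
    stop("vocabulary contains no OUTCOME code sets", call. = FALSE)
  }
  deliveries$delivery_date <- as_event_date(deliveries$delivery_date,
                                            "delivery_date")
  diagnoses$date <- as_event_date(diagnoses$date, "diagnosis date")

  if (!is.null(patients)) {
    check_columns(patients, "patient_id", "patients")
    unknown <- setdiff(deliveries$patient_id, patients$patient_id)
    if (length(unknown) > 0) {
      stop(sprintf("deliveries reference unknown patient(s): %s",
                   paste(utils::head(unknown, 10), collapse = ", ")),
           call. = FALSE)
    }
  }

  key <- paste(deliveries$patient_id, deliveries$delivery_date)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    warning(sprintf(
      "collapsed %d duplicate same-day delivery row(s) to one event each",
      sum(duplicated(key))), call. = FALSE)
    deliveries <- deliveries[!duplicated(key), , drop = FALSE]
    key <- key[!duplicated(key)]
  }

  cohort <- deliveries[, c("patient_id", "delivery_id", "delivery_date")]
  norm <- if (nrow(diagnoses) > 0) normalize_icd(diagnoses$code)$normalized
          else character(0)
  for (cs in outcome_sets) {
    hit <- code_matches(norm, cs)
    dkey <- paste(diagnoses$patient_id[hit], diagnoses$date[hit])
    if (outcome_window_days > 0) {
      sub <- diagnoses[hit, , drop = FALSE]
      dkey <- unlist(lapply(0:outcome_window_days, function(w)
        paste(sub$patient_id, sub$date + w)))
    }
    cohort[[cs$name]] <- as.integer(
      paste(cohort$patient_id, cohort$delivery_date) %in% dkey)
  }
  class(cohort) <- c("delivery_cohort", "data.frame")
  cohort
}

#' Cohort summary stratified by medication exposure
#'
#' Counts and percentages of each outcome (and, optionally, each
#' comorbidity flag) overall and stratified by any-candidate-medication
#' exposure, mirroring the layout of a cohort characteristics table.
#' Percentages are `100 * count / stratum_total` rounded half-up to two
#' decimals. Counts below the suppression threshold are masked in the
#' rendered form (see [render_summary()]).
#'
#' @param cohort a [build_cohort()] result.
#' @param exposed 0/1 vector, one element per cohort row: any-candidate
#'   exposure.
#' @param covariates optional [build_covariates()] result aligned with the
#'   cohort; adds one row per comorbidity flag and a mean-age row.
#' @return data.frame of class `cohort_summary` with numeric columns
#'   `n_unexposed`, `pct_unexposed`, `n_exposed`, `pct_exposed`, `n_total`,
#'   `pct_total`; attribute `totals` holds the stratum sizes and
#'   `age` the stratified mean/SD of maternal age when available.
#' @export
summarize_cohort <- function(cohort, exposed, covariates = NULL) {
  stopifnot(length(exposed) == nrow(cohort), all(exposed %in% c(0, 1)))
  exposed <- as.integer(exposed)
  outcome_cols <- setdiff(names(cohort),
                          c("patient_id", "delivery_id", "delivery_date"))
  rows <- lapply(outcome_cols, function(cn) {
    summary_row(cn, "outcome", cohort[[cn]], exposed)
  })
  age <- NULL
  if (!is.null(covariates)) {
    flag_cols <- setdiff(colnames(covariates), "maternal_age")
    rows <- c(rows, lapply(flag_cols, function(cn) {
      summary_row(cn, "comorbidity", covariates[, cn], exposed)
    }))
    if ("maternal_age" %in% colnames(covariates)) {
      a <- covariates[, "maternal_age"]
      age <- data.frame(
        stratum = c("unexposed", "exposed", "total"),
        mean = round_half_up(c(mean(a[exposed == 0]), mean(a[exposed == 1]),
                               mean(a)), 2),
        sd = round_half_up(c(stats::sd(a[exposed == 0]), stats::sd(a[exposed == 1]),
                             stats::sd(a)), 2))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "totals") <- c(unexposed = sum(exposed == 0),
                           exposed = sum(exposed == 1),
                           total = length(exposed))
  attr(out, "age") <- age
  class(out) <- c("cohort_summary", "data.frame")
  out
}

summary_row <- function(label, group, flag, exposed) {
  flag <- as.integer(flag)
  n_un <- sum(flag[exposed == 0])
  n_ex <- sum(flag[exposed == 1])
  data.frame(group = group, label = label,
             n_unexposed = n_un, pct_unexposed = pct(n_un, sum(exposed == 0)),
             n_exposed = n_ex, pct_exposed = pct(n_ex, sum(exposed == 1)),
             n_total = n_un + n_ex, pct_total = pct(n_un + n_ex, length(exposed)),
             stringsAsFactors = FALSE)
}
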
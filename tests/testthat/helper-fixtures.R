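# Small in-code fixtures shared across tests.

toy_vocab <- function() {
  structure(list(
    cesarean = codeset("cesarean", "OUTCOME", members = "O82",
                       prefix_members = "669.7"),
    preterm = codeset("preterm", "OUTCOME", members = "O60.10",
                      prefix_members = c("O60.1", "644.2")),
    stillbirth = codeset("stillbirth", "OUTCOME",
                         members = c("Z37.1", "Z37.4"),
                         prefix_members = "656.4"),
    preeclampsia = codeset("preeclampsia", "COVARIATE", members = "O14.1",
                           prefix_members = c("O14", "642.4")),
    cancer = codeset("cancer", "COVARIATE", members = "C80.1",
                     prefix_members = "199")),
    class = "icd_vocabulary")
}

toy_patients <- function() {
  data.frame(patient_id = c("P1", "P2", "P3"),
             birth_date = as.Date(c("1985-03-10", "1990-07-01", "1980-01-20")),
             stringsAsFactors = FALSE)
}

toy_deliveries <- function() {
  data.frame(patient_id = c("P1", "P2", "P3"),
             delivery_id = c("D1", "D2", "D3"),
             delivery_date = as.Date(c("2015-06-01", "2016-02-15", "2014-11-30")),
             stringsAsFactors = FALSE)
}

# A null-model calibration configuration: single delivery per patient,
# confounding on, all planted effects zero, 2% baseline exposure per
# medication so every medication x outcome test carries adequate
# information (see the methods vignette for the design rationale).
null_calibration_config <- function(seed, n = 20000) {
  base <- default_sim_config(seed = seed)
  sim_config(
    n_patients = n, seed = seed,
    deliveries_per_patient_dist = c("1" = 1),
    medication_base_exposure_prob =
      stats::setNames(rep(0.02, 10), names(default_medication_exposure())),
    covariate_outcome_log_odds = base$covariate_outcome_log_odds,
    covariate_exposure_log_odds = base$covariate_exposure_log_odds)
}

# Run the downstream pipeline stages on a simulated cohort and screen it.
screen_simulated <- function(co, min_patients = 10) {
  vocab <- co$config$vocabulary
  ch <- build_cohort(co$deliveries, co$diagnoses, vocab, co$patients)
  ex <- suppressMessages(apply_min_patient_filter(
    build_exposures(co$orders, ch, default_drug_map()), min_patients))
  cv <- build_covariates(ch, co$diagnoses, vocab, co$patients)
  spec <- screen_spec(names(co$config$outcome_base_prevalence),
                      colnames(ex$matrix),
                      setdiff(colnames(cv), "maternal_age"))
  run_screen(spec, ex, cv, ch)
}
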
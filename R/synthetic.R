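#' @name synthetic-ehr
#' @title Synthetic obstetric EHR generator
#'
#' @description
#' Generates the four EHR-style event tables the screening pipeline
#' consumes — patients, deliveries, medication orders, diagnoses — from an
#' explicit generative model that mirrors the analysis model: per delivery,
#' comorbidity covariates are Bernoulli draws at configured prevalences,
#' each medication exposure is Bernoulli on the logit scale with
#' covariate-driven confounding, and each outcome is Bernoulli on the logit
#' scale with covariate effects plus planted medication log odds ratios.
#' Exposed medications emit 1-3 dated orders inside the 280-day pre-delivery
#' window; covariate flags emit diagnoses dated before delivery; outcome
#' flags emit delivery-day diagnoses coded with the bundled toy ICD
#' vocabulary. Protected real-world data never enters the package: every
#' downstream stage is exercised against this generator.
NULL

# Deterministic per-stage seed derived from the master seed, kept < 2^31.
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + k) %% 2147483647L)
}

#' Default comorbidity prevalences
#'
#' Marginal prevalences for the sixteen default adjustment comorbidities,
#' taken from the totals column of the source cohort's summary table
#' (63,334 deliveries). Two cells (`cerebrovascular`, `drug_resistance`)
#' are suppressed/absent in that table; their defaults are set to 5/63,334
#' and should be treated as guesses.
#'
#' @return named numeric vector of prevalences.
#' @export
default_covariate_prevalence <- function() {
  n <- 63334
  c(infectious_disease = 1255 / n,
    obesity            = 1101 / n,
    cancer             = 397 / n,
    cardiovascular     = 613 / n,
    circulatory        = 47 / n,
    cerebrovascular    = 5 / n,     # masked cell; guess
    respiratory        = 172 / n,
    immune_disorders   = 45 / n,
    organ_transplant   = 38 / n,
    obstetric_history  = 182 / n,
    maternal_care      = 264 / n,
    preeclampsia       = 5071 / n,
    multiple_birth     = 1562 / n,
    drug_allergies     = 310 / n,
    procedures         = 218 / n,
    drug_resistance    = 5 / n)     # not tabulated; guess
}

#' Default candidate medications with brand/generic aliases
#'
#' Ten candidate medications with their raw order-name spellings
#' (generic plus brand equivalents) used by the generator and the bundled
#' drug map.
#'
#' @return named list: medication variable -> character vector of raw names.
#' @export
default_drug_aliases <- function() {
  list(oseltamivir        = c("oseltamivir", "Tamiflu"),
       hydroxychloroquine = c("hydroxychloroquine", "Plaquenil"),
       azithromycin       = c("azithromycin", "Zithromax"),
       amoxicillin        = c("amoxicillin", "Amoxil"),
       famotidine         = c("famotidine", "Pepcid"),
       methylprednisolone = c("methylprednisolone", "Medrol"),
       heparin            = "heparin",
       enoxaparin         = c("enoxaparin", "Lovenox"),
       aspirin            = "aspirin",
       ibuprofen          = c("ibuprofen", "Advil", "Motrin"))
}

#' Default per-medication baseline exposure probabilities
#'
#' Base exposure 0.0045 per medication gives ~4.4% any-candidate exposure
#' across the ten defaults, matching the source cohort's 4.47%.
#'
#' @return named numeric vector of probabilities.
#' @export
default_medication_exposure <- function() {
  meds <- names(default_drug_aliases())
  stats::setNames(rep(0.0045, length(meds)), meds)
}

#' Build an effect matrix from sparse triples
#'
#' Convenience constructor for the log odds ratio matrices of
#' [sim_config()]: a zero `rows x cols` matrix with the listed
#' `(row, col, value)` triples filled in.
#'
#' @param rows,cols dimension names (e.g. covariates and outcomes).
#' @param entries list of 3-element lists: row name, col name, log odds
#'   ratio.
#' @return numeric matrix with `dimnames = list(rows, cols)`.
#' @export
effect_matrix <- function(rows, cols, entries = list()) {
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  for (e in entries) {
    if (!(e[[1]] %in% rows) || !(e[[2]] %in% cols)) {
      stop(sprintf("effect entry (%s, %s) names an unknown variable",
                   e[[1]], e[[2]]), call. = FALSE)
    }
    m[e[[1]], e[[2]]] <- as.numeric(e[[3]])
  }
  m
}

#' Construct a simulation configuration
#'
#' All probabilities must lie in `[0, 1]`; the seed fully determines the
#' generated cohort. Effect matrices default to zero (no confounding, no
#' planted effects); see [default_sim_config()] for the configured study
#' conditions.
#'
#' @param n_patients number of patients.
#' @param deliveries_per_patient_dist named probabilities over 1, 2, 3
#'   deliveries per patient.
#' @param outcome_base_prevalence named baseline outcome probabilities.
#' @param covariate_prevalence named comorbidity prevalences.
#' @param covariate_outcome_log_odds covariate-by-outcome matrix of log
#'   odds ratios (confounder-outcome effects).
#' @param covariate_exposure_log_odds covariate-by-medication matrix of log
#'   odds ratios (confounder-exposure effects).
#' @param medication_base_exposure_prob named baseline exposure
#'   probabilities per medication.
#' @param planted_log_or medication-by-outcome matrix of true exposure log
#'   odds ratios.
#' @param age_log_odds per-outcome log odds ratio per year of maternal age
#'   (centered at the configured mean); default 0.
#' @param maternal_age_mean_sd mean and SD of maternal age in years; draws
#'   are truncated to [12, 55].
#' @param seed integer master seed.
#' @param date_range earliest and latest delivery date.
#' @param old_diagnosis_fraction fraction of covariate diagnoses dated in
#'   the 731-1095 day pre-delivery band (outside the 2-year lookback), to
#'   exercise lookback truncation; default 0 so the generative covariates
#'   equal the recoverable ones.
#' @param patient_intercept_sd SD of an optional patient-level random
#'   intercept on the outcome logit; default 0 (deliveries independent, as
#'   in the analysis model).
#' @param drug_aliases named list mapping each medication variable to its
#'   raw order-name spellings (generic + brands).
#' @param vocabulary an `icd_vocabulary` providing one OUTCOME set per
#'   outcome and one COVARIATE set per covariate; defaults to the bundled
#'   toy vocabulary.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000,
                       deliveries_per_patient_dist = c("1" = 0.78, "2" = 0.19, "3" = 0.03),
                       outcome_base_prevalence = c(cesarean = 0.3299,
                                                   preterm = 0.0615,
                                                   stillbirth = 0.0081),
                       covariate_prevalence = default_covariate_prevalence(),
                       covariate_outcome_log_odds = NULL,
                       covariate_exposure_log_odds = NULL,
                       medication_base_exposure_prob = default_medication_exposure(),
                       planted_log_or = NULL,
                       age_log_odds = NULL,
                       maternal_age_mean_sd = c(29.48, 6.08),
                       seed = 1L,
                       date_range = as.Date(c("2010-01-01", "2017-12-31")),
                       old_diagnosis_fraction = 0,
                       patient_intercept_sd = 0,
                       drug_aliases = default_drug_aliases(),
                       vocabulary = NULL) {
  covs <- names(covariate_prevalence)
  meds <- names(medication_base_exposure_prob)
  outs <- names(outcome_base_prevalence)
  if (is.null(covariate_outcome_log_odds)) {
    covariate_outcome_log_odds <- effect_matrix(covs, outs)
  }
  if (is.null(covariate_exposure_log_odds)) {
    covariate_exposure_log_odds <- effect_matrix(covs, meds)
  }
  if (is.null(planted_log_or)) planted_log_or <- effect_matrix(meds, outs)
  if (is.null(age_log_odds)) age_log_odds <- stats::setNames(rep(0, length(outs)), outs)
  if (is.null(vocabulary)) vocabulary <- default_vocabulary()
  cfg <- structure(list(
    n_patients = n_patients,
    deliveries_per_patient_dist = deliveries_per_patient_dist,
    outcome_base_prevalence = outcome_base_prevalence,
    covariate_prevalence = covariate_prevalence,
    covariate_outcome_log_odds = covariate_outcome_log_odds,
    covariate_exposure_log_odds = covariate_exposure_log_odds,
    medication_base_exposure_prob = medication_base_exposure_prob,
    planted_log_or = planted_log_or,
    age_log_odds = age_log_odds,
    maternal_age_mean_sd = maternal_age_mean_sd,
    seed = as.integer(seed),
    date_range = as.Date(date_range),
    old_diagnosis_fraction = old_diagnosis_fraction,
    patient_intercept_sd = patient_intercept_sd,
    drug_aliases = drug_aliases,
    vocabulary = vocabulary), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks probability ranges, distribution normalization, name alignment of
#' the effect matrices, and vocabulary coverage before any generation.
#'
#' @param cfg a [sim_config()].
#' @return `cfg`, invisibly; errors on the first violated constraint.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk_prob <- function(p, what) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
      stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
    }
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 0) {
    stop("n_patients must be >= 0", call. = FALSE)
  }
  d <- cfg$deliveries_per_patient_dist
  chk_prob(d, "deliveries_per_patient_dist")
  if (abs(sum(d) - 1) > 1e-8) {
    stop("deliveries_per_patient_dist must sum to 1", call. = FALSE)
  }
  if (!all(names(d) %in% c("1", "2", "3"))) {
    stop("deliveries_per_patient_dist supports 1-3 deliveries per patient",
         call. = FALSE)
  }
  chk_prob(cfg$outcome_base_prevalence, "outcome_base_prevalence")
  chk_prob(cfg$covariate_prevalence, "covariate_prevalence")
  chk_prob(cfg$medication_base_exposure_prob, "medication_base_exposure_prob")
  chk_prob(cfg$old_diagnosis_fraction, "old_diagnosis_fraction")
  covs <- names(cfg$covariate_prevalence)
  meds <- names(cfg$medication_base_exposure_prob)
  outs <- names(cfg$outcome_base_prevalence)
  if (!identical(dimnames(cfg$covariate_outcome_log_odds), list(covs, outs))) {
    stop("covariate_outcome_log_odds must be a covariate x outcome matrix",
         call. = FALSE)
  }
  if (!identical(dimnames(cfg$covariate_exposure_log_odds), list(covs, meds))) {
    stop("covariate_exposure_log_odds must be a covariate x medication matrix",
         call. = FALSE)
  }
  if (!identical(dimnames(cfg$planted_log_or), list(meds, outs))) {
    stop("planted_log_or must be a medication x outcome matrix", call. = FALSE)
  }
  if (!identical(names(cfg$age_log_odds), outs)) {
    stop("age_log_odds must be named by outcome", call. = FALSE)
  }
  if (!all(meds %in% names(cfg$drug_aliases))) {
    stop("every medication needs drug_aliases entries", call. = FALSE)
  }
  if (cfg$maternal_age_mean_sd[2] <= 0) {
    stop("maternal age SD must be positive", call. = FALSE)
  }
  vnames <- names(cfg$vocabulary)
  if (!all(outs %in% vnames) || !all(covs %in% vnames)) {
    stop("vocabulary must contain a code set per outcome and per covariate",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Default study-condition configuration
#'
#' The configuration the package treats as its reference cohort: outcome
#' prevalences 32.99% / 6.15% / 0.81% (cesarean / preterm / stillbirth),
#' the sixteen default comorbidity prevalences of
#' [default_covariate_prevalence()], maternal age 29.48 +/- 6.08 years, ten
#' candidate medications at ~4.4% combined exposure, and a moderate
#' clinically-oriented confounding structure (preeclampsia raises both
#' anticoagulant exposure and all three outcomes; infection raises
#' antibiotic exposure and preterm birth; obesity raises famotidine
#' exposure, cesarean and stillbirth; multiple birth raises cesarean and
#' preterm). All planted medication effects are zero.
#'
#' @param n_patients number of patients (default 10,000).
#' @param seed master seed.
#' @return a validated [sim_config()].
#' @export
default_sim_config <- function(n_patients = 10000, seed = 1L) {
  covs <- names(default_covariate_prevalence())
  meds <- names(default_medication_exposure())
  outs <- c("cesarean", "preterm", "stillbirth")
  cov_out <- effect_matrix(covs, outs, list(
    list("preeclampsia", "cesarean", log(1.6)),
    list("preeclampsia", "preterm", log(2.5)),
    list("preeclampsia", "stillbirth", log(2.0)),
    list("multiple_birth", "cesarean", log(3.0)),
    list("multiple_birth", "preterm", log(3.0)),
    list("obesity", "cesarean", log(1.5)),
    list("obesity", "stillbirth", log(1.5)),
    list("infectious_disease", "preterm", log(1.5))))
  cov_exp <- effect_matrix(covs, meds, list(
    list("preeclampsia", "heparin", log(2.0)),
    list("preeclampsia", "enoxaparin", log(2.0)),
    list("preeclampsia", "aspirin", log(2.0)),
    list("infectious_disease", "azithromycin", log(2.0)),
    list("infectious_disease", "amoxicillin", log(2.0)),
    list("obesity", "famotidine", log(1.5))))
  sim_config(n_patients = n_patients, seed = seed,
             covariate_outcome_log_odds = cov_out,
             covariate_exposure_log_odds = cov_exp)
}

# Representative code a set emits in generated diagnoses: first exact
# member, else first prefix (a code equal to its prefix matches it).
emit_code <- function(cs) {
  if (length(cs$members) > 0) cs$members[1] else cs$prefix_members[1]
}

empty_cohort <- function(cfg) {
  structure(list(
    patients = data.frame(patient_id = character(),
                          birth_date = as.Date(character())),
    deliveries = data.frame(patient_id = character(), delivery_id = character(),
                            delivery_date = as.Date(character())),
    orders = data.frame(patient_id = character(),
                        order_date = as.Date(character()),
                        drug_name = character(), ingredient = character()),
    diagnoses = data.frame(patient_id = character(),
                           date = as.Date(character()), code = character()),
    latent = data.frame(delivery_id = character()),
    truth = cfg$planted_log_or,
    config = cfg), class = "simulated_cohort")
}

# Exactly round(p * n) ones placed at seeded-random positions.
exact_flags <- function(n, p) {
  k <- round(p * n)
  f <- integer(n)
  if (k > 0) f[sample.int(n, k)] <- 1L
  f
}

# Integer age vector whose mean rounds (half-up, 2 dp) to the target mean.
exact_margin_ages <- function(n, mean_age, sd_age) {
  if (n == 1) return(round(mean_age))
  z <- stats::rnorm(n)
  z <- (z - mean(z)) / stats::sd(z)
  age <- pmin(pmax(round(mean_age + sd_age * z), 12L), 55L)
  target <- round(mean_age * n)
  delta <- target - sum(age)
  while (delta != 0) {
    step <- sign(delta)
    elig <- if (step > 0) which(age < 55L) else which(age > 12L)
    idx <- sample(elig, min(abs(delta), length(elig)))
    age[idx] <- age[idx] + step
    delta <- target - sum(age)
  }
  age
}

#' Simulate a cohort of EHR event tables
#'
#' Draws the full generative model of [sim_config()] and materializes it as
#' patients, deliveries, medication orders and diagnoses tables, plus a
#' `latent` per-delivery table of the true covariate, exposure and outcome
#' indicators (for test assertions) and the planted effect matrix as
#' `truth`. Identical configurations produce identical output.
#'
#' With `exact_margins = TRUE` the generator runs in fixture mode: one
#' delivery per patient, every outcome and covariate flag assigned to
#' exactly `round(prevalence * n)` deliveries, integer ages whose mean
#' reproduces the configured mean at two decimals, and no effect terms.
#' This mode exists to reproduce printed cohort margins exactly and makes
#' no generative claim.
#'
#' @param cfg a validated [sim_config()].
#' @param exact_margins logical; fixture mode (see above).
#' @return object of class `simulated_cohort`: list with elements
#'   `patients`, `deliveries`, `orders`, `diagnoses`, `latent`, `truth`,
#'   `config`.
#' @export
simulate_cohort <- function(cfg, exact_margins = FALSE) {
  validate_sim_config(cfg)
  if (cfg$n_patients == 0) return(empty_cohort(cfg))

  covs <- names(cfg$covariate_prevalence)
  meds <- names(cfg$medication_base_exposure_prob)
  outs <- names(cfg$outcome_base_prevalence)
  npat <- cfg$n_patients
  start <- cfg$date_range[1]
  end <- cfg$date_range[2]
  span <- as.integer(end - start)

  # stage 1: deliveries per patient
  set.seed(stage_seed(cfg$seed, 1))
  sizes <- as.integer(names(cfg$deliveries_per_patient_dist))
  k <- if (exact_margins) rep(1L, npat) else
    sample(sizes, npat, replace = TRUE, prob = cfg$deliveries_per_patient_dist)
  nd <- sum(k)
  pat_of <- rep(seq_len(npat), k)
  patient_id <- sprintf("P%06d", seq_len(npat))
  delivery_id <- sprintf("D%07d", seq_len(nd))

  # stage 2: delivery dates; later deliveries spaced 300-600 days apart so
  # exposure windows of one patient's deliveries never overlap
  set.seed(stage_seed(cfg$seed, 2))
  reserve <- 620L * (k - 1L)
  first_span <- pmax(span - reserve, 1L)
  first_date <- start + floor(stats::runif(npat) * first_span)
  seq_in_pat <- sequence(k)
  gaps <- 300L + floor(stats::runif(nd) * 300)
  gaps[seq_in_pat == 1] <- 0L
  offset <- stats::ave(gaps, pat_of, FUN = cumsum)
  delivery_date <- pmin(first_date[pat_of] + offset, end)

  # stage 3: maternal age and covariate flags
  set.seed(stage_seed(cfg$seed, 3))
  m_age <- cfg$maternal_age_mean_sd[1]
  s_age <- cfg$maternal_age_mean_sd[2]
  if (exact_margins) {
    age_first <- exact_margin_ages(npat, m_age, s_age)
    birth_date <- first_date - round((age_first + 0.5) * 365.25)
  } else {
    plo <- stats::pnorm((12 - m_age) / s_age)
    phi <- stats::pnorm((55 - m_age) / s_age)
    age_first <- m_age + s_age * stats::qnorm(stats::runif(npat, plo, phi))
    birth_date <- first_date - round(age_first * 365.25)
  }
  # integer age at each delivery, same floor rule the covariates stage uses
  age <- floor(as.integer(delivery_date - birth_date[pat_of]) / 365.25)
  if (exact_margins) {
    flags <- vapply(covs, function(cv) exact_flags(nd, cfg$covariate_prevalence[cv]),
                    integer(nd))
  } else {
    flags <- vapply(covs, function(cv)
      as.integer(stats::runif(nd) < cfg$covariate_prevalence[cv]), integer(nd))
  }
  if (nd == 1) flags <- matrix(flags, nrow = 1, dimnames = list(NULL, covs))

  # stage 4: medication exposures
  set.seed(stage_seed(cfg$seed, 4))
  if (exact_margins) {
    expo <- vapply(meds, function(md)
      exact_flags(nd, cfg$medication_base_exposure_prob[md]), integer(nd))
  } else {
    eta <- matrix(stats::qlogis(cfg$medication_base_exposure_prob),
                  nd, length(meds), byrow = TRUE) +
      flags %*% cfg$covariate_exposure_log_odds
    expo <- matrix(as.integer(stats::runif(nd * length(meds)) < stats::plogis(eta)),
                   nd, length(meds))
  }
  if (nd == 1) expo <- matrix(expo, nrow = 1)
  colnames(expo) <- meds

  # stage 5: outcomes
  set.seed(stage_seed(cfg$seed, 5))
  if (exact_margins) {
    out <- vapply(outs, function(o)
      exact_flags(nd, cfg$outcome_base_prevalence[o]), integer(nd))
  } else {
    b <- if (cfg$patient_intercept_sd > 0)
      stats::rnorm(npat, 0, cfg$patient_intercept_sd)[pat_of] else 0
    eta <- matrix(stats::qlogis(cfg$outcome_base_prevalence),
                  nd, length(outs), byrow = TRUE) +
      outer(age - round(m_age), cfg$age_log_odds) +
      flags %*% cfg$covariate_outcome_log_odds +
      expo %*% cfg$planted_log_or + b
    out <- matrix(as.integer(stats::runif(nd * length(outs)) < stats::plogis(eta)),
                  nd, length(outs))
  }
  if (nd == 1) out <- matrix(out, nrow = 1)
  colnames(out) <- outs

  # stage 6: event tables
  set.seed(stage_seed(cfg$seed, 6))
  orders <- make_orders(cfg, expo, pat_of, delivery_date, patient_id, meds)
  diagnoses <- make_diagnoses(cfg, flags, out, pat_of, delivery_date,
                              patient_id, covs, outs, exact_margins)

  latent <- data.frame(delivery_id = delivery_id,
                       patient_id = patient_id[pat_of],
                       delivery_date = delivery_date,
                       maternal_age = age,
                       stringsAsFactors = FALSE)
  latent <- cbind(latent, as.data.frame(flags), as.data.frame(out),
                  as.data.frame(expo))

  structure(list(
    patients = data.frame(patient_id = patient_id, birth_date = birth_date,
                          stringsAsFactors = FALSE),
    deliveries = data.frame(patient_id = patient_id[pat_of],
                            delivery_id = delivery_id,
                            delivery_date = delivery_date,
                            stringsAsFactors = FALSE),
    orders = orders,
    diagnoses = diagnoses,
    latent = latent,
    truth = cfg$planted_log_or,
    config = cfg), class = "simulated_cohort")
}

make_orders <- function(cfg, expo, pat_of, delivery_date, patient_id, meds) {
  hit <- which(expo == 1L, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(data.frame(patient_id = character(), order_date = as.Date(character()),
                      drug_name = character(), ingredient = character(),
                      stringsAsFactors = FALSE))
  }
  n_orders <- sample(1:3, nrow(hit), replace = TRUE)
  idx <- rep(seq_len(nrow(hit)), n_orders)
  del <- hit[idx, 1]
  med <- meds[hit[idx, 2]]
  # 1..280 whole days before delivery: always inside the exposure window
  offs <- 1L + floor(stats::runif(length(idx)) * 280)
  aliases <- cfg$drug_aliases[meds]
  nalias <- lengths(aliases)
  flat <- unlist(aliases, use.names = FALSE)
  astart <- cumsum(c(0L, nalias[-length(nalias)]))
  names(astart) <- meds
  pick <- 1L + floor(stats::runif(length(idx)) * nalias[med])
  data.frame(patient_id = patient_id[pat_of[del]],
             order_date = delivery_date[del] - offs,
             drug_name = flat[astart[med] + pick],
             ingredient = med,
             stringsAsFactors = FALSE)
}

make_diagnoses <- function(cfg, flags, out, pat_of, delivery_date, patient_id,
                           covs, outs, exact_margins) {
  chit <- which(flags == 1L, arr.ind = TRUE)
  cov_codes <- vapply(covs, function(nm) emit_code(cfg$vocabulary[[nm]]),
                      character(1))
  out_codes <- vapply(outs, function(nm) emit_code(cfg$vocabulary[[nm]]),
                      character(1))
  cov_df <- NULL
  if (nrow(chit) > 0) {
    offs <- 1L + floor(stats::runif(nrow(chit)) * 730)
    if (!exact_margins && cfg$old_diagnosis_fraction > 0) {
      old <- stats::runif(nrow(chit)) < cfg$old_diagnosis_fraction
      offs[old] <- 731L + floor(stats::runif(sum(old)) * 365)
    }
    cov_df <- data.frame(patient_id = patient_id[pat_of[chit[, 1]]],
                         date = delivery_date[chit[, 1]] - offs,
                         code = cov_codes[chit[, 2]],
                         stringsAsFactors = FALSE)
  }
  ohit <- which(out == 1L, arr.ind = TRUE)
  out_df <- NULL
  if (nrow(ohit) > 0) {
    out_df <- data.frame(patient_id = patient_id[pat_of[ohit[, 1]]],
                         date = delivery_date[ohit[, 1]],
                         code = out_codes[ohit[, 2]],
                         stringsAsFactors = FALSE)
  }
  dg <- rbind(cov_df, out_df)
  if (is.null(dg)) {
    dg <- data.frame(patient_id = character(), date = as.Date(character()),
                     code = character(), stringsAsFactors = FALSE)
  }
  dg[order(dg$patient_id, dg$date, dg$code), , drop = FALSE]
}

#' Write a simulated cohort to delimited files
#'
#' Writes `patients.tsv`, `deliveries.tsv`, `orders.tsv`, `diagnoses.tsv`
#' and `truth.json` (the planted log odds ratio matrix) under `dir`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulated_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table_file(cohort$patients, file.path(dir, "patients.tsv"))
  write_table_file(cohort$deliveries, file.path(dir, "deliveries.tsv"))
  write_table_file(cohort$orders, file.path(dir, "orders.tsv"))
  write_table_file(cohort$diagnoses, file.path(dir, "diagnoses.tsv"))
  tr <- as.data.frame(as.table(cohort$truth), stringsAsFactors = FALSE)
  names(tr) <- c("medication", "outcome", "log_or")
  jsonlite::write_json(tr, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}

#' Bundled toy ICD vocabulary
#'
#' Loads the illustrative vocabulary shipped with the package: one OUTCOME
#' code set per pregnancy outcome and one COVARIATE set per default
#' comorbidity, each with an exact ICD-10-style member and an ICD-9-style
#' prefix. These lists are illustrative plumbing, not clinically validated
#' phenotypes; real analyses should load their own vocabulary with
#' [read_codesets()].
#'
#' @return an `icd_vocabulary`.
#' @export
default_vocabulary <- function() {
  path <- system.file("extdata", "toy_codesets.tsv", package = "mwascreen")
  if (path == "") stop("bundled vocabulary not found; is the package installed?")
  read_codesets(path)
}

#' Bundled toy drug map
#'
#' Brand and generic raw order names for the ten default candidate
#' medications, mapped many-to-one onto medication variables.
#'
#' @return a [drug_map()].
#' @export
default_drug_map <- function() {
  aliases <- default_drug_aliases()
  drug_map(data.frame(raw_name = unlist(aliases, use.names = FALSE),
                      variable = rep(names(aliases), lengths(aliases)),
                      stringsAsFactors = FALSE))
}
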
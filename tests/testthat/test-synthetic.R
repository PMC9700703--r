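test_that("an empty cohort produces empty tables without error", {
  co <- simulate_cohort(sim_config(n_patients = 0))
  expect_equal(nrow(co$patients), 0)
  expect_equal(nrow(co$deliveries), 0)
  expect_equal(nrow(co$orders), 0)
  expect_equal(nrow(co$diagnoses), 0)
})

test_that("invalid probabilities are rejected before generation", {
  expect_error(sim_config(outcome_base_prevalence = c(cesarean = 1.2,
                                                      preterm = 0.1,
                                                      stillbirth = 0.01)),
               "\\[0, 1\\]")
  expect_error(sim_config(n_patients = -1), "n_patients")
  cfg <- sim_config(n_patients = 10)
  cfg$covariate_prevalence[1] <- -0.1
  expect_error(simulate_cohort(cfg), "\\[0, 1\\]")
})

test_that("identical configurations generate identical cohorts", {
  cfg <- default_sim_config(n_patients = 300, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$patients, b$patients)
  expect_identical(a$deliveries, b$deliveries)
  expect_identical(a$orders, b$orders)
  expect_identical(a$diagnoses, b$diagnoses)
  c2 <- simulate_cohort(default_sim_config(n_patients = 300, seed = 12))
  expect_false(identical(a$deliveries, c2$deliveries))
})

test_that("generated tables satisfy referential and date invariants", {
  cfg <- default_sim_config(n_patients = 500, seed = 3)
  co <- simulate_cohort(cfg)
  expect_false(anyDuplicated(co$deliveries$delivery_id) > 0)
  expect_true(all(co$orders$patient_id %in% co$patients$patient_id))
  expect_true(all(co$diagnoses$patient_id %in% co$patients$patient_id))
  expect_true(all(co$deliveries$delivery_date >= cfg$date_range[1]))
  expect_true(all(co$deliveries$delivery_date <= cfg$date_range[2]))
  # outcome diagnoses are dated ON a delivery date; covariate diagnoses
  # strictly before the corresponding delivery
  vocab <- cfg$vocabulary
  norm <- normalize_icd(co$diagnoses$code)$normalized
  is_outcome <- code_matches(norm, vocab$cesarean) |
    code_matches(norm, vocab$preterm) | code_matches(norm, vocab$stillbirth)
  dkey <- paste(co$deliveries$patient_id, co$deliveries$delivery_date)
  expect_true(all(paste(co$diagnoses$patient_id[is_outcome],
                        co$diagnoses$date[is_outcome]) %in% dkey))
  expect_false(any(paste(co$diagnoses$patient_id[!is_outcome],
                         co$diagnoses$date[!is_outcome]) %in% dkey))
})

test_that("marginal outcome frequency converges to the configured prevalence", {
  # all effect terms zero: cesarean ~ Bernoulli(0.33) per delivery
  cfg <- sim_config(n_patients = 10000, seed = 42,
                    deliveries_per_patient_dist = c("1" = 1),
                    outcome_base_prevalence = c(cesarean = 0.33,
                                                preterm = 0.0615,
                                                stillbirth = 0.0081))
  co <- simulate_cohort(cfg)
  freq <- mean(co$latent$cesarean)
  se <- sqrt(0.33 * 0.67 / nrow(co$latent))
  expect_lt(abs(freq - 0.33), 3 * se)
})

test_that("default configuration carries the reference prevalences", {
  cfg <- default_sim_config()
  expect_equal(unname(cfg$outcome_base_prevalence["cesarean"]), 0.3299)
  expect_equal(unname(cfg$outcome_base_prevalence["stillbirth"]), 0.0081)
  expect_equal(unname(cfg$covariate_prevalence["preeclampsia"]), 5071 / 63334)
  expect_equal(round(unname(cfg$covariate_prevalence["preeclampsia"]), 4), 0.0801)
  expect_equal(cfg$maternal_age_mean_sd, c(29.48, 6.08))
  expect_length(cfg$covariate_prevalence, 16)
  expect_silent(validate_sim_config(cfg))
})

test_that("exact-margins fixture reproduces the reference cohort margins", {
  cfg <- default_sim_config(n_patients = 63334, seed = 5)
  co <- simulate_cohort(cfg, exact_margins = TRUE)
  vocab <- cfg$vocabulary
  ch <- build_cohort(co$deliveries, co$diagnoses, vocab, co$patients)
  expect_equal(nrow(ch), 63334)
  expect_equal(sum(ch$cesarean), 20894)
  expect_equal(pct(sum(ch$cesarean), nrow(ch)), 32.99)
  expect_equal(pct(sum(ch$preterm), nrow(ch)), 6.15)
  expect_equal(pct(sum(ch$stillbirth), nrow(ch)), 0.81)
  cv <- build_covariates(ch, co$diagnoses, vocab, co$patients)
  expect_equal(sum(cv[, "preeclampsia"]), 5071)
  expect_equal(pct(sum(cv[, "preeclampsia"]), nrow(ch)), 8.01)
  expect_equal(round_half_up(mean(cv[, "maternal_age"]), 2), 29.48)
})

test_that("old-dated diagnoses fall outside the downstream lookback", {
  cfg <- sim_config(n_patients = 400, seed = 9,
                    deliveries_per_patient_dist = c("1" = 1),
                    old_diagnosis_fraction = 1)
  co <- simulate_cohort(cfg)
  ch <- build_cohort(co$deliveries, co$diagnoses, cfg$vocabulary, co$patients)
  cv <- build_covariates(ch, co$diagnoses, cfg$vocabulary, co$patients)
  flags <- cv[, setdiff(colnames(cv), "maternal_age")]
  expect_true(sum(co$latent$preeclampsia) > 0)  # latent flags exist
  expect_equal(sum(flags), 0)                   # none recoverable
})

test_that("written cohort round-trips through the file readers", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(default_sim_config(n_patients = 50, seed = 2))
  write_simulated_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("patients.tsv", "deliveries.tsv", "orders.tsv", "diagnoses.tsv",
      "truth.json")))))
  del <- read_table_file(file.path(dir, "deliveries.tsv"))
  expect_equal(nrow(del), nrow(co$deliveries))
  expect_equal(as.Date(del$delivery_date), co$deliveries$delivery_date)
})
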
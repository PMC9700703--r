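test_that("covariate-free logistic OR equals the 2x2 cross-product ratio", {
  # exposed 100 with 30 events, unexposed 900 with 90 events
  y <- c(rep(1, 30), rep(0, 70), rep(1, 90), rep(0, 810))
  x <- c(rep(1, 100), rep(0, 900))
  fit <- fit_single(y, x)
  oracle <- (30 * 810) / (70 * 90)
  expect_lt(abs(fit$or_estimate - oracle) / oracle, 1e-6)
  expect_true(fit$converged)
  expect_false(fit$separation_flag)
  expect_equal(fit$n_exposed, 100)
  expect_true(fit$ci_low <= fit$or_estimate && fit$or_estimate <= fit$ci_high)
})

test_that("perfect separation is flagged and the estimate nulled", {
  y <- c(rep(1, 10), rep(0, 10))
  fit <- fit_single(y, y)
  expect_true(fit$separation_flag)
  expect_true(is.na(fit$or_estimate))
  expect_true(is.na(fit$p_nominal))
})

test_that("degenerate inputs raise structured errors", {
  expect_error(fit_single(rep(0, 20), rep(c(0, 1), 10)),
               class = "mwas_degenerate_outcome")
  expect_error(fit_single(rep(c(0, 1), 10), rep(1, 20)),
               class = "mwas_degenerate_exposure")
  expect_error(fit_single(c(0, 1, 2, 1), c(0, 1, 0, 1)), "binary")
})

test_that("screen applies the Bonferroni formula, flags, and ordering", {
  co <- simulate_cohort(default_sim_config(n_patients = 3000, seed = 13))
  res <- screen_simulated(co)
  m <- attr(res, "bonferroni_m")
  expect_equal(m, 30)
  expect_equal(res$p_bonferroni, pmin(1, res$p_nominal * m))
  ok <- !is.na(res$p_nominal)
  expect_true(all(res$p_bonferroni[ok] >= res$p_nominal[ok]))
  expect_true(all(res$p_bonferroni[ok] <= 1))
  expect_equal(res$sig_nominal[ok],
               as.integer(res$p_nominal[ok] <= 0.05))
  expect_equal(res$sig_bonferroni,
               as.integer(res$sig_nominal == 1 &
                            !is.na(res$p_bonferroni) & res$p_bonferroni <= 0.05))
  expect_true(all(res$ci_low[ok & res$converged] <= res$or_estimate[ok & res$converged]))
  # deterministic (medication, outcome) ordering
  expect_equal(res$medication, rep(names(default_medication_exposure()), each = 3))
  # a p-value of 1 stays 1 after correction
  expect_equal(pmin(1, 1 * m), 1)
})

test_that("degenerate pairs yield flagged rows without aborting the screen", {
  co <- simulate_cohort(default_sim_config(n_patients = 2000, seed = 17))
  vocab <- co$config$vocabulary
  ch <- build_cohort(co$deliveries, co$diagnoses, vocab, co$patients)
  ex <- suppressMessages(apply_min_patient_filter(
    build_exposures(co$orders, ch, default_drug_map()), 1))
  cv <- build_covariates(ch, co$diagnoses, vocab, co$patients)
  ch$stillbirth <- 0L  # make one outcome constant
  spec <- screen_spec(c("cesarean", "preterm", "stillbirth"),
                      colnames(ex$matrix),
                      setdiff(colnames(cv), "maternal_age"))
  res <- run_screen(spec, ex, cv, ch)
  bad <- res$outcome == "stillbirth"
  expect_true(all(!res$converged[bad]))
  expect_true(all(grepl("degenerate outcome", res$note[bad])))
  expect_true(all(is.na(res$or_estimate[bad])))
  expect_true(any(res$converged[!bad]))
})

test_that("row-pattern aggregation leaves every reported number unchanged", {
  co <- simulate_cohort(default_sim_config(n_patients = 2500, seed = 19))
  co$config$vocabulary <- default_vocabulary()
  vocab <- co$config$vocabulary
  ch <- build_cohort(co$deliveries, co$diagnoses, vocab, co$patients)
  ex <- suppressMessages(apply_min_patient_filter(
    build_exposures(co$orders, ch, default_drug_map()), 5))
  cv <- build_covariates(ch, co$diagnoses, vocab, co$patients)
  for (med in colnames(ex$matrix)[1:3]) {
    plain <- fit_single(ch$cesarean, ex$matrix[, med], cv)
    spec <- screen_spec("cesarean", med, setdiff(colnames(cv), "maternal_age"))
    agg <- run_screen(spec, ex, cv, ch)
    expect_equal(agg$log_or, plain$log_or, tolerance = 1e-9)
    expect_equal(agg$se, plain$se, tolerance = 1e-9)
  }
})

test_that("permuting delivery rows changes no reported number", {
  co <- simulate_cohort(default_sim_config(n_patients = 1500, seed = 23))
  vocab <- co$config$vocabulary
  perm <- sample(nrow(co$deliveries))
  run_one <- function(deliveries) {
    ch <- build_cohort(deliveries, co$diagnoses, vocab, co$patients)
    ex <- suppressMessages(apply_min_patient_filter(
      build_exposures(co$orders, ch, default_drug_map()), 5))
    cv <- build_covariates(ch, co$diagnoses, vocab, co$patients)
    spec <- screen_spec(c("cesarean", "preterm", "stillbirth"),
                        sort(colnames(ex$matrix)),
                        setdiff(colnames(cv), "maternal_age"))
    run_screen(spec, ex, cv, ch)
  }
  a <- run_one(co$deliveries)
  b <- run_one(co$deliveries[perm, ])
  expect_equal(a, b, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("goodness-of-fit comparison reports a non-negative LR for nesting", {
  co <- simulate_cohort(default_sim_config(n_patients = 4000, seed = 29))
  vocab <- co$config$vocabulary
  ch <- build_cohort(co$deliveries, co$diagnoses, vocab, co$patients)
  ex <- build_exposures(co$orders, ch, default_drug_map())
  cv <- build_covariates(ch, co$diagnoses, vocab, co$patients)
  x <- ex$matrix[, "heparin"]
  adjusted <- fit_single(ch$cesarean, x, cv)
  unadjusted <- fit_single(ch$cesarean, x)
  cmp <- compare_goodness_of_fit(adjusted, unadjusted)
  expect_gte(cmp$lr_statistic, 0)
  expect_equal(cmp$df, adjusted$df - unadjusted$df)
  # identical models give an LR of exactly zero
  same <- compare_goodness_of_fit(adjusted, adjusted)
  expect_equal(same$lr_statistic, 0)
  # mismatched rows are an alignment error
  half <- fit_single(ch$cesarean[1:2000], x[1:2000])
  expect_error(compare_goodness_of_fit(adjusted, half), "identical rows")
})
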
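toy_candidates_df <- function() {
  read_candidates(system.file("extdata", "toy_candidates.tsv",
                              package = "mwascreen"))
}

test_that("each exclusion rule fires with its documented reason", {
  drugs <- toy_candidates_df()
  res <- apply_exclusions(drugs)
  reason_of <- function(nm) res$excluded$reason[res$excluded$name == nm]
  expect_equal(reason_of("remdesivir"), "approved after cutoff")      # 2020
  expect_equal(reason_of("baricitinib"), "approved after cutoff")     # 2018
  expect_equal(reason_of("experimental-ag7"), "no FDA approval")
  expect_equal(reason_of("lopinavir"), "HIV-only indication")
  expect_equal(reason_of("vitamin-d-lifestyle-arm"),
               "non-pharmaceutical or biological product")
  expect_equal(reason_of("colchicine-male-only"),
               "no reproductive-age female participants")
  expect_true("oseltamivir" %in% res$kept$name)   # fully compliant
  expect_true("tocilizumab" %in% res$kept$name)   # approved 2010
})

test_that("exactly the first matching rule is reported", {
  d <- data.frame(name = "multi-fail", fda_approved = FALSE,
                  approval_year = NA, hiv_only_indication = TRUE,
                  pharmaceutical_or_biological = FALSE,
                  trial_includes_reproductive_age_females = FALSE)
  res <- apply_exclusions(d)
  expect_equal(res$excluded$reason, "no FDA approval")
  d2 <- d
  d2$fda_approved <- TRUE; d2$approval_year <- 2019L
  expect_equal(apply_exclusions(d2)$excluded$reason, "approved after cutoff")
  d3 <- d2
  d3$approval_year <- 2000L
  expect_equal(apply_exclusions(d3)$excluded$reason,
               "non-pharmaceutical or biological product")
})

test_that("kept and excluded partition the input and stay order-stable", {
  drugs <- toy_candidates_df()
  res <- apply_exclusions(drugs)
  expect_equal(sort(c(res$kept$name, res$excluded$name)), sort(drugs$name))
  expect_length(intersect(res$kept$name, res$excluded$name), 0)
  expect_equal(res$kept$name, drugs$name[drugs$name %in% res$kept$name])
  rep <- exclusion_report(res)
  expect_equal(sum(rep$n), nrow(res$excluded))
})

test_that("raising the cutoff year never shrinks the kept set", {
  drugs <- toy_candidates_df()
  kept <- lapply(c(2015, 2017, 2019, 2021),
                 function(y) apply_exclusions(drugs, cutoff_year = y)$kept$name)
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i]] %in% kept[[i + 1]]))
  }
})

test_that("the rule engine is byte-stable across runs", {
  drugs <- toy_candidates_df()
  expect_equal(nrow(drugs), 20)
  a <- apply_exclusions(drugs)
  b <- apply_exclusions(drugs)
  expect_identical(a, b)
  ta <- tempfile(); tb <- tempfile()
  utils::write.table(a$excluded, ta, sep = "\t", row.names = FALSE)
  utils::write.table(b$excluded, tb, sep = "\t", row.names = FALSE)
  expect_identical(readBin(ta, "raw", file.size(ta)),
                   readBin(tb, "raw", file.size(tb)))
})

test_that("missing required fields fail validation naming the record", {
  d <- data.frame(name = "x", fda_approved = TRUE, approval_year = NA,
                  hiv_only_indication = FALSE,
                  pharmaceutical_or_biological = TRUE,
                  trial_includes_reproductive_age_females = TRUE)
  expect_error(apply_exclusions(d), "approval_year")
  d2 <- data.frame(name = "y", fda_approved = TRUE, approval_year = 2000,
                   hiv_only_indication = NA,
                   pharmaceutical_or_biological = TRUE,
                   trial_includes_reproductive_age_females = TRUE)
  expect_error(apply_exclusions(d2), "hiv_only_indication")
})
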
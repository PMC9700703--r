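test_that("exposure window bounds match the 280-to-1-day rule exactly", {
  d <- as.Date("2015-06-01")
  # brute force over offsets 0..400 against the stated inequality
  offsets <- 0:400
  expect_equal(in_exposure_window(d - offsets, d),
               offsets >= 1 & offsets <= 280)
  expect_true(in_exposure_window(d - 1, d))
  expect_false(in_exposure_window(d, d))        # delivery-day order
  expect_true(in_exposure_window(d - 280, d))
  expect_false(in_exposure_window(d - 281, d))
})

test_that("window membership is translation invariant", {
  d <- as.Date("2015-06-01")
  for (k in c(-500, -1, 17, 3650)) {
    expect_equal(in_exposure_window(d - 0:400 + k, d + k),
                 in_exposure_window(d - 0:400, d))
  }
})

test_that("brand and generic orders merge into one binary variable", {
  map <- drug_map(data.frame(raw_name = c("Tamiflu", "oseltamivir"),
                             variable = "oseltamivir"))
  cohort <- toy_deliveries()
  orders <- data.frame(
    patient_id = c("P1", "P1", "P1"),
    order_date = as.Date(c("2015-05-20", "2015-04-01", "2015-03-15")),
    drug_name = c("Tamiflu", "oseltamivir", "Tamiflu"),
    stringsAsFactors = FALSE)
  m <- build_exposures(orders, cohort, map)
  expect_equal(colnames(m$matrix), "oseltamivir")
  expect_equal(unname(m$matrix[, 1]), c(1L, 0L, 0L))  # binary, not a count
  expect_equal(unname(m$patient_count), 1L)
})

test_that("splitting orders across equivalent brand names changes nothing", {
  map <- drug_map(data.frame(raw_name = c("Advil", "Motrin", "ibuprofen"),
                             variable = "ibuprofen"))
  cohort <- toy_deliveries()
  dates <- as.Date(c("2015-05-20", "2015-04-02"))
  one_name <- data.frame(patient_id = "P1", order_date = dates,
                         drug_name = "ibuprofen", stringsAsFactors = FALSE)
  split_names <- data.frame(patient_id = "P1", order_date = dates,
                            drug_name = c("Advil", "Motrin"),
                            stringsAsFactors = FALSE)
  expect_equal(build_exposures(one_name, cohort, map)$matrix,
               build_exposures(split_names, cohort, map)$matrix)
})

test_that("unmapped drug names are excluded and reported", {
  map <- drug_map(data.frame(raw_name = "aspirin", variable = "aspirin"))
  orders <- data.frame(patient_id = "P1",
                       order_date = as.Date("2015-05-20"),
                       drug_name = c("aspirin", "mystery-drug"),
                       stringsAsFactors = FALSE)
  expect_message(m <- build_exposures(orders, toy_deliveries(), map),
                 "unmapped")
  expect_equal(m$unmapped$raw_name, "mystery-drug")
  expect_equal(unname(m$matrix[, "aspirin"]), c(1L, 0L, 0L))
})

test_that("a raw name mapping to two variables is rejected", {
  expect_error(drug_map(data.frame(raw_name = c("a", "a"),
                                   variable = c("x", "y"))),
               "more than one variable")
})

test_that("minimum-patient filter drops at 9 and keeps at 10, monotonely", {
  n <- 25
  cohort <- data.frame(
    patient_id = sprintf("P%02d", 1:n),
    delivery_id = sprintf("D%02d", 1:n),
    delivery_date = as.Date("2015-06-01") + seq_len(n),
    stringsAsFactors = FALSE)
  map <- drug_map(data.frame(raw_name = c("a", "b"), variable = c("a", "b")))
  orders <- rbind(
    data.frame(patient_id = sprintf("P%02d", 1:9),
               order_date = cohort$delivery_date[1:9] - 5, drug_name = "a"),
    data.frame(patient_id = sprintf("P%02d", 1:10),
               order_date = cohort$delivery_date[1:10] - 5, drug_name = "b"))
  m <- build_exposures(orders, cohort, map)
  expect_message(f10 <- apply_min_patient_filter(m, 10), "dropped")
  expect_equal(colnames(f10$matrix), "b")
  # monotone: lowering the threshold never removes a retained column
  f9 <- apply_min_patient_filter(m, 9)
  expect_true(all(colnames(f10$matrix) %in% colnames(f9$matrix)))
  expect_equal(sort(colnames(f9$matrix)), c("a", "b"))
})

test_that("patients, not deliveries, are counted for the inclusion filter", {
  # one patient with two exposed deliveries is still one patient
  cohort <- data.frame(patient_id = c("P1", "P1"),
                       delivery_id = c("D1", "D2"),
                       delivery_date = as.Date(c("2013-06-01", "2015-06-01")),
                       stringsAsFactors = FALSE)
  map <- drug_map(data.frame(raw_name = "a", variable = "a"))
  orders <- data.frame(patient_id = "P1",
                       order_date = as.Date(c("2013-05-01", "2015-05-01")),
                       drug_name = "a", stringsAsFactors = FALSE)
  m <- build_exposures(orders, cohort, map)
  expect_equal(sum(m$matrix), 2)
  expect_equal(unname(m$patient_count), 1L)
})

test_that("empty cohort yields an empty matrix without error", {
  map <- drug_map(data.frame(raw_name = "a", variable = "a"))
  cohort <- toy_deliveries()[0, ]
  orders <- data.frame(patient_id = "P1", order_date = as.Date("2015-01-01"),
                       drug_name = "a", stringsAsFactors = FALSE)
  m <- build_exposures(orders, cohort, map)
  expect_equal(nrow(m$matrix), 0)
})
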
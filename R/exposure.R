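#' Construct a drug map
#'
#' A many-to-one map from raw order drug names (brand and generic
#' spellings) to medication analysis variables, used to merge brand/generic
#' equivalents (e.g. Tamiflu and oseltamivir into one `oseltamivir`
#' variable) before exposures are counted. Combination products with
#' additional active ingredients should map to their own variable rather
#' than the single-ingredient one.
#'
#' @param df data.frame with columns `raw_name`, `variable`.
#' @return object of class `drug_map`.
#' @export
drug_map <- function(df) {
  check_columns(df, c("raw_name", "variable"), "drug map")
  if (anyDuplicated(df$raw_name)) {
    clash <- unique(df$raw_name[duplicated(df$raw_name)])
    stop(sprintf("raw drug name(s) map to more than one variable: %s",
                 paste(utils::head(clash, 10), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(entries = stats::setNames(df$variable, df$raw_name),
                 variables = unique(df$variable)), class = "drug_map")
}

#' Read a drug map file
#'
#' @param path tab-delimited file with columns `raw_name`, `variable`.
#' @return a [drug_map()].
#' @export
read_drug_map <- function(path) drug_map(read_table_file(path))

#' Pregnancy exposure window test
#'
#' An order exposes a delivery when it falls from `window_days` days before
#' delivery up to `end_offset_days` before delivery, both bounds inclusive,
#' in whole-day arithmetic: with the defaults,
#' `delivery - 280 <= order <= delivery - 1`. An order on the delivery day
#' itself is not an exposure.
#'
#' @param order_date,delivery_date Date vectors (recycled).
#' @param window_days window start, in days before delivery (default 280).
#' @param end_offset_days window end, in days before delivery (default 1).
#' @return logical vector.
#' @export
in_exposure_window <- function(order_date, delivery_date,
                               window_days = 280, end_offset_days = 1) {
  d <- as.numeric(as.Date(delivery_date) - as.Date(order_date))
  d >= end_offset_days & d <= window_days
}

#' Build the per-delivery exposure matrix
#'
#' Maps each order's raw drug name to its medication variable, restricts to
#' orders inside the exposure window of each delivery of the ordering
#' patient, and marks the cell 1 when at least one such order exists
#' (binary, not a count). Orders whose raw name is absent from the map are
#' excluded and reported via a message.
#'
#' @param orders data.frame with columns `patient_id`, `order_date`,
#'   `drug_name`.
#' @param cohort a [build_cohort()] result (or any data.frame with
#'   `patient_id`, `delivery_id`, `delivery_date`).
#' @param map a [drug_map()].
#' @param window_days,end_offset_days see [in_exposure_window()].
#' @return object of class `exposure_matrix`: list with `matrix` (0/1,
#'   deliveries x medication variables, rownames = delivery_id),
#'   `patient_count` (distinct patients with >= 1 exposed delivery, per
#'   variable), `delivery_patient` (patient of each row), and
#'   `unmapped` (excluded raw names with order counts).
#' @export
build_exposures <- function(orders, cohort, map,
                            window_days = 280, end_offset_days = 1) {
  stopifnot(inherits(map, "drug_map"))
  check_columns(orders, c("patient_id", "order_date", "drug_name"), "orders")
  vars <- map$variables
  m <- matrix(0L, nrow(cohort), length(vars),
              dimnames = list(cohort$delivery_id, vars))
  unmapped <- data.frame(raw_name = character(), n_orders = integer())
  if (nrow(orders) > 0 && nrow(cohort) > 0) {
    orders$order_date <- as_event_date(orders$order_date, "order_date")
    known <- orders$drug_name %in% names(map$entries)
    if (any(!known)) {
      tab <- table(orders$drug_name[!known])
      unmapped <- data.frame(raw_name = names(tab),
                             n_orders = as.integer(tab))
      message(sprintf("excluded %d order(s) with %d unmapped drug name(s)",
                      sum(!known), length(tab)))
    }
    orders <- orders[known, , drop = FALSE]
    orders$variable <- unname(map$entries[orders$drug_name])
    dl <- data.frame(row = seq_len(nrow(cohort)),
                     patient_id = cohort$patient_id,
                     delivery_date = as_event_date(cohort$delivery_date,
                                                   "delivery_date"))
    j <- merge(dl, orders[, c("patient_id", "order_date", "variable")],
               by = "patient_id")
    if (nrow(j) > 0) {
      inw <- in_exposure_window(j$order_date, j$delivery_date,
                                window_days, end_offset_days)
      j <- j[inw, , drop = FALSE]
      m[cbind(j$row, match(j$variable, vars))] <- 1L
    }
  }
  patient_count <- vapply(vars, function(v) {
    length(unique(cohort$patient_id[m[, v] == 1L]))
  }, integer(1))
  structure(list(matrix = m, patient_count = patient_count,
                 delivery_patient = cohort$patient_id, unmapped = unmapped),
            class = "exposure_matrix")
}

#' Minimum-patient inclusion filter
#'
#' Drops medication variables prescribed, within the exposure window, to
#' fewer than `threshold` distinct patients. Protects privacy and avoids
#' screening associations with negligible power. Dropped variables are
#' reported via a message with counts masked below the threshold.
#'
#' @param m an [build_exposures()] result.
#' @param threshold minimum distinct exposed patients (default 10).
#' @return a filtered `exposure_matrix`.
#' @export
apply_min_patient_filter <- function(m, threshold = 10) {
  stopifnot(inherits(m, "exposure_matrix"), threshold >= 1)
  keep <- m$patient_count >= threshold
  if (any(!keep)) {
    message(sprintf("dropped %d medication variable(s) below %d patients: %s",
                    sum(!keep), threshold,
                    paste(sprintf("%s (n<%d)", names(which(!keep)), threshold),
                          collapse = ", ")))
  }
  structure(list(matrix = m$matrix[, keep, drop = FALSE],
                 patient_count = m$patient_count[keep],
                 delivery_patient = m$delivery_patient,
                 unmapped = m$unmapped,
                 dropped = names(which(!keep))),
            class = "exposure_matrix")
}
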
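default_pipeline_params <- function() {
  list(alpha = 0.05, bonferroni_m = NULL, min_patients = 10,
       window_days = 280, end_offset_days = 1, lookback_days = 730,
       cutoff_year = 2017, suppression_threshold = 10,
       outcome_window_days = 0)
}

#' Run the full MWAS pipeline
#'
#' End-to-end driver: candidate-drug exclusions (when a candidate table is
#' configured), cohort assembly with outcome flags, exposure matrix with
#' brand/generic merging and the minimum-patient filter, covariate matrix,
#' the adjusted logistic screen with Bonferroni correction, and rendered
#' outputs — a cohort summary table, an association table, forest-plot
#' exports, and a JSON run manifest with per-stage record counts. All
#' rendered tables apply small-cell suppression. On any stage failure the
#' partially written outputs are removed and the error is re-raised with
#' the stage name.
#'
#' @param config a list, or path to a YAML file, with elements `inputs`
#'   (paths: `patients`, `deliveries`, `orders`, `diagnoses`, `vocabulary`,
#'   `drug_map`, optional `candidates`), `out_dir`, and optional `params`
#'   overriding alpha, `bonferroni_m`, `min_patients`, `window_days`,
#'   `end_offset_days`, `lookback_days`, `cutoff_year`,
#'   `suppression_threshold`, `outcome_window_days`.
#' @return invisibly, a list with the in-memory stage objects (`cohort`,
#'   `exposures`, `covariates`, `results`, `summary`, `forest`,
#'   `exclusions`, `manifest`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$inputs), !is.null(config$out_dir))
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  inp <- config$inputs
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      unlink(written)
      stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  emit <- function(df, name, header = NULL) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(header, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }

  patients <- stage("read_inputs", read_table_file(inp$patients))
  deliveries <- stage("read_inputs", read_table_file(inp$deliveries))
  orders <- stage("read_inputs", read_table_file(inp$orders))
  diagnoses <- stage("read_inputs", read_table_file(inp$diagnoses))
  vocab <- stage("read_inputs", read_codesets(inp$vocabulary))
  dmap <- stage("read_inputs", read_drug_map(inp$drug_map))

  exclusions <- NULL
  if (!is.null(inp$candidates)) {
    exclusions <- stage("trial_filter", {
      apply_exclusions(read_candidates(inp$candidates), params$cutoff_year)
    })
    kept_vars <- intersect(dmap$variables, exclusions$kept$name)
    keep_raw <- dmap$entries %in% kept_vars
    dmap <- drug_map(data.frame(raw_name = names(dmap$entries)[keep_raw],
                                variable = unname(dmap$entries[keep_raw]),
                                stringsAsFactors = FALSE))
    exc <- exclusions$excluded[, c("name", "reason")]
    stage("trial_filter", emit(exc, "exclusions.tsv"))
  }

  cohort <- stage("cohort_outcomes",
                  build_cohort(deliveries, diagnoses, vocab, patients,
                               params$outcome_window_days))
  exposures <- stage("exposure", {
    m <- build_exposures(orders, cohort, dmap,
                         params$window_days, params$end_offset_days)
    apply_min_patient_filter(m, params$min_patients)
  })
  covs <- stage("covariates",
                build_covariates(cohort, diagnoses, vocab, patients,
                                 params$lookback_days))

  outcomes <- setdiff(names(cohort),
                      c("patient_id", "delivery_id", "delivery_date"))
  meds <- colnames(exposures$matrix)
  results <- stage("screen", {
    spec <- screen_spec(outcomes, meds,
                        setdiff(colnames(covs), "maternal_age"),
                        alpha = params$alpha,
                        bonferroni_m = params$bonferroni_m)
    run_screen(spec, exposures, covs, cohort)
  })

  any_exposed <- as.integer(rowSums(exposures$matrix) > 0)
  summary <- stage("reporting",
                   summarize_cohort(cohort, any_exposed, covs))
  cov_effects <- stage("reporting", fit_covariate_effects(cohort, covs))
  forest <- stage("reporting", export_forest(results, cov_effects))

  stage("reporting", {
    emit(render_summary(summary, params$suppression_threshold),
         "cohort_summary.tsv")
    assoc <- render_associations(results, params$suppression_threshold)
    emit(assoc, "associations.tsv", header = attr(assoc, "header"))
    emit(forest, "forest.tsv")
  })

  manifest <- list(
    package = "mwascreen",
    version = as.character(utils::packageVersion("mwascreen")),
    inputs = inp, params = params,
    record_counts = list(
      patients = nrow(patients), deliveries = nrow(deliveries),
      orders = nrow(orders), diagnoses = nrow(diagnoses),
      cohort_deliveries = nrow(cohort),
      medications_screened = length(meds),
      outcomes_screened = length(outcomes),
      tests = nrow(results)),
    medications = meds,
    bonferroni_m = attr(results, "bonferroni_m"),
    alpha = attr(results, "alpha"))
  stage("reporting", {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, file.path(out_dir, "manifest.json"))
  })

  invisible(list(cohort = cohort, exposures = exposures, covariates = covs,
                 results = results, summary = summary, forest = forest,
                 exclusions = exclusions, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
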
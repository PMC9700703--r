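#' Small-cell suppression
#'
#' Renders patient/delivery counts for user-facing tables: counts below the
#' threshold become the mask token (protecting against re-identification of
#' rare combinations); counts at or above it are formatted with thousands
#' separators. Percentages derived from a masked count must be masked too —
#' [render_summary()] applies that rule.
#'
#' @param count non-negative integer vector.
#' @param threshold minimum publishable count (default 10).
#' @param mask mask token (default `"*"`).
#' @return character vector.
#' @examples
#' suppress_small_cells(c(9, 10, 5071))
#' @export
suppress_small_cells <- function(count, threshold = 10, mask = "*") {
  stopifnot(all(count >= 0))
  ifelse(count < threshold, mask,
         formatC(count, format = "d", big.mark = ","))
}

#' Render a cohort summary for publication
#'
#' Formats a [summarize_cohort()] result as text: counts via
#' [suppress_small_cells()], percentages to two decimals with the
#' percentage masked whenever its count is masked, and a mean +/- SD
#' maternal age row when age information is present.
#'
#' @param s a `cohort_summary`.
#' @param threshold,mask see [suppress_small_cells()].
#' @return character data.frame ready to write.
#' @export
render_summary <- function(s, threshold = 10, mask = "*") {
  stopifnot(inherits(s, "cohort_summary"))
  cell <- function(n, p) {
    ifelse(n < threshold, mask, sprintf("%.2f", p))
  }
  out <- data.frame(
    group = s$group, label = s$label,
    n_unexposed = suppress_small_cells(s$n_unexposed, threshold, mask),
    pct_unexposed = cell(s$n_unexposed, s$pct_unexposed),
    n_exposed = suppress_small_cells(s$n_exposed, threshold, mask),
    pct_exposed = cell(s$n_exposed, s$pct_exposed),
    n_total = suppress_small_cells(s$n_total, threshold, mask),
    pct_total = cell(s$n_total, s$pct_total),
    stringsAsFactors = FALSE)
  age <- attr(s, "age")
  if (!is.null(age)) {
    fmt <- sprintf("%.2f ± %.2f", age$mean, age$sd)
    out <- rbind(out, data.frame(
      group = "age", label = "maternal_age_mean_sd",
      n_unexposed = fmt[1], pct_unexposed = "",
      n_exposed = fmt[2], pct_exposed = "",
      n_total = fmt[3], pct_total = "", stringsAsFactors = FALSE))
  }
  out
}

#' Render the association table
#'
#' Formats screen results in the style of a published MWAS table: OR with
#' 95% CI per medication and outcome, the exposed-delivery count
#' (suppressed below the threshold), and the screening significance
#' markers: `*` nominal p <= alpha, `**` nominal and Bonferroni-adjusted
#' p <= alpha. A header comment records the Bonferroni family size, since
#' the choice of family is a reporting convention.
#'
#' @param results an [run_screen()] result.
#' @param threshold,mask see [suppress_small_cells()].
#' @return character data.frame with attribute `header`.
#' @export
render_associations <- function(results, threshold = 10, mask = "*") {
  stopifnot(inherits(results, "mwas_results"))
  fmt_or <- function(or, lo, hi) {
    ifelse(is.na(or), "-", sprintf("%.2f (%.2f-%.2f)", or, lo, hi))
  }
  marker <- ifelse(results$sig_bonferroni == 1L, "**",
                   ifelse(results$sig_nominal == 1L, "*", ""))
  out <- data.frame(
    medication = results$medication, outcome = results$outcome,
    n_exposed = suppress_small_cells(results$n_exposed, threshold, mask),
    or_95ci = fmt_or(results$or_estimate, results$ci_low, results$ci_high),
    p_nominal = ifelse(is.na(results$p_nominal), "-",
                       sprintf("%.3g", results$p_nominal)),
    p_bonferroni = ifelse(is.na(results$p_bonferroni), "-",
                          sprintf("%.3g", results$p_bonferroni)),
    sig = marker,
    flag = ifelse(results$separation_flag, "separation",
                  ifelse(!results$converged, results$note, "")),
    stringsAsFactors = FALSE)
  attr(out, "header") <- sprintf(
    "# Bonferroni family: m = %d tests (all medications x all outcomes); alpha = %g",
    attr(results, "bonferroni_m"), attr(results, "alpha"))
  out
}

#' Export forest-plot rows
#'
#' Collects the nominally significant associations into plot-ready rows,
#' split into a medication panel (screened exposures) and a covariate panel
#' (terms of the baseline adjusted model) per outcome, ordered
#' deterministically by outcome then estimate. Data export only; no figure
#' is drawn.
#'
#' @param results an [run_screen()] result.
#' @param covariate_results optional [fit_covariate_effects()] result.
#' @param alpha significance level (default: the screen's alpha).
#' @return data.frame with columns `label`, `estimate`, `ci_low`,
#'   `ci_high`, `group`, `outcome`.
#' @export
export_forest <- function(results, covariate_results = NULL, alpha = NULL) {
  stopifnot(inherits(results, "mwas_results"))
  if (is.null(alpha)) alpha <- attr(results, "alpha")
  keep <- results$sig_nominal == 1L & !is.na(results$or_estimate)
  med <- data.frame(label = results$medication[keep],
                    estimate = results$or_estimate[keep],
                    ci_low = results$ci_low[keep],
                    ci_high = results$ci_high[keep],
                    group = rep("medication", sum(keep)),
                    outcome = results$outcome[keep],
                    stringsAsFactors = FALSE)
  cov <- NULL
  if (!is.null(covariate_results)) {
    ck <- !is.na(covariate_results$p_nominal) &
      covariate_results$p_nominal <= alpha
    cov <- data.frame(label = covariate_results$term[ck],
                      estimate = covariate_results$or_estimate[ck],
                      ci_low = covariate_results$ci_low[ck],
                      ci_high = covariate_results$ci_high[ck],
                      group = rep("covariate", sum(ck)),
                      outcome = covariate_results$outcome[ck],
                      stringsAsFactors = FALSE)
  }
  out <- rbind(med, cov)
  out <- out[order(out$outcome, out$group, out$estimate, out$label), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
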
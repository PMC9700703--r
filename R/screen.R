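z975 <- 1.959964

# Maximum-likelihood logistic fit on an explicit design matrix, with Wald
# standard errors recovered from the final IRLS QR decomposition. `start`
# warm-starts IRLS (e.g. from a baseline fit without the exposure) and
# `weights` are prior row multiplicities: for a 0/1 response, collapsing
# duplicated rows into weights leaves coefficients, standard errors,
# log-likelihood and AIC exactly unchanged.
ml_logit <- function(X, y, weights = NULL, start = NULL) {
  if (is.null(weights)) weights <- rep(1, length(y))
  fit <- suppressWarnings(stats::glm.fit(
    X, y, weights = weights, family = stats::binomial(), start = start,
    control = stats::glm.control(epsilon = 1e-10, maxit = 60)))
  p <- fit$rank
  coefs <- fit$coefficients
  se <- rep(NA_real_, ncol(X))
  if (p > 0) {
    v <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
    piv <- fit$qr$pivot[seq_len(p)]
    se[piv] <- sqrt(diag(v))
  }
  names(se) <- colnames(X)
  list(coef = coefs, se = se, converged = fit$converged,
       deviance = fit$deviance, loglik = -fit$deviance / 2,
       aic = fit$aic, rank = p, n = sum(weights))
}

# Mixed-radix key over integer-valued columns with small ranges, used to
# collapse duplicated design rows. NULL when the columns don't admit a
# compact exact encoding.
encode_rows <- function(M) {
  if (nrow(M) == 0 || any(!is.finite(M)) || any(M != floor(M))) return(NULL)
  key <- numeric(nrow(M))
  mult <- 1
  for (j in seq_len(ncol(M))) {
    cj <- M[, j]
    lo <- min(cj)
    rad <- max(cj) - lo + 1
    key <- key + (cj - lo) * mult
    mult <- mult * rad
    if (mult > 2^50) return(NULL)
  }
  list(key = key, mult = mult)
}

degenerate <- function(kind, message) {
  stop(structure(class = c(paste0("mwas_degenerate_", kind),
                           "mwas_degenerate", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

# Common post-processing of an exposure fit: Wald interval and p-value for
# the exposure coefficient with flag-and-null handling of non-convergence
# and separation (|log OR| > 10).
summarize_exposure_fit <- function(fit, X, n_exposed, n) {
  b <- fit$coef["exposure"]
  se <- fit$se["exposure"]
  separation <- is.na(b) || abs(b) > 10
  ok <- fit$converged && !separation && !is.na(se)
  ct <- data.frame(term = colnames(X), estimate = unname(fit$coef),
                   se = unname(fit$se), stringsAsFactors = FALSE)
  structure(list(
    or_estimate = if (ok) exp(unname(b)) else NA_real_,
    ci_low  = if (ok) exp(unname(b) - z975 * unname(se)) else NA_real_,
    ci_high = if (ok) exp(unname(b) + z975 * unname(se)) else NA_real_,
    p_nominal = if (ok) 2 * stats::pnorm(-abs(unname(b) / unname(se)))
                else NA_real_,
    log_or = if (ok) unname(b) else NA_real_,
    se = if (ok) unname(se) else NA_real_,
    n_exposed = n_exposed, n = n,
    converged = fit$converged, separation_flag = separation,
    loglik = fit$loglik, aic = fit$aic, df = fit$rank,
    coef_table = ct), class = "mwas_fit")
}

check_binary_pair <- function(y, x) {
  if (length(y) != length(x)) {
    stop("outcome and exposure vectors differ in length", call. = FALSE)
  }
  if (!all(y %in% c(0, 1)) || !all(x %in% c(0, 1))) {
    stop("outcome and exposure must be binary 0/1", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    degenerate("outcome", "degenerate outcome: no variation in outcome vector")
  }
  if (length(unique(x)) < 2) {
    degenerate("exposure", "degenerate exposure: no variation in exposure vector")
  }
}

#' Fit one medication-outcome logistic model
#'
#' Maximum-likelihood logistic regression of a binary outcome on an
#' intercept, the binary exposure, and any supplied covariate columns
#' (typically maternal age plus the comorbidity flags). Reports the
#' exposure odds ratio with a 95% Wald interval
#' (`exp(coef +/- 1.959964 * SE)`) and a two-sided Wald p-value.
#' Non-convergence or an exposure coefficient beyond 10 in absolute value
#' (the signature of separation) sets the `converged` / `separation_flag`
#' fields and nulls the estimate rather than reporting a diverging MLE.
#'
#' @param outcome_vec 0/1 outcome, one element per delivery.
#' @param exposure_vec 0/1 exposure, aligned with `outcome_vec`.
#' @param covariate_matrix optional numeric matrix of adjustment columns.
#' @param start optional starting coefficients for IRLS, ordered as
#'   (intercept, exposure, covariates); affects speed only, not the fit.
#' @return object of class `mwas_fit`: list with `or_estimate`, `ci_low`,
#'   `ci_high`, `p_nominal`, `log_or`, `se`, `n_exposed`, `converged`,
#'   `separation_flag`, `loglik`, `aic`, `df`, `n`, and the full
#'   coefficient table `coef_table`.
#' @export
fit_single <- function(outcome_vec, exposure_vec, covariate_matrix = NULL,
                       start = NULL) {
  y <- as.numeric(outcome_vec)
  x <- as.numeric(exposure_vec)
  check_binary_pair(y, x)
  X <- cbind(`(Intercept)` = 1, exposure = x)
  if (!is.null(covariate_matrix)) {
    covariate_matrix <- as.matrix(covariate_matrix)
    if (nrow(covariate_matrix) != length(y)) {
      stop("covariate matrix rows do not align with the outcome vector",
           call. = FALSE)
    }
    X <- cbind(X, covariate_matrix)
  }
  fit <- ml_logit(X, y, start = start)
  summarize_exposure_fit(fit, X, sum(x), length(y))
}

#' @export
print.mwas_fit <- function(x, ...) {
  cat(sprintf("<mwas_fit: OR %.3f (%.3f-%.3f), p=%.3g, n_exposed=%d%s>\n",
              x$or_estimate, x$ci_low, x$ci_high, x$p_nominal, x$n_exposed,
              if (x$separation_flag) ", SEPARATION" else ""))
  invisible(x)
}

#' Screen specification
#'
#' @param outcomes outcome names (columns of the cohort).
#' @param medications medication variable names (post inclusion filter).
#' @param covariate_names comorbidity columns used for adjustment.
#' @param alpha nominal significance level (default 0.05).
#' @param bonferroni_m family size for the Bonferroni correction; defaults
#'   to `length(medications) * length(outcomes)`, the full screen. The
#'   choice of family is a reporting convention and is echoed in output
#'   headers.
#' @return object of class `screen_spec`.
#' @export
screen_spec <- function(outcomes, medications, covariate_names,
                        alpha = 0.05, bonferroni_m = NULL) {
  if (is.null(bonferroni_m)) {
    bonferroni_m <- length(medications) * length(outcomes)
  }
  stopifnot(alpha > 0, alpha < 1,
            bonferroni_m >= length(medications) * length(outcomes))
  structure(list(outcomes = outcomes, medications = medications,
                 covariate_names = covariate_names, alpha = alpha,
                 bonferroni_m = bonferroni_m), class = "screen_spec")
}

#' Run the medication-wide association screen
#'
#' Fits one adjusted logistic regression per medication x outcome pair
#' (outcome on intercept + exposure + maternal age + comorbidity flags),
#' each medication assessed separately as a binary exposure, and applies
#' the Bonferroni correction across the whole screen:
#' `p_bonferroni = min(1, p_nominal * m)`. Significance flags follow the
#' screening convention: `sig_nominal` iff `p_nominal <= alpha`;
#' `sig_bonferroni` iff additionally `p_bonferroni <= alpha`. Degenerate
#' pairs (constant outcome or exposure) yield a flagged row and the screen
#' continues.
#'
#' Internally, deliveries sharing an identical (outcome, exposure,
#' covariate) pattern are collapsed into weighted rows before fitting —
#' an exact reformulation that changes no reported number — and each fit is
#' warm-started from the per-outcome baseline model.
#'
#' @param spec a [screen_spec()].
#' @param exposures an `exposure_matrix` (or plain 0/1 matrix with
#'   delivery_id rownames).
#' @param covs a [build_covariates()] matrix.
#' @param cohort a [build_cohort()] result supplying the outcome columns.
#' @return data.frame of class `mwas_results`, one row per medication x
#'   outcome, ordered by (medication, outcome); attributes `alpha` and
#'   `bonferroni_m`.
#' @export
run_screen <- function(spec, exposures, covs, cohort) {
  stopifnot(inherits(spec, "screen_spec"))
  em <- if (inherits(exposures, "exposure_matrix")) exposures$matrix else exposures
  if (!identical(rownames(em), cohort$delivery_id) ||
      !identical(rownames(covs), cohort$delivery_id)) {
    stop("exposure, covariate and cohort tables are not aligned on delivery_id",
         call. = FALSE)
  }
  missing_meds <- setdiff(spec$medications, colnames(em))
  if (length(missing_meds) > 0) {
    stop(sprintf("medications absent from exposure matrix: %s",
                 paste(missing_meds, collapse = ", ")), call. = FALSE)
  }
  adjm <- as.matrix(covs[, c("maternal_age", spec$covariate_names),
                         drop = FALSE])
  n <- nrow(adjm)
  X0 <- cbind(`(Intercept)` = 1, adjm)
  enc <- if (n > 2000) encode_rows(adjm) else NULL
  # warm start every medication fit from the per-outcome baseline model
  starts <- lapply(spec$outcomes, function(oc) {
    y <- as.numeric(cohort[[oc]])
    if (length(unique(y)) < 2) return(NULL)
    b0 <- ml_logit(X0, y)$coef
    if (anyNA(b0)) return(NULL)
    c(b0[1], exposure = 0, b0[-1])
  })
  names(starts) <- spec$outcomes

  fit_pair <- function(y, x, start) {
    check_binary_pair(y, x)
    if (!is.null(enc)) {
      key <- (enc$key * 2 + y) * 2 + x
      first <- which(!duplicated(key))
      idx <- match(key, key[first])
      w <- tabulate(idx, length(first))
      Xu <- cbind(`(Intercept)` = 1, exposure = x[first],
                  adjm[first, , drop = FALSE])
      fit <- ml_logit(Xu, y[first], weights = w, start = start)
      summarize_exposure_fit(fit, Xu, sum(x), n)
    } else {
      fit_single(y, x, adjm, start = start)
    }
  }

  rows <- vector("list", length(spec$medications) * length(spec$outcomes))
  i <- 0
  for (med in spec$medications) {
    for (oc in spec$outcomes) {
      i <- i + 1
      res <- tryCatch(
        fit_pair(as.numeric(cohort[[oc]]), as.numeric(em[, med]),
                 starts[[oc]]),
        mwas_degenerate = function(e) e)
      if (inherits(res, "mwas_degenerate")) {
        rows[[i]] <- data.frame(
          medication = med, outcome = oc, n_exposed = sum(em[, med]),
          or_estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          p_nominal = NA_real_, log_or = NA_real_, se = NA_real_,
          converged = FALSE, separation_flag = FALSE,
          note = conditionMessage(res), stringsAsFactors = FALSE)
      } else {
        rows[[i]] <- data.frame(
          medication = med, outcome = oc, n_exposed = res$n_exposed,
          or_estimate = res$or_estimate, ci_low = res$ci_low,
          ci_high = res$ci_high, p_nominal = res$p_nominal,
          log_or = res$log_or, se = res$se, converged = res$converged,
          separation_flag = res$separation_flag, note = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_nominal * spec$bonferroni_m)
  out$sig_nominal <- as.integer(!is.na(out$p_nominal) &
                                  out$p_nominal <= spec$alpha)
  out$sig_bonferroni <- as.integer(out$sig_nominal == 1L &
                                     !is.na(out$p_bonferroni) &
                                     out$p_bonferroni <= spec$alpha)
  out <- out[order(match(out$medication, spec$medications),
                   match(out$outcome, spec$outcomes)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- spec$alpha
  attr(out, "bonferroni_m") <- spec$bonferroni_m
  class(out) <- c("mwas_results", "data.frame")
  out
}

#' Adjusted covariate effects per outcome
#'
#' Fits the baseline adjusted model (outcome on intercept + maternal age +
#' comorbidity flags, no medication) for each outcome and reports each
#' adjustment term's odds ratio, Wald interval and p-value. Used for the
#' covariate panels of forest exports.
#'
#' @param cohort a [build_cohort()] result.
#' @param covs a [build_covariates()] matrix aligned with the cohort.
#' @param outcomes outcome columns to model; default: all in the cohort.
#' @return data.frame with columns `outcome`, `term`, `or_estimate`,
#'   `ci_low`, `ci_high`, `p_nominal`.
#' @export
fit_covariate_effects <- function(cohort, covs, outcomes = NULL) {
  if (is.null(outcomes)) {
    outcomes <- setdiff(names(cohort),
                        c("patient_id", "delivery_id", "delivery_date"))
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(covs))
  out <- lapply(outcomes, function(oc) {
    fit <- ml_logit(X, as.numeric(cohort[[oc]]))
    terms <- setdiff(colnames(X), "(Intercept)")
    b <- fit$coef[terms]
    se <- fit$se[terms]
    data.frame(outcome = oc, term = terms, or_estimate = exp(b),
               ci_low = exp(b - z975 * se), ci_high = exp(b + z975 * se),
               p_nominal = 2 * stats::pnorm(-abs(b / se)),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare adjusted and unadjusted model fit
#'
#' Goodness-of-fit comparison of a covariate-adjusted fit against the
#' unadjusted (exposure-only) fit on the same deliveries: log-likelihoods,
#' AIC, and the likelihood-ratio statistic with degrees of freedom equal to
#' the difference in fitted parameters. Reports only; performs no model
#' selection.
#'
#' @param adjusted,unadjusted [fit_single()] results fit on identical rows.
#' @return list with `loglik_adjusted`, `loglik_unadjusted`,
#'   `aic_adjusted`, `aic_unadjusted`, `lr_statistic`, `df`, `p_value`.
#' @export
compare_goodness_of_fit <- function(adjusted, unadjusted) {
  stopifnot(inherits(adjusted, "mwas_fit"), inherits(unadjusted, "mwas_fit"))
  if (adjusted$n != unadjusted$n || adjusted$n_exposed != unadjusted$n_exposed) {
    stop("models were not fit on identical rows", call. = FALSE)
  }
  lr <- 2 * (adjusted$loglik - unadjusted$loglik)
  df <- adjusted$df - unadjusted$df
  list(loglik_adjusted = adjusted$loglik,
       loglik_unadjusted = unadjusted$loglik,
       aic_adjusted = adjusted$aic, aic_unadjusted = unadjusted$aic,
       lr_statistic = lr, df = df,
       p_value = if (df > 0) stats::pchisq(lr, df, lower.tail = FALSE)
                 else NA_real_)
}
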
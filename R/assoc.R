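## Association models: linear mixed-effects models (one per AP shape
## property, plus the percent-fibrosis model) with a per-patient random
## intercept, binomial logistic regressions for arrhythmia outcomes, and
## the drug-induced-vs-spontaneous two-sample t-test.
##
## Defaults: REML estimation; p-values from Wald-type t-tests with
## Satterthwaite denominator degrees of freedom (lmerTest), which stay
## calibrated at the small patient counts typical of surgical cohorts;
## plain Wald-normal p-values are available via `p_method = "wald"`. The
## reported adjusted R-squared is the OLS adjusted R-squared of the
## fixed-effects-only fit — a convention choice, since adjusted R-squared
## has no unique mixed-model definition.

#' Specification of one association model
#'
#' @param dependent response column name (one of the seven AP properties
#'   or `percent_fibrosis`).
#' @param fixed_effects ordered character vector of covariate column
#'   names.
#' @param random_intercept grouping column for the random intercept.
#' @param estimation `"REML"` (default) or `"ML"`.
#' @param p_method `"satterthwaite"` (default) or `"wald"` (normal
#'   approximation).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(dependent,
                       fixed_effects = setdiff(.cohort_covariates,
                                               character(0)),
                       random_intercept = "patient_id",
                       estimation = c("REML", "ML"),
                       p_method = c("satterthwaite", "wald")) {
  structure(list(dependent = dependent, fixed_effects = fixed_effects,
                 random_intercept = random_intercept,
                 estimation = match.arg(estimation),
                 p_method = match.arg(p_method)),
            class = "model_spec")
}

#' Fit a linear mixed-effects association model
#'
#' Fits `dependent ~ fixed_effects + (1 | patient)` on a long-format
#' feature table (one row per location x frequency observation) and
#' returns fixed-effect estimates, p-values, and the adjusted R-squared of
#' the fixed-effects-only OLS fit. A singular fit (between-patient
#' variance estimated at zero) is reported, not hidden; in that degenerate
#' case the estimates coincide with ordinary least squares.
#'
#' @param feature_table data.frame containing the dependent, all
#'   covariates, and the grouping column.
#' @param spec a [model_spec()].
#' @return object of class `assoc_result`: `coefficients` (term, estimate,
#'   se, df, statistic, p_value), `adj_r2`, `n_obs`, `n_groups`,
#'   `singular`, `converged`.
#' @export
fit_ap_mixed_model <- function(feature_table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c(spec$dependent, spec$fixed_effects, spec$random_intercept)
  miss <- setdiff(need, names(feature_table))
  check_that(!length(miss), "covariate '%s' absent from the feature table",
             miss[1])
  grp <- feature_table[[spec$random_intercept]]
  check_that(length(unique(grp)) >= 2,
             "random-intercept grouping '%s' needs >= 2 levels",
             spec$random_intercept)

  fe <- paste(spec$fixed_effects, collapse = " + ")
  fml <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)", spec$dependent, fe,
                                   spec$random_intercept))
  fit <- suppressMessages(
    lmerTest::lmer(fml, data = feature_table,
                   REML = spec$estimation == "REML"))
  conv <- fit@optinfo$conv$lme4
  converged <- is.null(conv$messages) ||
    !any(grepl("failed to converge", conv$messages))
  if (!converged)
    warning(sprintf("mixed model for %s did not converge: %s",
                    spec$dependent, paste(conv$messages, collapse = "; ")))
  singular <- lme4::isSingular(fit)

  ct <- stats::coef(summary(fit))
  p <- if (spec$p_method == "satterthwaite") ct[, "Pr(>|t|)"]
       else 2 * stats::pnorm(-abs(ct[, "t value"]))
  coefs <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                      se = ct[, "Std. Error"],
                      df = if ("df" %in% colnames(ct)) ct[, "df"] else NA_real_,
                      statistic = ct[, "t value"], p_value = p,
                      row.names = NULL)

  ols <- stats::lm(stats::as.formula(sprintf("%s ~ %s", spec$dependent, fe)),
                   data = feature_table)
  structure(list(dependent = spec$dependent, coefficients = coefs,
                 adj_r2 = summary(ols)$adj.r.squared,
                 n_obs = stats::nobs(fit),
                 n_groups = length(unique(grp)),
                 estimation = spec$estimation, p_method = spec$p_method,
                 singular = singular, converged = converged, fit = fit),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %s: %d obs, %d patients, adj R2 = %.2f%s%s\n",
              x$dependent, x$n_obs, x$n_groups, x$adj_r2,
              if (x$singular) " [singular fit]" else "",
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(transform(x$coefficients,
                  estimate = signif(estimate, 4), se = signif(se, 3),
                  df = round(df, 1), statistic = signif(statistic, 3),
                  p_value = signif(p_value, 3)), row.names = FALSE)
  invisible(x)
}

#' Fit the percent-fibrosis mixed model
#'
#' Percent-fibrosis (per section) as the dependent variable, patient as
#' random effect, and clinical parameters, electrophysiological tissue
#' abnormalities and AP properties at 1 Hz pacing as fixed effects.
#'
#' @param patient_table per-section table (see
#'   [generate_fibrosis_table()]); must contain `percent_fibrosis`.
#' @param spec optional [model_spec()]; defaults to the standard fibrosis
#'   covariate set present in the table.
#' @return an `assoc_result` (see [fit_ap_mixed_model()]).
#' @export
fit_fibrosis_model <- function(patient_table, spec = NULL) {
  if (is.null(spec)) {
    std <- c(setdiff(.cohort_covariates, "stim_frequency"),
             "rmp_1hz", "apa_1hz", "auc90_1hz")
    spec <- model_spec("percent_fibrosis",
                       fixed_effects = intersect(std, names(patient_table)))
  }
  fit_ap_mixed_model(patient_table, spec)
}

## Firth bias-reduced logistic regression (Newton-Raphson on the modified
## score); used as the penalised fallback under perfect separation.
.firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- numeric(ncol(X))
  Iinv <- NULL
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(X %*% beta))
    w <- pmax(p * (1 - p), 1e-12)
    XW <- X * w
    Iinv <- solve(crossprod(X, XW))
    h <- rowSums((X %*% Iinv) * XW)
    U <- crossprod(X, (y - p) + h * (0.5 - p))
    delta <- drop(Iinv %*% U)
    if (any(!is.finite(delta))) break
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  list(coef = beta, se = sqrt(diag(Iinv)))
}

#' Binomial logistic regression for arrhythmia outcomes
#'
#' Standard maximum-likelihood logistic regression; under (quasi-)perfect
#' separation the fit is flagged and refitted with Firth's bias-reduced
#' penalised likelihood, reported as such.
#'
#' @param patient_table one row per patient.
#' @param dependent binary outcome column (e.g. `tissue_arrhythmia` or
#'   `clinical_arrhythmia`); both classes must be present.
#' @param covariates character vector of covariate columns.
#' @return data.frame (term, estimate, se, statistic, p_value) with
#'   attributes `separation` (logical) and `method` ("ml" or "firth").
#' @export
fit_logistic <- function(patient_table, dependent, covariates) {
  miss <- setdiff(c(dependent, covariates), names(patient_table))
  check_that(!length(miss), "covariate '%s' absent from the table", miss[1])
  y <- patient_table[[dependent]]
  check_that(length(unique(y[!is.na(y)])) == 2,
             "single-class outcome: '%s' must contain both classes", dependent)
  fml <- stats::as.formula(paste(dependent, "~",
                                 paste(covariates, collapse = " + ")))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = patient_table, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!sep && any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) sep <- TRUE
  if (sep) {
    mf <- stats::model.frame(fml, patient_table)
    X <- stats::model.matrix(fml, mf)
    fb <- .firth_logistic(X, as.numeric(stats::model.response(mf)))
    z <- fb$coef / fb$se
    out <- data.frame(term = colnames(X), estimate = fb$coef, se = fb$se,
                      statistic = z, p_value = 2 * stats::pnorm(-abs(z)),
                      row.names = NULL)
    attr(out, "separation") <- TRUE
    attr(out, "method") <- "firth"
    warning(sprintf("perfect separation in logistic model for %s; reporting Firth penalised fit",
                    dependent))
    return(out)
  }
  ct <- stats::coef(summary(fit))
  out <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                    se = ct[, "Std. Error"], statistic = ct[, "z value"],
                    p_value = ct[, "Pr(>|z|)"], row.names = NULL)
  attr(out, "separation") <- FALSE
  attr(out, "method") <- "ml"
  out
}

#' Compare AP properties between drug-induced and spontaneous arrhythmias
#'
#' Two-sided two-sample t-test per AP property across all pacing
#' frequencies, between location summaries from tissue with drug-induced
#' versus spontaneous arrhythmias.
#'
#' @param location_summaries [summarise_location()]-style table with an
#'   additional grouping column.
#' @param group_col name of the grouping column (two levels).
#' @param properties property columns to test.
#' @param var_equal passed to [stats::t.test()] (default Welch).
#' @return data.frame: property, group means, t, df, p_value.
#' @export
ttest_drug_vs_spontaneous <- function(location_summaries,
                                      group_col = "provenance",
                                      properties = c("rmp", "apa", "dvdt_max",
                                                     "apd20", "apd50", "apd90",
                                                     "auc90"),
                                      var_equal = FALSE) {
  g <- factor(location_summaries[[group_col]])
  check_that(nlevels(g) == 2, "grouping column '%s' must have two levels",
             group_col)
  check_that(all(table(g) >= 2), "each group needs >= 2 observations")
  out <- lapply(properties, function(p) {
    x <- location_summaries[[p]]
    tt <- stats::t.test(x ~ g, var.equal = var_equal)
    data.frame(property = p,
               mean_1 = tt$estimate[1], mean_2 = tt$estimate[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, row.names = NULL)
  })
  res <- do.call(rbind, out)
  attr(res, "groups") <- levels(g)
  res
}

#' Assemble per-dependent model results into one wide table
#'
#' Rows are covariates in the standard order, with an (estimate, p) column
#' pair per dependent variable and an adjusted-R-squared footer attribute.
#' Estimates significant at p < 0.05 (strict) are flagged in the companion
#' logical matrix attribute `"significant"`. A missing dependent produces
#' a warning and a blanked column pair.
#'
#' @param results list of `assoc_result` objects (ideally all seven AP
#'   dependents).
#' @param dependents expected dependents, in column order.
#' @return data.frame with a `term` column and `est_*` / `p_*` columns.
#' @export
render_results_table <- function(results,
                                 dependents = .ap_dependents) {
  names(results) <- vapply(results, `[[`, character(1), "dependent")
  missing_dep <- setdiff(dependents, names(results))
  if (length(missing_dep))
    warning(sprintf("no results for dependent(s): %s; column(s) blanked",
                    paste(missing_dep, collapse = ", ")))
  terms <- c("(Intercept)", .cohort_covariates)
  out <- data.frame(term = terms)
  sig <- matrix(FALSE, length(terms), length(dependents),
                dimnames = list(terms, dependents))
  r2 <- stats::setNames(rep(NA_real_, length(dependents)), dependents)
  for (d in dependents) {
    est <- p <- rep(NA_real_, length(terms))
    if (d %in% names(results)) {
      co <- results[[d]]$coefficients
      i <- match(co$term, terms)
      est[i] <- co$estimate
      p[i] <- co$p_value
      r2[d] <- results[[d]]$adj_r2
    }
    out[[paste0("est_", d)]] <- est
    out[[paste0("p_", d)]] <- p
    sig[, d] <- !is.na(p) & p < 0.05
  }
  attr(out, "significant") <- sig
  attr(out, "adj_r2") <- r2
  out
}
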
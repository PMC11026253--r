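## Cohort-level synthetic feature tables drawn from a linear mixed-effects
## generating model: response = intercept + sum(coef * covariate) +
## patient random intercept + residual. Default coefficients emulate the
## fixed-effect estimates reported for a mixed repaired/unrepaired TOF + ASD
## RVOT cohort, with treatment coding against the reference levels ASD,
## unrepaired, acyanotic, mild RV-PA gradient, no beta blocker, none/mild
## proBNP, no clinical arrhythmia.

.ap_dependents <- c("rmp", "apa", "dvdt_max", "apd20", "apd50", "apd90", "auc90")

.cohort_covariates <- c("stim_frequency", "disease_tof", "repaired",
                        "age_years", "cyanosis", "rvpa_moderate",
                        "rvpa_severe", "probnp_severe", "beta_blocker",
                        "clinical_arrhythmia", "tissue_arrhythmia",
                        "impaired_apd_shortening", "apd_alternans")

#' Default generating fixed effects for the AP shape properties
#'
#' One named coefficient vector per dependent variable (units: mV for
#' RMP/APA, V/s for dV/dt_max, ms for APD, mV*s for AUC90), in the standard
#' covariate order. Intercepts correspond to the reference category of every
#' categorical covariate at 0 Hz / age 0.
#'
#' @return named list of named numeric vectors.
#' @export
default_fixed_effects <- function() {
  row <- function(...) {
    x <- c(...)
    names(x) <- c("(Intercept)", .cohort_covariates)
    x
  }
  list(
    rmp      = row(-73.40,   0.38,  -3.98,   0.11, 0.10,   1.81,   1.35,   0.48,  -0.72,  -1.63,   0.30,   0.78,   -0.59,   1.05),
    apa      = row( 82.87,  -1.38,   5.06,  -0.57, 0.01,  -4.17,  13.38,   5.36,   3.78,   6.05,  -1.81,   5.11,    2.42,   2.35),
    dvdt_max = row(124.16, -15.85,  17.89,  76.90, -1.59, -31.32,  36.16,   2.27,  11.88,  29.94,  27.32,  15.28,  -34.58,  10.71),
    apd20    = row(112.16, -22.78,  -5.02, -59.93, 1.50,   2.00, -21.60, -10.88,  23.42,   8.87, -12.22,  27.92,   52.68,  28.82),
    apd50    = row(157.43, -37.32,  29.16, -31.86, 1.56,  21.05,  12.26,  20.47,  26.36,  25.18, -29.27,  43.80,   93.51,   6.67),
    apd90    = row(217.62, -41.46,  37.08,  12.30, 0.98,  41.21,  41.16,  45.84,  16.37,  31.39, -56.37,  41.41,  127.82, -24.15),
    auc90    = row( 11.86,  -3.22,   3.49,  -2.74, 0.16,   1.15,   3.51,   2.73,   2.80,   3.13,  -2.80,   4.52,    8.17,   0.42))
}

#' Default marginal prevalences of the categorical covariates
#'
#' Prevalences emulate a 25-patient surgical RVOT cohort: 22/25 TOF, 6/25
#' repaired with prolonged QRS, 9/25 cyanotic, RV-PA gradient 12/2/11
#' mild/moderate/severe, 9/25 on beta blockers, 12/25 with severe proBNP
#' elevation, 6/25 with post-operative clinical arrhythmias, 13/25 with
#' tissue arrhythmias, 6/25 with impaired APD shortening, 12/25 with APD
#' alternans.
#'
#' @return named list of probabilities (the RV-PA gradient entry is a
#'   three-level probability vector).
#' @export
default_covariate_frequencies <- function() {
  list(disease_tof = 22 / 25, repaired = 6 / 25, cyanosis = 9 / 25,
       rvpa = c(mild = 12 / 25, moderate = 2 / 25, severe = 11 / 25),
       probnp_severe = 12 / 25, beta_blocker = 9 / 25,
       clinical_arrhythmia = 6 / 25, tissue_arrhythmia = 13 / 25,
       impaired_apd_shortening = 6 / 25, apd_alternans = 12 / 25)
}

#' Cohort generating model
#'
#' @param fixed_effects named list (one entry per dependent variable) of
#'   named coefficient vectors; names must be `"(Intercept)"` plus known
#'   covariate names (see [default_fixed_effects()]).
#' @param patient_sd named vector of between-patient random-intercept
#'   standard deviations, one per dependent (>= 0).
#' @param residual_sd named vector of within-patient residual standard
#'   deviations (> 0).
#' @param covariate_frequencies see [default_covariate_frequencies()].
#' @return an object of class `cohort_model`.
#' @export
cohort_model <- function(fixed_effects = default_fixed_effects(),
                         patient_sd = c(rmp = 2, apa = 5, dvdt_max = 25,
                                        apd20 = 15, apd50 = 20, apd90 = 25,
                                        auc90 = 2),
                         residual_sd = c(rmp = 2, apa = 4, dvdt_max = 20,
                                         apd20 = 10, apd50 = 12, apd90 = 15,
                                         auc90 = 1.5),
                         covariate_frequencies = default_covariate_frequencies()) {
  deps <- names(fixed_effects)
  check_that(length(deps) > 0, "fixed_effects must name at least one dependent")
  for (d in deps) {
    fe <- fixed_effects[[d]]
    bad <- setdiff(names(fe), c("(Intercept)", .cohort_covariates))
    check_that(!length(bad), "unknown covariate '%s' in fixed effects for %s",
               bad[1], d)
    check_that(!is.na(patient_sd[d]) && patient_sd[d] >= 0,
               "patient_sd['%s'] must be >= 0", d)
    check_that(!is.na(residual_sd[d]) && residual_sd[d] > 0,
               "residual_sd['%s'] must be > 0", d)
  }
  structure(list(fixed_effects = fixed_effects, patient_sd = patient_sd,
                 residual_sd = residual_sd,
                 covariate_frequencies = covariate_frequencies),
            class = "cohort_model")
}

## Sample one patient-level covariate table. Age (years) is sampled
## conditional on repair status: unrepaired patients are mostly infants,
## repaired patients mostly adults, emulating a bimodal surgical cohort.
.sample_patients <- function(n_patients, freqs) {
  rvpa <- sample(c("mild", "moderate", "severe"), n_patients, replace = TRUE,
                 prob = freqs$rvpa)
  repaired <- stats::rbinom(n_patients, 1, freqs$repaired)
  age <- ifelse(repaired == 1,
                stats::rlnorm(n_patients, log(27), 0.4),
                stats::rlnorm(n_patients, log(0.83), 0.8))
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n_patients)),
    disease_tof = stats::rbinom(n_patients, 1, freqs$disease_tof),
    repaired = repaired,
    age_years = age,
    cyanosis = stats::rbinom(n_patients, 1, freqs$cyanosis),
    rvpa_moderate = as.integer(rvpa == "moderate"),
    rvpa_severe = as.integer(rvpa == "severe"),
    probnp_severe = stats::rbinom(n_patients, 1, freqs$probnp_severe),
    beta_blocker = stats::rbinom(n_patients, 1, freqs$beta_blocker),
    clinical_arrhythmia = stats::rbinom(n_patients, 1, freqs$clinical_arrhythmia),
    tissue_arrhythmia = stats::rbinom(n_patients, 1, freqs$tissue_arrhythmia),
    impaired_apd_shortening = stats::rbinom(n_patients, 1,
                                            freqs$impaired_apd_shortening),
    apd_alternans = stats::rbinom(n_patients, 1, freqs$apd_alternans))
}

#' Generate a cohort feature table from a mixed-effects generating model
#'
#' One row per patient x location x pacing frequency, with all covariates
#' and one column per dependent variable. Each response equals the linear
#' predictor plus a per-patient random intercept (independent across
#' dependents) plus residual noise.
#'
#' @param model a [cohort_model()].
#' @param n_patients number of patients (>= 2).
#' @param locations_per_patient recording locations per patient.
#' @param freqs pacing frequencies, Hz.
#' @param seed integer seed (reproducible tables).
#' @return data.frame; the per-patient random intercepts are attached as
#'   attribute `"random_intercepts"` (patient x dependent data.frame).
#' @export
generate_cohort <- function(model = cohort_model(), n_patients = 25,
                            locations_per_patient = 3,
                            freqs = c(0.5, 1, 2, 3, 4), seed = 1) {
  stopifnot(inherits(model, "cohort_model"))
  check_that(n_patients >= 2, "n_patients must be >= 2")
  set.seed(seed)
  pats <- .sample_patients(n_patients, model$covariate_frequencies)
  grid <- expand.grid(freq_i = seq_along(freqs),
                      location_id = sprintf("L%02d", seq_len(locations_per_patient)),
                      patient_id = pats$patient_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- merge(grid, pats, by = "patient_id", sort = FALSE)
  tab$stim_frequency <- freqs[tab$freq_i]
  tab$freq_i <- NULL
  tab <- tab[order(tab$patient_id, tab$location_id, tab$stim_frequency), ]
  rownames(tab) <- NULL

  deps <- names(model$fixed_effects)
  ranef <- data.frame(patient_id = pats$patient_id)
  for (d in deps) {
    fe <- model$fixed_effects[[d]]
    lp <- rep(fe[["(Intercept)"]], nrow(tab))
    for (cv in setdiff(names(fe), "(Intercept)"))
      lp <- lp + fe[[cv]] * tab[[cv]]
    b <- stats::rnorm(n_patients, 0, model$patient_sd[d])
    ranef[[d]] <- b
    names(b) <- pats$patient_id
    tab[[d]] <- lp + b[tab$patient_id] +
      stats::rnorm(nrow(tab), 0, model$residual_sd[d])
  }
  attr(tab, "random_intercepts") <- ranef
  tab
}

#' Generate a per-section percent-fibrosis table
#'
#' Companion generator for the fibrosis association model: one row per
#' patient x histology section, with patient-level clinical covariates, AP
#' properties at 1 Hz pacing (RMP, APA, AUC90 as continuous covariates,
#' sampled around typical values), and a percent-fibrosis response equal to
#' the linear predictor plus a patient random intercept plus per-section
#' noise. Continuous AP covariates enter the linear predictor centred at
#' their sampling means so the intercept stays on the percent scale.
#'
#' @param fixed_effects named coefficient vector; allowed names are
#'   `"(Intercept)"`, the standard categorical covariates, `age_years`, and
#'   the 1-Hz AP properties `rmp_1hz`, `apa_1hz`, `auc90_1hz`.
#' @param patient_sd,section_sd random-intercept and per-section noise SD
#'   (percentage points).
#' @param n_patients,sections_per_patient cohort dimensions.
#' @param covariate_frequencies see [default_covariate_frequencies()].
#' @param seed integer seed.
#' @return data.frame with one row per section and a `percent_fibrosis`
#'   column; per-patient random intercepts attached as attribute
#'   `"random_intercepts"`.
#' @export
generate_fibrosis_table <- function(fixed_effects = c("(Intercept)" = 12,
                                                      repaired = 20.4,
                                                      tissue_arrhythmia = -7.0,
                                                      auc90_1hz = 11.1),
                                    patient_sd = 3, section_sd = 3,
                                    n_patients = 25, sections_per_patient = 30,
                                    covariate_frequencies = default_covariate_frequencies(),
                                    seed = 1) {
  ap_means <- c(rmp_1hz = -73, apa_1hz = 90, auc90_1hz = 12)
  ap_sds <- c(rmp_1hz = 3, apa_1hz = 8, auc90_1hz = 1.5)
  allowed <- c("(Intercept)", setdiff(.cohort_covariates, "stim_frequency"),
               names(ap_means))
  bad <- setdiff(names(fixed_effects), allowed)
  check_that(!length(bad), "unknown covariate '%s' in fibrosis fixed effects",
             bad[1])
  check_that(n_patients >= 2, "n_patients must be >= 2")
  set.seed(seed)
  pats <- .sample_patients(n_patients, covariate_frequencies)
  for (v in names(ap_means))
    pats[[v]] <- stats::rnorm(n_patients, ap_means[v], ap_sds[v])
  lp <- rep(fixed_effects[["(Intercept)"]], n_patients)
  for (cv in setdiff(names(fixed_effects), "(Intercept)")) {
    x <- pats[[cv]]
    if (cv %in% names(ap_means)) x <- x - ap_means[cv]
    lp <- lp + fixed_effects[[cv]] * x
  }
  b <- stats::rnorm(n_patients, 0, patient_sd)
  tab <- pats[rep(seq_len(n_patients), each = sections_per_patient), ]
  tab$section_id <- sprintf("S%02d", rep(seq_len(sections_per_patient), n_patients))
  tab$percent_fibrosis <- rep(lp + b, each = sections_per_patient) +
    stats::rnorm(nrow(tab), 0, section_sd)
  rownames(tab) <- NULL
  attr(tab, "random_intercepts") <-
    data.frame(patient_id = pats$patient_id, percent_fibrosis = b)
  tab
}

#' Write / read the cohort table as CSV
#' @param tab cohort data.frame.
#' @param path CSV path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the table.
#' @export
write_cohort <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) utils::read.csv(path)
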
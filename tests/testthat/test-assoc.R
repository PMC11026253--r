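test_that("zero between-patient variance reproduces OLS estimates", {
  m <- cohort_model(patient_sd = c(apd90 = 1e-12),
                    residual_sd = c(apd90 = 15),
                    fixed_effects = default_fixed_effects()["apd90"])
  tab <- generate_cohort(m, n_patients = 15, seed = 4)
  covs <- c("stim_frequency", "cyanosis", "repaired", "tissue_arrhythmia")
  fit <- fit_ap_mixed_model(tab, model_spec("apd90", fixed_effects = covs))
  ols <- lm(apd90 ~ stim_frequency + cyanosis + repaired + tissue_arrhythmia,
            data = tab)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)), tolerance = 1e-6)
})

test_that("mixed model recovers a generating slope and reports metadata", {
  tab <- generate_cohort(seed = 10)
  fit <- fit_ap_mixed_model(tab, model_spec("apd90"))
  co <- fit$coefficients
  i <- co$term == "stim_frequency"
  expect_lt(abs(co$estimate[i] - (-41.46)), 2 * co$se[i])
  expect_equal(fit$n_obs, nrow(tab))
  expect_equal(fit$n_groups, 25)
  expect_true(is.finite(fit$adj_r2))
  expect_true(all(co$p_value >= 0 & co$p_value <= 1))
})

test_that("missing covariates and degenerate grouping raise named errors", {
  tab <- generate_cohort(seed = 1)
  expect_error(fit_ap_mixed_model(tab, model_spec("apd90",
                                                  fixed_effects = "not_there")),
               "not_there")
  one <- tab[tab$patient_id == "P01", ]
  expect_error(fit_ap_mixed_model(one, model_spec("apd90")), ">= 2 levels")
})

test_that("fibrosis model recovers the repaired-status effect", {
  tab <- generate_fibrosis_table(seed = 4)
  fit <- fit_fibrosis_model(tab)
  co <- fit$coefficients
  i <- co$term == "repaired"
  expect_lt(abs(co$estimate[i] - 20.4), 2 * co$se[i])
  j <- co$term == "auc90_1hz"
  expect_lt(abs(co$estimate[j] - 11.1), 2 * co$se[j])
})

test_that("logistic regression recovers log-odds; separation is flagged", {
  set.seed(2)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  d <- data.frame(tissue_arrhythmia = rbinom(n, 1, plogis(-0.5 + 1.5 * x)),
                  repaired = x)
  lg <- fit_logistic(d, "tissue_arrhythmia", "repaired")
  i <- lg$term == "repaired"
  expect_lt(abs(lg$estimate[i] - 1.5), 2 * lg$se[i])
  expect_false(attr(lg, "separation"))

  d0 <- data.frame(y = rep(0L, 10), x = rbinom(10, 1, 0.5))
  expect_error(fit_logistic(d0, "y", "x"), "single-class")

  dsep <- data.frame(y = c(0, 0, 0, 0, 1, 1, 1, 1),
                     x = c(0, 0, 0, 0, 1, 1, 1, 1))
  lg2 <- suppressWarnings(fit_logistic(dsep, "y", "x"))
  expect_true(attr(lg2, "separation"))
  expect_equal(attr(lg2, "method"), "firth")
  expect_true(all(is.finite(lg2$se)))
})

test_that("drug-vs-spontaneous t-test behaves on constructed groups", {
  base <- data.frame(rmp = c(1, 2, 3, 1, 2, 3), apa = c(4, 5, 6, 4, 5, 6),
                     dvdt_max = 1, apd20 = 1, apd50 = 1, apd90 = 1, auc90 = 1,
                     provenance = rep(c("drug", "spontaneous"), each = 3))
  tt <- ttest_drug_vs_spontaneous(base, properties = c("rmp", "apa"))
  expect_equal(tt$t, c(0, 0))
  expect_equal(tt$p_value, c(1, 1))

  set.seed(3)
  sep <- data.frame(apa = c(rnorm(20, 100, 1), rnorm(20, 105, 1)),
                    provenance = rep(c("drug", "spontaneous"), each = 20))
  tt2 <- ttest_drug_vs_spontaneous(sep, properties = "apa")
  expect_lt(tt2$p_value, 0.001)

  bad <- data.frame(apa = c(1, 2, 3),
                    provenance = c("drug", "drug", "spontaneous"))
  expect_error(ttest_drug_vs_spontaneous(bad, properties = "apa"),
               ">= 2 observations")
})

test_that("results table has the canonical layout and significance marks", {
  tab <- generate_cohort(seed = 6)
  fits <- lapply(c("rmp", "apa", "dvdt_max", "apd20", "apd50", "apd90",
                   "auc90"),
                 function(d) fit_ap_mixed_model(tab, model_spec(d)))
  out <- render_results_table(fits)
  expect_equal(nrow(out), 14)                      # intercept + 13 covariates
  expect_equal(sum(out$term != "(Intercept)"), 13)
  expect_equal(ncol(out), 1 + 2 * 7)               # (est, p) pair per dependent
  sig <- attr(out, "significant")
  expect_identical(unname(sig[, "apd90"]),
                   unname(!is.na(out$p_apd90) & out$p_apd90 < 0.05))

  # a missing dependent blanks its columns with a warning
  expect_warning(part <- render_results_table(fits[1:6]), "auc90")
  expect_true(all(is.na(part$est_auc90)))
})

test_that("type-I error is controlled on a small null check", {
  covs <- c("stim_frequency", "cyanosis", "beta_blocker")
  fe <- setNames(rep(0, 4), c("(Intercept)", covs))
  m <- cohort_model(fixed_effects = list(apd90 = fe),
                    patient_sd = c(apd90 = 25), residual_sd = c(apd90 = 15))
  seeds <- 7000 + seq_len(60)
  rej <- sapply(seeds, function(s) {
    tab <- generate_cohort(m, seed = s)
    fit <- fit_ap_mixed_model(tab, model_spec("apd90", fixed_effects = covs))
    fit$coefficients$p_value[-1] < 0.05
  })
  # loose smoke check at small n; the calibrated 1000-replicate check runs
  # with the acceptance suite
  expect_lt(mean(rej), 0.15)
})
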
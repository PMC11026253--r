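test_that("EAD detector: injected humps found, monotone/low-amplitude not", {
  ab <- abnormality_config(ead_prob = 1)
  sim <- generate_recording(ap_params(), 1, 8, ab, seed = 1)
  f <- extract_features(sim$recording)
  rep <- abnormality_report(f, list("1" = sim$recording))
  expect_equal(sum(rep$events$type == "ead"), nrow(sim$events))
  # each detection within 5 ms of an injected event
  for (t in rep$events$time_s[rep$events$type == "ead"])
    expect_lt(min(abs(t - sim$events$time_s)), 0.005)

  # monotone repolarisation: no events
  sim0 <- generate_recording(ap_params(), 1, 8, seed = 1)
  f0 <- extract_features(sim0$recording)
  rep0 <- abnormality_report(f0, list("1" = sim0$recording))
  expect_equal(nrow(rep0$events), 0)

  # +1 mV wiggle below the 5 mV default threshold: no events
  ab1 <- abnormality_config(ead_prob = 1, ead_amp_mV = 1)
  sim1 <- generate_recording(ap_params(), 1, 8, ab1, seed = 1)
  f1 <- extract_features(sim1$recording)
  rep1 <- abnormality_report(f1, list("1" = sim1$recording))
  expect_equal(sum(rep1$events$type == "ead"), 0)
})

test_that("extrasystole vs couplet classification is exclusive", {
  # two spontaneous AP 250 ms apart form one couplet, not two extrasystoles
  w <- data.frame(t_act_s = c(1, 2, 2.25, 3), stimulated = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(detect_spontaneous_couplets(w), 2)
  expect_equal(length(detect_extrasystoles(w)), 0)
  # 800 ms apart: two extrasystoles, no couplet
  w2 <- data.frame(t_act_s = c(1, 2, 2.8, 4), stimulated = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(detect_extrasystoles(w2), c(2, 2.8))
  expect_equal(length(detect_spontaneous_couplets(w2)), 0)
  # clean train: nothing
  w3 <- data.frame(t_act_s = 1:5, stimulated = TRUE)
  expect_equal(length(detect_extrasystoles(w3)), 0)
})

test_that("injected extrasystoles and couplets are recovered end to end", {
  ab <- abnormality_config(extrasystole_prob = 0.5, couplet_prob = 0.3)
  for (s in 1:5) {
    sim <- generate_recording(ap_params(), 1, 10, ab, seed = s)
    f <- extract_features(sim$recording)
    rep <- abnormality_report(f, list("1" = sim$recording))
    expect_equal(sum(rep$events$type == "extrasystole"),
                 sum(sim$events$type == "extrasystole"))
    expect_equal(sum(rep$events$type == "couplet"),
                 sum(sim$events$type == "couplet"))
    expect_equal(rep$tissue_arrhythmia, nrow(sim$events) > 0)
  }
})

test_that("APD alternans rule: magnitude, alternation and length", {
  expect_true(detect_apd_alternans(c(200, 160, 200, 160, 200, 160)))
  # jitter of ~1 ms around 200 is below the 5% / 5 ms floor
  set.seed(1)
  expect_false(detect_apd_alternans(200 + rnorm(12, 0, 1)))
  # too short: indeterminate, not FALSE
  expect_true(is.na(detect_apd_alternans(c(200, 160, 200))))
  # large but non-alternating drift is not alternans
  expect_false(detect_apd_alternans(seq(260, 150, by = -10)))
})

test_that("impaired shortening flags capture failure at fast rates", {
  s <- data.frame(pacing_freq = c(1, 3), apd90 = c(250, 250))
  r <- detect_impaired_shortening(s, c("1" = 1, "3" = 0.5))
  expect_true(r$flag)
  expect_equal(r$failing_freqs, 3)

  # healthy rate adaptation at full capture: not flagged
  s2 <- data.frame(pacing_freq = c(0.5, 1, 2, 3, 4),
                   apd90 = c(280, 260, 230, 200, 180))
  r2 <- detect_impaired_shortening(s2, setNames(rep(1, 5), c(0.5, 1, 2, 3, 4)))
  expect_false(r2$flag)

  # a single slow frequency measured: indeterminate
  s3 <- data.frame(pacing_freq = 1, apd90 = 250)
  expect_true(is.na(detect_impaired_shortening(s3, c("1" = 1))$flag))
})

test_that("location report + patient rollup match the generating config", {
  wave <- ap_params()
  reports <- list()
  for (loc in 1:2) {
    ab <- if (loc == 1)
      abnormality_config(alternans_depth_ms = 40)
    else abnormality_config(capture_failure_freqs_hz = 3)
    feats <- list()
    recs <- list()
    for (fr in c(1, 3)) {
      sim <- generate_recording(wave, fr, 12, ab, seed = loc * 10 + fr)
      recs[[as.character(fr)]] <- sim$recording
      feats[[as.character(fr)]] <- extract_features(sim$recording)
    }
    reports[[paste0("L", loc)]] <- abnormality_report(do.call(rbind, feats), recs)
  }
  expect_true(isTRUE(reports$L1$apd_alternans[["1"]]))
  expect_true(reports$L2$impaired_shortening$flag)
  expect_equal(reports$L2$capture_ratios[["3"]], 0.5)
  pt <- summarise_abnormalities(reports, "P01")
  expect_true(pt$apd_alternans)
  expect_true(pt$impaired_apd_shortening)
  expect_false(pt$tissue_arrhythmias)
})
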
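test_that("segmentation: full capture, 2:1 capture, spontaneous tagging", {
  sim <- generate_recording(ap_params(), 1, 20, seed = 1)
  w <- segment_aps(sim$recording)
  expect_equal(nrow(w), 20)
  expect_true(all(w$stimulated))

  ab <- abnormality_config(capture_failure_freqs_hz = 3)
  sim2 <- generate_recording(ap_params(), 3, 20, abnormalities = ab, seed = 1)
  w2 <- segment_aps(sim2$recording)
  expect_equal(sum(w2$stimulated), 10)

  ab3 <- abnormality_config(extrasystole_prob = 1)
  sim3 <- generate_recording(ap_params(), 1, 6, abnormalities = ab3, seed = 2)
  w3 <- segment_aps(sim3$recording)
  expect_equal(sum(!w3$stimulated), sum(!sim3$aps$stimulated))
  expect_gt(sum(!w3$stimulated), 0)
})

test_that("flat or empty traces are handled as specified", {
  flat <- trace_recording(rep(-80, 5000), 10000, 0.1, 1)
  expect_equal(nrow(segment_aps(flat)), 0)       # no upstrokes, not an error
  expect_error(trace_recording(numeric(0), 10000, numeric(0), 1), "empty")
})

test_that("low-level property computations match closed forms", {
  fs <- 10000
  # RMP: constant baseline, then median under noise
  v <- rep(-80, 400)
  expect_equal(compute_rmp(v, fs, 0.04), -80)
  set.seed(42)
  vn <- -73.4 + rnorm(2000, 0, 0.5)
  expect_equal(compute_rmp(vn, fs, 0.2), median(vn[1:2000][1801:2000]))
  expect_lt(abs(compute_rmp(vn, fs, 0.2) - (-73.4)), 0.1)
  expect_true(is.na(compute_rmp(v, fs, 0.01)))   # insufficient baseline -> NA

  # APA: peak minus RMP
  expect_equal(compute_apa(c(rep(-80, 10), 35), -80), 115)
  expect_equal(compute_apa(rep(-80, 10), -80), 0)

  # dV/dt_max: -80 -> +30 mV in 1 ms is 110 V/s
  ramp <- c(rep(-80, 50), seq(-80, 30, length.out = 11), rep(30, 50))
  expect_equal(compute_dvdt_max(ramp, fs), 110)
  expect_equal(compute_dvdt_max(rep(-80, 100), fs), 0)

  # APD on an instantaneous-rise linear-fall triangle: level crossings of
  # the 300 ms ramp at 60/150/270 ms
  t_act <- 0.01
  n_pre <- t_act * fs
  fall <- seq(20, -80, length.out = 3001)        # 300 ms at 10 kHz
  tri <- c(rep(-80, n_pre), fall, rep(-80, 100))
  expect_equal(compute_apd(tri, fs, t_act, -80, 100, 0.2), 60, tolerance = 1e-3)
  expect_equal(compute_apd(tri, fs, t_act, -80, 100, 0.5), 150, tolerance = 1e-3)
  expect_equal(compute_apd(tri, fs, t_act, -80, 100, 0.9), 270, tolerance = 1e-3)
  # AUC90 of the triangle: 0.5 * (100 + 10) * 0.27 = 14.85 mV*s
  expect_equal(compute_auc90(tri, fs, t_act, -80, 270), 14.85, tolerance = 1e-3)

  # AUC90 of a 200 ms rectangle 100 mV above baseline: 20 mV*s
  rect <- c(rep(-80, n_pre), rep(20, 2000), rep(-80, 100))
  expect_equal(compute_auc90(rect, fs, t_act, -80, 200), 20, tolerance = 0.01)
})

test_that("feature closure: noise-free extraction recovers generator truth", {
  for (shape in c("linear", "sigmoidal")) {
    sim <- generate_recording(ap_params(apa_mV = 110, apd90_ms = 280,
                                        repolarisation_shape = shape),
                              pacing_freq = 1, n_beats = 8, seed = 5)
    f <- extract_features(sim$recording)
    expect_true(all(f$qc_status == "accepted"))
    tol_ms <- 1000 / sim$recording$sampling_rate
    expect_lt(max(abs(f$apd20 - sim$aps$apd20)), tol_ms)
    expect_lt(max(abs(f$apd50 - sim$aps$apd50)), tol_ms)
    expect_lt(max(abs(f$apd90 - sim$aps$apd90)), tol_ms)
    expect_lt(max(abs(f$rmp - sim$aps$rmp)), 0.5)
    expect_lt(max(abs(f$apa - sim$aps$apa)), 0.5)
    expect_lt(max(abs(f$dvdt_max - sim$aps$dvdt_max)), 1)
    expect_lt(max(abs(f$auc90 - sim$aps$auc90)), 0.05)
  }
})

test_that("APD ordering holds for every accepted AP, clean or noisy", {
  for (s in 1:4) {
    sim <- generate_recording(ap_params(), 1, 10, noise_sd = 1, seed = s)
    f <- extract_features(sim$recording)
    acc <- f[f$qc_status == "accepted", ]
    expect_true(all(acc$apd20 <= acc$apd50 & acc$apd50 <= acc$apd90))
  }
})

test_that("sampling-rate robustness: 5 vs 20 kHz agree within tolerance", {
  p <- ap_params(apa_mV = 100, apd90_ms = 250)
  f5 <- extract_features(generate_recording(p, 1, 5, seed = 1,
                                            sampling_rate = 5000)$recording)
  f20 <- extract_features(generate_recording(p, 1, 5, seed = 1,
                                             sampling_rate = 20000)$recording)
  for (prop in c("apd20", "apd50", "apd90"))
    expect_lt(abs(mean(f5[[prop]]) - mean(f20[[prop]])), 0.2)
  for (prop in c("rmp", "apa"))
    expect_lt(abs(mean(f5[[prop]]) - mean(f20[[prop]])), 0.5)
})

test_that("QC: amplitude threshold is strict 'below 75 mV'", {
  for (apa in c(70, 74.9, 75, 80, 115)) {
    sim <- generate_recording(ap_params(apa_mV = apa), 1, 5, seed = 1)
    f <- extract_features(sim$recording)
    if (apa < 75) {
      expect_true(all(f$qc_status == "rejected"), label = paste("APA", apa))
      expect_true(all(f$qc_reason == "low_amplitude"), label = paste("APA", apa))
    } else {
      expect_true(all(f$qc_status == "accepted"), label = paste("APA", apa))
    }
  }
})

test_that("QC: upstroke inside the blanking window is rejected", {
  # latency 1 ms << 5 ms blanking: insufficient separation from the artifact
  sim <- generate_recording(ap_params(), 1, 5, seed = 1, stim_latency_ms = 1)
  f <- extract_features(sim$recording)
  expect_true(all(f$qc_status == "rejected"))
  expect_true(all(f$qc_reason == "upstroke_in_artifact"))
})

test_that("QC: lowering the APA threshold never decreases acceptance", {
  sim <- generate_recording(ap_params(apa_mV = 80), 1, 10, noise_sd = 1, seed = 3)
  n_acc <- vapply(c(90, 75, 60, 40), function(thr) {
    f <- extract_features(sim$recording, apa_threshold_mV = thr)
    sum(f$qc_status == "accepted")
  }, numeric(1))
  expect_true(all(diff(n_acc) >= 0))
})

test_that("qc_ap applies the rejection hierarchy on constructed inputs", {
  base <- list(rmp = -80, apa = 100, apd90 = 250, t_act_s = 0.11,
               stimulated = TRUE, stim_time_s = 0.1, artifact_flag = FALSE)
  expect_equal(qc_ap(base)$status, "accepted")
  expect_equal(qc_ap(modifyList(base, list(rmp = NA)))$reason, "no_baseline")
  expect_equal(qc_ap(modifyList(base, list(t_act_s = 0.102)))$reason,
               "upstroke_in_artifact")
  expect_equal(qc_ap(modifyList(base, list(artifact_flag = TRUE)))$reason,
               "artifact")
  expect_equal(qc_ap(modifyList(base, list(apd90 = NA)))$reason,
               "incomplete_repolarisation")
  expect_equal(qc_ap(modifyList(base, list(apa = 74.9)))$reason,
               "low_amplitude")
  expect_equal(qc_ap(modifyList(base, list(apa = 75)))$status, "accepted")
})

test_that("location summary averages accepted AP and warns when sparse", {
  sim <- generate_recording(ap_params(), 1, 20, seed = 1)
  f <- extract_features(sim$recording)
  s <- summarise_location(f, min_aps = 20)
  expect_equal(nrow(s), 1)
  expect_equal(s$apd90, mean(f$apd90))
  expect_equal(s$n_accepted, 20)

  # alternating APDs average to the midpoint
  ab <- abnormality_config(alternans_depth_ms = 40)
  sim2 <- generate_recording(ap_params(apd90_ms = 250), 1, 20,
                             abnormalities = ab, seed = 1)
  f2 <- extract_features(sim2$recording)
  s2 <- suppressWarnings(summarise_location(f2))
  expect_equal(s2$apd90, 250, tolerance = 0.05)

  expect_warning(summarise_location(f[0, ]), "no accepted")
  expect_warning(summarise_location(f[1:5, ]), "fewer than")
})
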
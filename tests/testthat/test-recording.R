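test_that("clean paced train: stimuli spaced 1/f, one identical AP each", {
  sim <- generate_recording(ap_params(), pacing_freq = 1, n_beats = 20,
                            noise_sd = 0, seed = 1)
  expect_equal(length(sim$recording$stim_times), 20)
  expect_equal(diff(sim$recording$stim_times), rep(1, 19))
  expect_equal(nrow(sim$aps), 20)
  expect_true(all(sim$aps$stimulated))
  expect_equal(nrow(sim$events), 0)
  # identical per-beat ground truth
  expect_equal(length(unique(sim$aps$apd90)), 1)
})

test_that("same seed gives bit-identical recordings, different seed differs", {
  ab <- abnormality_config(ead_prob = 0.3, extrasystole_prob = 0.3)
  a <- generate_recording(ap_params(), 1, 10, ab, noise_sd = 1, seed = 7)
  b <- generate_recording(ap_params(), 1, 10, ab, noise_sd = 1, seed = 7)
  c <- generate_recording(ap_params(), 1, 10, ab, noise_sd = 1, seed = 8)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$events, b$events)
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("alternans depth is realised as alternating ground-truth APD", {
  ab <- abnormality_config(alternans_depth_ms = 40)
  sim <- generate_recording(ap_params(), 1, 10, ab, seed = 1)
  d <- diff(sim$aps$apd90)
  expect_equal(abs(d), rep(40, 9))
  expect_true(all(sign(d[-1]) != sign(d[-length(d)])))
})

test_that("2:1 capture failure yields half the APs and an invariant APD", {
  ab <- abnormality_config(capture_failure_freqs_hz = 3)
  sim <- generate_recording(ap_params(apd90_ms = 250), 3, n_beats = 20,
                            abnormalities = ab, seed = 2)
  expect_equal(length(sim$recording$stim_times), 20)
  expect_equal(nrow(sim$aps), 10)
  expect_equal(unique(sim$aps$apd90), 250)  # no rate adaptation when impaired
})

test_that("physically impossible APD/cycle combinations are rejected", {
  expect_error(generate_recording(ap_params(apd90_ms = 350), pacing_freq = 4,
                                  n_beats = 5, seed = 1),
               "does not fit")
  # the same request with capture failure configured is valid
  ab <- abnormality_config(capture_failure_freqs_hz = 4)
  expect_silent(generate_recording(ap_params(apd90_ms = 350), 4, 6,
                                   abnormalities = ab, seed = 1))
})

test_that("event log length equals the number of injected events", {
  ab <- abnormality_config(ead_prob = 0.5, extrasystole_prob = 0.3,
                           couplet_prob = 0.2)
  for (s in 1:5) {
    sim <- generate_recording(ap_params(), 1, 12, ab, seed = s)
    n_spont <- sum(!sim$aps$stimulated)
    n_from_events <- sum(sim$events$type == "extrasystole") +
      2 * sum(sim$events$type == "couplet")
    expect_equal(n_spont, n_from_events)
    expect_equal(sum(sim$aps$has_ead), sum(sim$events$type == "ead"))
  }
})

test_that("trace CSV + sidecar round-trips", {
  sim <- generate_recording(ap_params(), 2, 5, seed = 3)
  rec <- sim$recording
  pre <- file.path(tempdir(), "trace_rt")
  write_trace(rec, pre, seed = 3)
  back <- read_trace(paste0(pre, ".csv"))
  expect_equal(back$samples, rec$samples, tolerance = 1e-8)
  expect_equal(back$stim_times, rec$stim_times)
  expect_equal(back$pacing_freq, rec$pacing_freq)
})
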
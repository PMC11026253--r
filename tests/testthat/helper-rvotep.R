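# shared fixture builders; everything is generated in code at test time

std_wave <- function(...) ap_params(...)

# recording + extracted features in one go
sim_features <- function(wave = ap_params(), freq = 1, n_beats = 10,
                         abnormalities = abnormality_config(), noise_sd = 0,
                         seed = 1, ...) {
  sim <- generate_recording(wave, pacing_freq = freq, n_beats = n_beats,
                            abnormalities = abnormalities,
                            noise_sd = noise_sd, seed = seed, ...)
  list(sim = sim, features = extract_features(sim$recording))
}

# independent oracle for APD of a sampled waveform: dense linear
# interpolation root of the (1 - level) crossing after the peak
apd_root_oracle <- function(voltage, fs, onset_s, rmp, apa, level) {
  thr <- rmp + (1 - level) * apa
  t <- (seq_along(voltage) - 1) / fs
  i_pk <- which.max(voltage)
  f <- stats::approxfun(t[i_pk:length(t)], voltage[i_pk:length(t)] - thr)
  lo <- t[i_pk]
  hi <- t[length(t)]
  (stats::uniroot(f, c(lo, hi), tol = 1e-9)$root - onset_s) * 1000
}
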
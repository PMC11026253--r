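## Synthetic paced recordings: a train of parametric action potentials on a
## baseline, with stimulation artifacts, optional injected abnormalities
## (EADs, extrasystoles, spontaneous couplets, APD alternans, 2:1 capture
## failure) and Gaussian noise. Every injected event and every AP's analytic
## shape properties are returned as ground truth.

#' Abnormality configuration for synthetic recordings
#'
#' @param ead_prob per-beat probability of an early-afterdepolarisation hump
#'   during repolarisation.
#' @param extrasystole_prob per inter-stimulus-interval probability of one
#'   non-stimulated full AP in diastole.
#' @param couplet_prob per-interval probability of a stimulation-independent
#'   two-AP burst (two spontaneous AP 250 ms apart).
#' @param alternans_depth_ms peak-to-peak beat-to-beat APD90 alternation in
#'   ms (0 disables alternans).
#' @param capture_failure_freqs_hz pacing frequencies (Hz) at which the
#'   tissue fails to follow 1:1 and responds 2:1; at these frequencies the
#'   APD is also frequency-invariant (impaired rate adaptation).
#' @param ead_amp_mV,ead_width_ms amplitude and full width of the injected
#'   EAD hump.
#' @return an object of class `abnormality_config`.
#' @export
abnormality_config <- function(ead_prob = 0, extrasystole_prob = 0,
                               couplet_prob = 0, alternans_depth_ms = 0,
                               capture_failure_freqs_hz = numeric(0),
                               ead_amp_mV = 15, ead_width_ms = 30) {
  for (p in c(ead_prob, extrasystole_prob, couplet_prob))
    check_that(p >= 0 && p <= 1, "event probabilities must lie in [0, 1]")
  check_that(alternans_depth_ms >= 0, "alternans_depth_ms must be >= 0")
  structure(list(ead_prob = ead_prob, extrasystole_prob = extrasystole_prob,
                 couplet_prob = couplet_prob,
                 alternans_depth_ms = alternans_depth_ms,
                 capture_failure_freqs_hz = capture_failure_freqs_hz,
                 ead_amp_mV = ead_amp_mV, ead_width_ms = ead_width_ms),
            class = "abnormality_config")
}

#' Paced intracellular recording container
#'
#' @param samples membrane potential, mV.
#' @param sampling_rate Hz.
#' @param stim_times stimulation timestamps in seconds from record start,
#'   strictly increasing and within the record.
#' @param pacing_freq nominal pacing frequency, Hz.
#' @param patient_id,location_id identifiers.
#' @return an object of class `trace_recording`.
#' @export
trace_recording <- function(samples, sampling_rate, stim_times, pacing_freq,
                            patient_id = "P01", location_id = "L01") {
  check_that(sampling_rate > 0, "sampling_rate must be > 0")
  check_that(length(samples) > 0, "empty trace")
  dur <- length(samples) / sampling_rate
  if (length(stim_times)) {
    check_that(all(diff(stim_times) > 0), "stim_times must be strictly increasing")
    check_that(min(stim_times) >= 0 && max(stim_times) <= dur,
               "stim_times must fall within the record")
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 stim_times = stim_times, pacing_freq = pacing_freq,
                 patient_id = patient_id, location_id = location_id),
            class = "trace_recording")
}

#' @export
print.trace_recording <- function(x, ...) {
  cat(sprintf("<trace_recording> %s/%s: %.1f s at %g kHz, %d stimuli at %g Hz\n",
              x$patient_id, x$location_id,
              length(x$samples) / x$sampling_rate, x$sampling_rate / 1000,
              length(x$stim_times), x$pacing_freq))
  invisible(x)
}

## sample index (1-based) of a time in seconds, snapped to the grid
.t2i <- function(t_s, fs) as.integer(round(t_s * fs)) + 1L

#' Generate a paced recording with ground truth
#'
#' Builds a pacing train of `n_beats` stimuli at `pacing_freq`, places one
#' action potential per captured stimulus (2:1 capture when `pacing_freq` is
#' listed in `abnormalities$capture_failure_freqs_hz`), injects the
#' configured abnormal events, adds a biphasic stimulation artifact at every
#' stimulus and optional Gaussian noise. APD rate adaptation follows a
#' linear ms-per-Hz slope relative to 1 Hz, except at capture-failure
#' frequencies where APD is frequency-invariant.
#'
#' @param waveform an [ap_params()] object; its `apd90_ms` is the APD90 at
#'   1 Hz pacing.
#' @param pacing_freq pacing frequency, Hz (0.5, 1, 2, 3, 4 in the standard
#'   protocol; other values allowed).
#' @param n_beats number of stimuli (>= 1).
#' @param abnormalities an [abnormality_config()].
#' @param noise_sd Gaussian noise standard deviation, mV.
#' @param artifact_amp stimulation-artifact amplitude, mV (biphasic, 2 ms).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @param sampling_rate Hz (>= 1000).
#' @param stim_latency_ms delay from stimulus to upstroke onset, ms.
#' @param rate_slope_ms_per_hz APD90 change per Hz of pacing relative to
#'   1 Hz (negative = physiological shortening).
#' @param pre_s baseline recorded before the first stimulus, s.
#' @return list with `recording` (a [trace_recording()]), `events`
#'   (data.frame: `type` in ead/extrasystole/couplet, `time_s`, `sample`),
#'   and `aps` (data.frame of per-AP ground truth: onset, stimulated flag,
#'   and the seven analytic shape properties).
#' @export
generate_recording <- function(waveform, pacing_freq = 1, n_beats = 20,
                               abnormalities = abnormality_config(),
                               noise_sd = 0, artifact_amp = 20, seed = 1,
                               sampling_rate = 10000, stim_latency_ms = 10,
                               rate_slope_ms_per_hz = -41.46, pre_s = 0.1) {
  stopifnot(inherits(waveform, "ap_params"),
            inherits(abnormalities, "abnormality_config"))
  check_that(n_beats >= 1, "n_beats must be >= 1")
  check_that(sampling_rate >= 1000, "sampling_rate must be >= 1000 Hz")
  fs <- sampling_rate
  ab <- abnormalities
  set.seed(seed)

  impaired <- pacing_freq %in% ab$capture_failure_freqs_hz
  cycle_s <- 1 / pacing_freq
  eff_cycle_ms <- 1000 * cycle_s * (if (impaired) 2 else 1)

  apd90_f <- if (impaired) waveform$apd90_ms
             else waveform$apd90_ms + rate_slope_ms_per_hz * (pacing_freq - 1)
  check_that(apd90_f > max(5, 2 * waveform$upstroke_duration_ms),
             "rate-adapted APD90 (%.1f ms) too short at %g Hz", apd90_f, pacing_freq)

  par_f <- waveform
  par_f$apd90_ms <- apd90_f
  baseline_ms <- 20
  truth_f <- ap_ground_truth(par_f)
  check_that(stim_latency_ms + truth_f$total_ms <=
               eff_cycle_ms - baseline_ms - 1,
             paste("action potential (%.1f ms incl. latency) does not fit the",
                   "%.1f ms pacing cycle at %g Hz; configure capture failure"),
             stim_latency_ms + truth_f$total_ms, eff_cycle_ms, pacing_freq)

  stim_t <- pre_s + (seq_len(n_beats) - 1L) / pacing_freq
  stim_t <- round(stim_t * fs) / fs        # snap to the sample grid
  n <- .t2i(max(stim_t) + cycle_s * (if (impaired) 2 else 1) + 0.1, fs)
  v <- rep(waveform$rmp_mV, n)
  t_s <- (seq_len(n) - 1L) / fs

  captured <- if (impaired) seq(1L, n_beats, by = 2L) else seq_len(n_beats)

  add_ap <- function(onset_s, params) {
    tr <- ap_ground_truth(params)
    i0 <- .t2i(onset_s, fs)
    i1 <- min(n, .t2i(onset_s + tr$total_ms / 1000, fs) + 1L)
    idx <- i0:i1
    rel_ms <- (idx - i0) / fs * 1000
    v[idx] <<- v[idx] + params$apa_mV * ap_vnorm(rel_ms, params)
    tr
  }

  aps <- list()
  events <- list()
  half <- ab$alternans_depth_ms / 2
  for (k in seq_along(captured)) {
    b <- captured[k]
    par_b <- par_f
    if (half > 0) par_b$apd90_ms <- apd90_f + if (k %% 2 == 1) half else -half
    onset <- round((stim_t[b] + stim_latency_ms / 1000) * fs) / fs
    tr <- add_ap(onset, par_b)
    has_ead <- ab$ead_prob > 0 && stats::runif(1) < ab$ead_prob
    if (has_ead) {
      span <- tr$apd90_ms - tr$apd20_ms
      w <- min(ab$ead_width_ms, 0.8 * span)
      c_ms <- stats::runif(1, tr$apd20_ms + 0.25 * span, tr$apd20_ms + 0.75 * span)
      ci <- .t2i(onset + c_ms / 1000, fs)
      hw <- as.integer(round(w / 2 / 1000 * fs))
      idx <- max(1L, ci - hw):min(n, ci + hw)
      v[idx] <- v[idx] + ab$ead_amp_mV * 0.5 *
        (1 + cos(pi * (idx - ci) / hw))
      events[[length(events) + 1L]] <-
        data.frame(type = "ead", time_s = (ci - 1L) / fs, sample = ci)
    }
    aps[[length(aps) + 1L]] <- data.frame(
      beat = b, onset_s = onset, stimulated = TRUE, type = "paced",
      has_ead = has_ead,
      rmp = tr$rmp_mV, apa = tr$apa_mV, dvdt_max = tr$dvdt_max_Vps,
      apd20 = tr$apd20_ms, apd50 = tr$apd50_ms, apd90 = tr$apd90_ms,
      auc90 = tr$auc90_mVs)
  }

  ## diastolic (spontaneous) events between consecutive captured beats
  spont_total_s <- (stim_latency_ms + truth_f$total_ms) / 1000
  for (k in seq_len(length(captured) - 1L)) {
    prev_onset <- aps[[k]]$onset_s
    lo <- prev_onset + aps[[k]]$apd90 / 1000 + 0.1
    next_stim <- stim_t[captured[k + 1L]]
    draw_couplet <- ab$couplet_prob > 0 && stats::runif(1) < ab$couplet_prob
    draw_extra <- !draw_couplet && ab$extrasystole_prob > 0 &&
      stats::runif(1) < ab$extrasystole_prob
    if (!draw_couplet && !draw_extra) next
    n_ap <- if (draw_couplet) 2L else 1L
    hi <- next_stim - spont_total_s - 0.02 - (n_ap - 1L) * 0.25
    if (hi <= lo) next                     # no diastolic room; skip injection
    onset1 <- round(stats::runif(1, lo, hi) * fs) / fs
    trs <- add_ap(onset1, par_f)
    if (draw_couplet) add_ap(onset1 + 0.25, par_f)
    typ <- if (draw_couplet) "couplet" else "extrasystole"
    events[[length(events) + 1L]] <-
      data.frame(type = typ, time_s = onset1, sample = .t2i(onset1, fs))
    for (j in seq_len(n_ap)) {
      on_j <- onset1 + (j - 1L) * 0.25
      aps[[length(aps) + 1L]] <- data.frame(
        beat = NA_integer_, onset_s = on_j, stimulated = FALSE, type = typ,
        has_ead = FALSE,
        rmp = trs$rmp_mV, apa = trs$apa_mV, dvdt_max = trs$dvdt_max_Vps,
        apd20 = trs$apd20_ms, apd50 = trs$apd50_ms, apd90 = trs$apd90_ms,
        auc90 = trs$auc90_mVs)
    }
  }

  ## biphasic stimulation artifact (1 ms positive + 1 ms negative) at every
  ## stimulus, captured or not
  if (artifact_amp != 0) {
    w1 <- max(1L, as.integer(round(fs / 1000)))
    for (st in stim_t) {
      i0 <- .t2i(st, fs)
      up <- i0:min(n, i0 + w1 - 1L)
      dn <- min(n, i0 + w1):min(n, i0 + 2L * w1 - 1L)
      v[up] <- v[up] + artifact_amp
      v[dn] <- v[dn] - artifact_amp
    }
  }

  if (noise_sd > 0) v <- v + stats::rnorm(n, 0, noise_sd)

  aps <- if (length(aps)) do.call(rbind, aps) else
    data.frame(beat = integer(0), onset_s = numeric(0), stimulated = logical(0),
               type = character(0), has_ead = logical(0), rmp = numeric(0),
               apa = numeric(0), dvdt_max = numeric(0), apd20 = numeric(0),
               apd50 = numeric(0), apd90 = numeric(0), auc90 = numeric(0))
  aps <- aps[order(aps$onset_s), , drop = FALSE]
  rownames(aps) <- NULL
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(0), time_s = numeric(0), sample = integer(0))
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL

  list(recording = trace_recording(v, fs, stim_t, pacing_freq),
       events = events, aps = aps)
}

#' Write a recording as CSV + JSON sidecar
#'
#' The on-disk dialect is a two-column CSV (`time_s`, `voltage_mV`) and a
#' JSON sidecar holding `patient_id`, `location_id`, `pacing_freq_hz`,
#' `sampling_rate_hz`, `stim_times_s` and optionally `seed`.
#'
#' @param rec a [trace_recording()].
#' @param path_prefix file path without extension; writes
#'   `<path_prefix>.csv` and `<path_prefix>.json`.
#' @param seed seed recorded in the sidecar (optional, for provenance).
#' @return invisibly, the two file paths.
#' @export
write_trace <- function(rec, path_prefix, seed = NULL) {
  stopifnot(inherits(rec, "trace_recording"))
  csv <- paste0(path_prefix, ".csv")
  js <- paste0(path_prefix, ".json")
  t_s <- (seq_along(rec$samples) - 1L) / rec$sampling_rate
  utils::write.csv(data.frame(time_s = t_s, voltage_mV = rec$samples),
                   csv, row.names = FALSE)
  side <- list(patient_id = rec$patient_id, location_id = rec$location_id,
               pacing_freq_hz = rec$pacing_freq,
               sampling_rate_hz = rec$sampling_rate,
               stim_times_s = rec$stim_times)
  if (!is.null(seed)) side$seed <- seed
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, sidecar = js))
}

#' Read a recording from CSV + JSON sidecar
#'
#' @param csv_path path to the two-column trace CSV; the sidecar is looked
#'   up as the same path with a `.json` extension unless given explicitly.
#' @param sidecar_path optional explicit sidecar path.
#' @return a [trace_recording()].
#' @export
read_trace <- function(csv_path, sidecar_path = NULL) {
  if (is.null(sidecar_path))
    sidecar_path <- sub("\\.csv$", ".json", csv_path)
  check_that(file.exists(csv_path), "trace file not found: %s", csv_path)
  check_that(file.exists(sidecar_path), "sidecar not found: %s", sidecar_path)
  d <- utils::read.csv(csv_path)
  check_that(all(c("time_s", "voltage_mV") %in% names(d)),
             "trace CSV must have columns time_s, voltage_mV")
  check_that(all(diff(d$time_s) > 0), "time_s must be strictly increasing")
  side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("patient_id", "location_id", "pacing_freq_hz", "sampling_rate_hz"))
    check_that(!is.null(side[[f]]), "sidecar missing field '%s'", f)
  trace_recording(d$voltage_mV, side$sampling_rate_hz,
                  as.numeric(side$stim_times_s %||% numeric(0)),
                  side$pacing_freq_hz, side$patient_id, side$location_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
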
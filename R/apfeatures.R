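## Segmentation of paced recordings into individual action potentials,
## computation of the seven AP shape properties (RMP, APA, dV/dt_max,
## APD20/50/90, AUC90) and the rejection rules: artifacts, amplitude below
## 75 mV, insufficient separation of the upstroke from the stimulation
## artifact, missing baseline, incomplete repolarisation.
##
## Conventions (config-exposed): activation time is the time of maximum
## upstroke velocity; RMP is the median of the last 20 ms of baseline before
## the stimulus blanking window; threshold crossings are linearly
## interpolated between samples; an AP is "stimulated" when its upstroke
## falls within 50 ms after a stimulus.

.ms2n <- function(ms, fs) as.integer(round(ms / 1000 * fs))

#' Segment a recording into action-potential windows
#'
#' Upstrokes are detected as sustained fast depolarisations: runs of
#' smoothed dV/dt above `upstroke_threshold_Vps` followed by a maintained
#' voltage elevation (so the 2 ms biphasic stimulation artifact, which
#' returns to baseline immediately, is not mistaken for an upstroke). Each
#' window contains exactly one upstroke; windows are non-overlapping and a
#' window is tagged `stimulated` when its upstroke lies within
#' `capture_window_ms` after a stimulus.
#'
#' @param rec a [trace_recording()].
#' @param blanking_ms stimulus blanking window, ms.
#' @param capture_window_ms window after a stimulus within which an upstroke
#'   counts as stimulated.
#' @param upstroke_threshold_Vps smoothed-derivative threshold, V/s.
#' @param min_sustained_mV minimal maintained elevation above
#'   pre-upstroke voltage for a candidate to count as an AP.
#' @param smooth_ms moving-average width used for detection, ms.
#' @param pre_window_ms baseline context retained before each upstroke.
#' @return data.frame with one row per AP: `ap`, `start_idx`, `end_idx`,
#'   `i_act` (sample of maximum upstroke slope), `t_act_s`, `stimulated`,
#'   `stim_time_s` (NA for spontaneous AP). Zero rows when no upstroke is
#'   detectable.
#' @export
segment_aps <- function(rec, blanking_ms = 5, capture_window_ms = 50,
                        upstroke_threshold_Vps = 10, min_sustained_mV = 30,
                        smooth_ms = 0.7, pre_window_ms = 30) {
  stopifnot(inherits(rec, "trace_recording"))
  v <- rec$samples
  fs <- rec$sampling_rate
  check_that(length(v) > 1, "empty trace")
  vs <- smooth_ma(v, .ms2n(smooth_ms, fs))
  dv <- diff(vs) * fs / 1000                       # V/s

  cand <- which(dv > upstroke_threshold_Vps)
  empty <- data.frame(ap = integer(0), start_idx = integer(0),
                      end_idx = integer(0), i_act = integer(0),
                      t_act_s = numeric(0), stimulated = logical(0),
                      stim_time_s = numeric(0))
  if (!length(cand)) return(empty)

  gap <- .ms2n(2, fs)
  grp <- cumsum(c(1L, diff(cand) > gap))
  n <- length(v)
  acts <- integer(0)
  for (g in split(cand, grp)) {
    dmax <- max(dv[g])
    i_max <- g[which(dv[g] >= dmax * (1 - 1e-9))[1]]
    i0 <- g[1]
    base_v <- vs[max(1L, i0 - .ms2n(0.5, fs))]
    hold <- vs[min(n, i_max + .ms2n(2, fs)):min(n, i_max + .ms2n(8, fs))]
    if (mean(hold) - base_v >= min_sustained_mV) acts <- c(acts, i_max)
  }
  if (!length(acts)) return(empty)
  ## refractory: collapse detections closer than 30 ms to one upstroke
  keep <- c(TRUE, diff(acts) > .ms2n(30, fs))
  acts <- acts[keep]

  pre <- .ms2n(pre_window_ms, fs)
  starts <- pmax(1L, acts - pre)
  ends <- c(pmax(1L, acts[-1] - pre) - 1L, n)
  t_act <- (acts - 1L) / fs
  stim_time <- rep(NA_real_, length(acts))
  stimulated <- rep(FALSE, length(acts))
  if (length(rec$stim_times)) {
    for (k in seq_along(acts)) {
      dt <- t_act[k] - rec$stim_times
      ok <- which(dt >= 0 & dt <= capture_window_ms / 1000)
      if (length(ok)) {
        stimulated[k] <- TRUE
        stim_time[k] <- rec$stim_times[max(ok)]
      }
    }
  }
  data.frame(ap = seq_along(acts), start_idx = starts, end_idx = ends,
             i_act = acts, t_act_s = t_act, stimulated = stimulated,
             stim_time_s = stim_time)
}

#' Resting membrane potential of one AP window
#'
#' Median of the baseline segment ending at `baseline_end_s` (for a
#' stimulated AP, the stimulus time, so the baseline is the last
#' `baseline_ms` before the stimulus blanking window).
#'
#' @param voltage window voltage, mV.
#' @param sampling_rate Hz.
#' @param baseline_end_s end of the baseline segment, seconds from the
#'   start of `voltage`.
#' @param baseline_ms baseline length, ms.
#' @return RMP in mV, or `NA` when fewer than `baseline_ms` of baseline are
#'   available ("no baseline" QC condition, not an error).
#' @export
compute_rmp <- function(voltage, sampling_rate, baseline_end_s,
                        baseline_ms = 20) {
  i_end <- as.integer(floor(baseline_end_s * sampling_rate))   # sample before end
  i_start <- i_end - .ms2n(baseline_ms, sampling_rate) + 1L
  if (i_start < 1L || i_end < i_start) return(NA_real_)
  stats::median(voltage[i_start:i_end])
}

#' Action-potential amplitude
#'
#' @param voltage window voltage, mV (should contain the AP peak).
#' @param rmp resting membrane potential, mV.
#' @return APA = peak potential - RMP, in mV.
#' @export
compute_apa <- function(voltage, rmp) max(voltage) - rmp

#' Maximum upstroke velocity
#'
#' Maximum of the discrete forward difference over the supplied (upstroke)
#' samples, converted to V/s.
#'
#' @param voltage upstroke-region voltage, mV.
#' @param sampling_rate Hz.
#' @return dV/dt_max in V/s (0 for a flat trace).
#' @export
compute_dvdt_max <- function(voltage, sampling_rate) {
  if (length(voltage) < 2) return(0)
  max(diff(voltage)) * sampling_rate / 1000
}

#' Action-potential duration at a repolarisation level
#'
#' Time from activation to the first downward crossing of
#' `rmp + (1 - level) * apa`, with linear interpolation between samples.
#' The search starts at the AP peak so the upstroke's upward crossing is
#' ignored.
#'
#' @param voltage window voltage, mV.
#' @param sampling_rate Hz.
#' @param t_act_s activation time, seconds from start of `voltage`.
#' @param rmp,apa resting potential and amplitude, mV.
#' @param level repolarisation fraction (0.2, 0.5 or 0.9 in the standard
#'   property set; any value in (0, 1) is accepted).
#' @return APD in ms, or `NA` when repolarisation never crosses the
#'   threshold within the window (incomplete repolarisation).
#' @export
compute_apd <- function(voltage, sampling_rate, t_act_s, rmp, apa, level) {
  thr <- rmp + (1 - level) * apa
  i_act <- as.integer(round(t_act_s * sampling_rate)) + 1L
  if (i_act >= length(voltage)) return(NA_real_)
  i_peak <- i_act - 1L + which.max(voltage[i_act:length(voltage)])
  seg <- voltage[i_peak:length(voltage)]
  below <- which(seg[-1] < thr & seg[-length(seg)] >= thr)
  if (!length(below)) return(NA_real_)
  i <- below[1]
  frac <- (seg[i] - thr) / (seg[i] - seg[i + 1])
  t_cross <- (i_peak - 1L + i - 1L + frac) / sampling_rate
  (t_cross - t_act_s) * 1000
}

#' Area under the curve to 90% repolarisation
#'
#' Trapezoidal integral of `voltage - rmp` from activation to the APD90
#' crossing, in mV*s.
#'
#' @param voltage window voltage, mV.
#' @param sampling_rate Hz.
#' @param t_act_s activation time, seconds from start of `voltage`.
#' @param rmp resting potential, mV.
#' @param apd90_ms APD90 in ms (the integration endpoint).
#' @return AUC90 in mV*s (0 for a flat trace).
#' @export
compute_auc90 <- function(voltage, sampling_rate, t_act_s, rmp, apd90_ms) {
  if (is.na(apd90_ms)) return(NA_real_)
  i_act <- as.integer(round(t_act_s * sampling_rate)) + 1L
  t_end <- t_act_s + apd90_ms / 1000
  i_last <- min(length(voltage), as.integer(floor(t_end * sampling_rate)) + 1L)
  if (i_last <= i_act) return(0)
  idx <- i_act:i_last
  t <- (idx - 1L) / sampling_rate
  y <- voltage[idx] - rmp
  a <- trapz(t, y)
  if (i_last < length(voltage) && t_end > t[length(t)]) {
    ## partial trapezoid up to the interpolated crossing time
    y_end <- y[length(y)] + (voltage[i_last + 1L] - voltage[i_last]) *
      (t_end - t[length(t)]) * sampling_rate
    a <- a + (t_end - t[length(t)]) * (y[length(y)] + y_end) / 2
  }
  a
}

#' Quality control of one AP measurement
#'
#' Applies the rejection rules in a fixed order: missing baseline, upstroke
#' inside the stimulation-artifact blanking window (insufficient
#' separation), artifact in the window, incomplete repolarisation, and
#' amplitude strictly below the acceptance threshold (an AP at exactly
#' 75 mV is accepted).
#'
#' @param measurement one-row data.frame or list with fields `rmp`, `apa`,
#'   `apd90`, `t_act_s`, `stimulated`, `stim_time_s` and optionally
#'   `artifact_flag`.
#' @param blanking_ms stimulus blanking window, ms.
#' @param apa_threshold_mV acceptance threshold for APA (strict "below"
#'   rejects).
#' @return list with `status` ("accepted"/"rejected") and `reason` (one of
#'   no_baseline, upstroke_in_artifact, artifact,
#'   incomplete_repolarisation, low_amplitude, or NA when accepted).
#' @export
qc_ap <- function(measurement, blanking_ms = 5, apa_threshold_mV = 75) {
  m <- as.list(measurement)
  reason <- NA_character_
  if (is.na(m$rmp %||% NA)) {
    reason <- "no_baseline"
  } else if (isTRUE(m$stimulated) && !is.na(m$stim_time_s %||% NA) &&
             (m$t_act_s - m$stim_time_s) <= blanking_ms / 1000) {
    reason <- "upstroke_in_artifact"
  } else if (isTRUE(m$artifact_flag %||% FALSE)) {
    reason <- "artifact"
  } else if (is.na(m$apd90 %||% NA)) {
    reason <- "incomplete_repolarisation"
  } else if ((m$apa %||% 0) < apa_threshold_mV) {
    reason <- "low_amplitude"
  }
  list(status = if (is.na(reason)) "accepted" else "rejected",
       reason = reason)
}

#' Extract QC'd AP shape properties from a recording
#'
#' Segments the recording, computes the seven shape properties per AP and
#' applies [qc_ap()]. Artifact screening flags windows with
#' `|dV/dt| > artifact_dvdt_Vps` outside the upstroke and outside stimulus
#' blanking, or voltage excursions above `artifact_max_mV`.
#'
#' @inheritParams segment_aps
#' @param apa_threshold_mV APA acceptance threshold, mV.
#' @param artifact_dvdt_Vps,artifact_max_mV artifact-screening thresholds.
#' @return data.frame with one row per detected AP: identifiers, pacing
#'   frequency, activation time, stimulated tag, the seven properties,
#'   `qc_status` and `qc_reason`.
#' @export
extract_features <- function(rec, blanking_ms = 5, capture_window_ms = 50,
                             apa_threshold_mV = 75,
                             upstroke_threshold_Vps = 10,
                             min_sustained_mV = 30, smooth_ms = 0.7,
                             artifact_dvdt_Vps = 1000, artifact_max_mV = 60) {
  wins <- segment_aps(rec, blanking_ms = blanking_ms,
                      capture_window_ms = capture_window_ms,
                      upstroke_threshold_Vps = upstroke_threshold_Vps,
                      min_sustained_mV = min_sustained_mV,
                      smooth_ms = smooth_ms)
  v <- rec$samples
  fs <- rec$sampling_rate
  vs <- smooth_ma(v, .ms2n(smooth_ms, fs))
  n <- length(v)

  rows <- lapply(seq_len(nrow(wins)), function(k) {
    w <- wins[k, ]
    idx <- w$start_idx:w$end_idx
    vw_raw <- v[idx]
    vw <- vs[idx]
    t0 <- (w$start_idx - 1L) / fs

    ## refine activation on the raw derivative near the detected upstroke
    r0 <- max(w$start_idx, w$i_act - .ms2n(2, fs))
    r1 <- min(n - 1L, w$i_act + .ms2n(2, fs))
    dvr <- diff(v[r0:(r1 + 1L)]) * fs / 1000
    dvdt_max <- max(dvr)
    ## ties (e.g. an exactly linear upstroke) break to the earliest sample
    i_act <- r0 - 1L + which(dvr >= dvdt_max * (1 - 1e-9))[1]
    t_act <- (i_act - 1L) / fs

    ## baseline on absolute trace indices: the last 20 ms before the
    ## stimulus (stimulated AP) or before the upstroke (spontaneous AP),
    ## rejected when it would overlap another AP's upstroke or another
    ## stimulus' blanking interval
    base_end <- if (w$stimulated) w$stim_time_s else t_act - 2 / 1000
    b_end_i <- as.integer(floor(base_end * fs))
    b_start_i <- b_end_i - .ms2n(20, fs) + 1L
    rmp <- NA_real_
    if (b_start_i >= 1L) {
      other_acts <- wins$i_act[wins$ap != w$ap]
      clash <- any(other_acts >= b_start_i & other_acts <= b_end_i)
      inblank <- FALSE
      if (length(rec$stim_times)) {
        st_i <- .t2i(rec$stim_times, fs)
        if (w$stimulated) st_i <- st_i[st_i != .t2i(w$stim_time_s, fs)]
        inblank <- any(st_i <= b_end_i &
                         st_i + .ms2n(blanking_ms, fs) >= b_start_i)
      }
      if (!clash && !inblank) rmp <- compute_rmp(v, fs, base_end)
    }

    ## peak search on the smoothed window after activation, ignoring
    ## blanking intervals of uncaptured stimuli inside the window
    vpk <- vw
    if (length(rec$stim_times)) {
      for (st in rec$stim_times) {
        bi <- .t2i(st, fs):min(n, .t2i(st, fs) + .ms2n(blanking_ms, fs))
        bi <- bi[bi %in% idx]
        if (length(bi)) vpk[bi - w$start_idx + 1L] <- -Inf
      }
    }
    rel_act <- i_act - w$start_idx + 1L
    apa <- if (is.na(rmp)) NA_real_ else
      max(vpk[rel_act:length(vpk)]) - rmp

    apd <- c(NA_real_, NA_real_, NA_real_)
    auc90 <- NA_real_
    if (!is.na(rmp) && !is.na(apa) && apa > 0) {
      apd <- vapply(c(0.2, 0.5, 0.9), function(lv)
        compute_apd(vw, fs, t_act - t0, rmp, apa, lv), numeric(1))
      auc90 <- compute_auc90(vw_raw, fs, t_act - t0, rmp, apd[3])
    }

    ## artifact screen outside the upstroke and outside stimulus blanking
    excl <- logical(length(idx) - 1L)
    up0 <- max(1L, rel_act - .ms2n(2, fs))
    up1 <- min(length(excl), rel_act + .ms2n(3, fs))
    excl[up0:up1] <- TRUE
    vmask <- rep(FALSE, length(idx))
    if (length(rec$stim_times)) {
      for (st in rec$stim_times) {
        bi <- (.t2i(st, fs) - .ms2n(0.5, fs)):(.t2i(st, fs) + .ms2n(blanking_ms, fs))
        bi <- bi[bi %in% idx] - w$start_idx + 1L
        if (length(bi)) {
          excl[bi[bi <= length(excl)]] <- TRUE
          vmask[bi] <- TRUE
        }
      }
    }
    dvw <- diff(vw_raw) * fs / 1000
    artifact_flag <- any(abs(dvw[!excl]) > artifact_dvdt_Vps) ||
      any(vw_raw[!vmask] > artifact_max_mV)

    m <- data.frame(patient_id = rec$patient_id,
                    location_id = rec$location_id,
                    pacing_freq = rec$pacing_freq,
                    ap = w$ap, t_act_s = t_act, stimulated = w$stimulated,
                    stim_time_s = w$stim_time_s,
                    rmp = rmp, apa = apa, dvdt_max = dvdt_max,
                    apd20 = apd[1], apd50 = apd[2], apd90 = apd[3],
                    auc90 = auc90, artifact_flag = artifact_flag)
    qc <- qc_ap(m, blanking_ms = blanking_ms,
                apa_threshold_mV = apa_threshold_mV)
    m$qc_status <- qc$status
    m$qc_reason <- qc$reason
    m
  })
  if (!length(rows))
    return(data.frame(patient_id = character(0), location_id = character(0),
                      pacing_freq = numeric(0), ap = integer(0),
                      t_act_s = numeric(0), stimulated = logical(0),
                      stim_time_s = numeric(0), rmp = numeric(0),
                      apa = numeric(0), dvdt_max = numeric(0),
                      apd20 = numeric(0), apd50 = numeric(0),
                      apd90 = numeric(0), auc90 = numeric(0),
                      artifact_flag = logical(0), qc_status = character(0),
                      qc_reason = character(0)))
  do.call(rbind, rows)
}

#' Per-location summary of accepted AP properties
#'
#' Arithmetic mean of each property per recording location and pacing
#' frequency, over accepted AP only ("one data point per recording
#' location" at each frequency). Warns when a frequency has fewer than
#' `min_aps` accepted AP; an input with zero accepted AP yields an empty
#' summary with a warning.
#'
#' @param features output of [extract_features()] (possibly several
#'   recordings row-bound).
#' @param min_aps minimal accepted AP count per frequency before warning.
#' @return data.frame with one row per patient x location x frequency and
#'   mean columns for the seven properties plus `n_accepted`.
#' @export
summarise_location <- function(features, min_aps = 20) {
  acc <- features[features$qc_status == "accepted", , drop = FALSE]
  if (!nrow(acc)) {
    warning("no accepted AP; empty summary")
    return(data.frame(patient_id = character(0), location_id = character(0),
                      pacing_freq = numeric(0), rmp = numeric(0),
                      apa = numeric(0), dvdt_max = numeric(0),
                      apd20 = numeric(0), apd50 = numeric(0),
                      apd90 = numeric(0), auc90 = numeric(0),
                      n_accepted = integer(0)))
  }
  props <- c("rmp", "apa", "dvdt_max", "apd20", "apd50", "apd90", "auc90")
  key <- interaction(acc$patient_id, acc$location_id, acc$pacing_freq,
                     drop = TRUE)
  out <- do.call(rbind, lapply(split(acc, key), function(g) {
    cbind(data.frame(patient_id = g$patient_id[1],
                     location_id = g$location_id[1],
                     pacing_freq = g$pacing_freq[1]),
          as.data.frame(as.list(colMeans(g[props]))),
          data.frame(n_accepted = nrow(g)))
  }))
  rownames(out) <- NULL
  out <- out[order(out$patient_id, out$location_id, out$pacing_freq), ]
  low <- out$n_accepted < min_aps
  if (any(low))
    warning(sprintf("fewer than %d accepted AP at %d location-frequency combination(s)",
                    min_aps, sum(low)))
  out
}
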
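## Detection and classification of pro-arrhythmic tissue abnormalities:
## early afterdepolarisations during repolarisation, extrasystoles between
## paced beats, stimulation-independent spontaneous couplets, beat-to-beat
## APD alternans, and impaired APD shortening with failure to follow fast
## pacing (2:1 capture). Thresholds default to conservative values and are
## config-exposed; the original calls were made visually, so there is no
## numeric reference to match.

#' Detect early afterdepolarisations within one AP window
#'
#' An EAD is a depolarising deflection during repolarisation. During a
#' steep decline, even a large transient produces only a shallow local
#' maximum, so the deflection amplitude is measured against the
#' repolarisation trajectory extrapolated from just before the deflection
#' onset: a local maximum of the smoothed voltage between the APD20
#' crossing and the 90% repolarisation level counts as an EAD when its
#' height above the linearly extrapolated pre-deflection trend is at least
#' `min_prominence_mV` and the rise into the peak has positive dV/dt of at
#' least `min_dvdt_Vps`.
#'
#' @param voltage window voltage, mV.
#' @param sampling_rate Hz.
#' @param t_act_s activation time, seconds from start of `voltage`.
#' @param rmp,apa resting potential and amplitude, mV.
#' @param apd20_ms,apd90_ms the AP's APD20 and APD90 (search interval).
#' @param min_prominence_mV minimal deflection amplitude above the
#'   extrapolated repolarisation trend, mV.
#' @param min_dvdt_Vps minimal positive slope into the deflection, V/s.
#' @param smooth_ms smoothing width before peak finding, ms.
#' @return numeric vector of event times (seconds from start of `voltage`);
#'   empty for a monotone repolarisation.
#' @export
detect_eads <- function(voltage, sampling_rate, t_act_s, rmp, apa,
                        apd20_ms, apd90_ms, min_prominence_mV = 5,
                        min_dvdt_Vps = 0.1, smooth_ms = 2) {
  if (is.na(apd20_ms) || is.na(apd90_ms)) return(numeric(0))
  fs <- sampling_rate
  vs <- smooth_ma(voltage, .ms2n(smooth_ms, fs))
  i0 <- max(1L, as.integer(round((t_act_s + apd20_ms / 1000) * fs)) + 1L)
  i1 <- min(length(vs), as.integer(round((t_act_s + apd90_ms / 1000) * fs)) + 1L)
  if (i1 - i0 < 3L) return(numeric(0))
  seg <- vs[i0:i1]
  ## any local maximum at all is a candidate; the trend test decides
  cand <- find_peaks(seg, min_prominence = 0.25)
  if (!length(cand)) return(numeric(0))
  n10 <- .ms2n(10, fs)
  n25 <- .ms2n(25, fs)
  keep <- vapply(cand, function(i) {
    ## deflection onset: lowest point in the 25 ms preceding the peak
    w0 <- max(1L, i - n25)
    j <- w0 - 1L + which.min(seg[w0:i])
    if (j >= i) return(FALSE)
    if (max(diff(seg[j:i])) * fs / 1000 < min_dvdt_Vps) return(FALSE)
    ## pre-onset trend slope over up to 10 ms, extrapolated to the peak
    j0 <- max(1L, j - n10)
    slope <- if (j > j0) (seg[j] - seg[j0]) / (j - j0) else 0
    amp <- seg[i] - (seg[j] + slope * (i - j))
    amp >= min_prominence_mV
  }, logical(1))
  pks <- cand[keep]
  if (!length(pks)) return(numeric(0))
  ## merge peaks closer than 10 ms into one event (highest wins)
  grp <- cumsum(c(1L, diff(pks) > n10))
  pks <- vapply(split(pks, grp), function(g) g[which.max(seg[g])], numeric(1))
  (i0 - 1L + pks - 1L) / fs
}

## Group spontaneous AP times: runs of consecutive spontaneous AP closer
## than the couplet interval form one couplet event; isolated spontaneous
## AP are extrasystoles. Every spontaneous AP contributes to exactly one
## event type.
.classify_spontaneous <- function(times_s, couplet_max_interval_s = 0.5) {
  if (!length(times_s))
    return(data.frame(type = character(0), time_s = numeric(0),
                      n_ap = integer(0)))
  times_s <- sort(times_s)
  grp <- cumsum(c(1, diff(times_s) > couplet_max_interval_s))
  out <- lapply(split(times_s, grp), function(ts) {
    data.frame(type = if (length(ts) >= 2) "couplet" else "extrasystole",
               time_s = ts[1], n_ap = length(ts))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect extrasystoles among segmented AP
#'
#' Each isolated spontaneous full AP (not part of a couplet) is one
#' extrasystole.
#'
#' @param windows output of [segment_aps()] or [extract_features()] (needs
#'   columns `t_act_s` and `stimulated`).
#' @param couplet_max_interval_s spontaneous AP closer than this belong to
#'   a couplet, not to separate extrasystoles.
#' @return numeric vector of event times, seconds.
#' @export
detect_extrasystoles <- function(windows, couplet_max_interval_s = 0.5) {
  ev <- .classify_spontaneous(windows$t_act_s[!windows$stimulated],
                              couplet_max_interval_s)
  ev$time_s[ev$type == "extrasystole"]
}

#' Detect stimulation-independent spontaneous couplets
#'
#' Two or more consecutive spontaneous AP with inter-AP interval at most
#' `couplet_max_interval_s` form one couplet event.
#'
#' @inheritParams detect_extrasystoles
#' @return numeric vector of couplet onset times, seconds.
#' @export
detect_spontaneous_couplets <- function(windows, couplet_max_interval_s = 0.5) {
  ev <- .classify_spontaneous(windows$t_act_s[!windows$stimulated],
                              couplet_max_interval_s)
  ev$time_s[ev$type == "couplet"]
}

#' Detect beat-to-beat APD alternans in an APD sequence
#'
#' True when successive APD differences alternate in sign over at least
#' `min_beats` consecutive beats and the mean absolute beat-to-beat change
#' within that run is at least `max(abs_ms, rel * mean(APD))`. Sequences
#' shorter than `min_beats` are indeterminate (`NA`), not negative.
#'
#' @param apd_sequence APDs of consecutive accepted AP at one pacing
#'   frequency, ms.
#' @param min_beats minimal run length in beats.
#' @param abs_ms,rel absolute (ms) and relative magnitude floors.
#' @return `TRUE`, `FALSE`, or `NA` (too few beats).
#' @export
detect_apd_alternans <- function(apd_sequence, min_beats = 6, abs_ms = 5,
                                 rel = 0.05) {
  x <- apd_sequence[!is.na(apd_sequence)]
  if (length(x) < min_beats) return(NA)
  d <- diff(x)
  if (any(d == 0)) d[d == 0] <- 1e-12 * rep_len(c(1, -1), sum(d == 0))
  alt <- sign(d[-1]) != sign(d[-length(d)])
  ## runs of alternating differences; a run of m alternations spans m+2 beats
  r <- rle(alt)
  pos <- cumsum(c(1, r$lengths))
  for (k in which(r$values & r$lengths >= (min_beats - 2))) {
    i0 <- pos[k]                       # first diff index of the run
    i1 <- i0 + r$lengths[k]            # last diff index (inclusive)
    dd <- d[i0:i1]
    beats <- x[i0:(i1 + 1L)]
    if (mean(abs(dd)) >= max(abs_ms, rel * mean(beats))) return(TRUE)
  }
  FALSE
}

#' Detect impaired APD shortening / failure to follow fast pacing
#'
#' A location is flagged when, at any of the fast pacing frequencies (>= 2
#' Hz), the tissue fails to follow 1:1 (capture ratio < 1) or the APD90
#' exceeds the available cycle length. Requires summaries at two or more
#' frequencies including at least one fast one; otherwise indeterminate.
#'
#' @param per_frequency_summaries data.frame with columns `pacing_freq` and
#'   `apd90` (see [summarise_location()]).
#' @param capture_ratios named numeric vector: captured AP per stimulus at
#'   each frequency (names = frequency in Hz).
#' @param fast_freqs frequencies at which failure to follow is assessed.
#' @return list with `flag` (`TRUE`/`FALSE`/`NA`) and `failing_freqs`.
#' @export
detect_impaired_shortening <- function(per_frequency_summaries, capture_ratios,
                                       fast_freqs = c(2, 3, 4)) {
  s <- per_frequency_summaries
  freqs <- sort(unique(c(s$pacing_freq, as.numeric(names(capture_ratios)))))
  if (length(freqs) < 2 || !any(freqs %in% fast_freqs))
    return(list(flag = NA, failing_freqs = numeric(0)))
  failing <- numeric(0)
  for (f in intersect(freqs, fast_freqs)) {
    cr <- capture_ratios[as.character(f)]
    if (!is.na(cr) && cr < 1) {
      failing <- c(failing, f)
      next
    }
    apd <- s$apd90[s$pacing_freq == f]
    if (length(apd) && !is.na(apd[1]) && apd[1] > 1000 / f)
      failing <- c(failing, f)
  }
  list(flag = length(failing) > 0, failing_freqs = failing)
}

#' Abnormality report for one recording location
#'
#' Runs all detectors on the extracted features of one location (one or
#' more recordings at different pacing frequencies) and assembles the
#' per-location report: event list, per-frequency APD alternans,
#' impaired-shortening flag, and the overall tissue-arrhythmia flag (true
#' iff any EAD/extrasystole/couplet event is present).
#'
#' @param features [extract_features()] output for this location (several
#'   frequencies row-bound).
#' @param recordings named list of [trace_recording()] objects keyed by
#'   pacing frequency (as character), used for the EAD search and capture
#'   ratios; optional — without it EADs and capture failure are skipped.
#' @param ... detector threshold overrides passed through by name.
#' @return object of class `abnormality_report`: list with `events`
#'   (data.frame `type`, `time_s`, `pacing_freq`), `apd_alternans` (named
#'   logical per frequency), `impaired_shortening`, `tissue_arrhythmia`.
#' @export
abnormality_report <- function(features, recordings = NULL, ...) {
  dots <- list(...)
  arg <- function(fn, nm) dots[[nm]] %||% formals(fn)[[nm]]

  events <- data.frame(type = character(0), time_s = numeric(0),
                       pacing_freq = numeric(0))
  freqs <- sort(unique(features$pacing_freq))

  ## spontaneous events per frequency
  for (f in freqs) {
    ff <- features[features$pacing_freq == f, , drop = FALSE]
    ev <- .classify_spontaneous(ff$t_act_s[!ff$stimulated],
                                arg(detect_extrasystoles, "couplet_max_interval_s"))
    if (nrow(ev))
      events <- rbind(events, data.frame(type = ev$type, time_s = ev$time_s,
                                         pacing_freq = f))
  }

  ## EADs on accepted stimulated AP (needs the raw traces)
  if (!is.null(recordings)) {
    for (f in freqs) {
      rec <- recordings[[as.character(f)]]
      if (is.null(rec)) next
      ff <- features[features$pacing_freq == f &
                       features$qc_status == "accepted", , drop = FALSE]
      for (k in seq_len(nrow(ff))) {
        tt <- detect_eads(rec$samples, rec$sampling_rate, ff$t_act_s[k],
                          ff$rmp[k], ff$apa[k], ff$apd20[k], ff$apd90[k],
                          min_prominence_mV = arg(detect_eads, "min_prominence_mV"),
                          min_dvdt_Vps = arg(detect_eads, "min_dvdt_Vps"))
        if (length(tt))
          events <- rbind(events, data.frame(type = "ead", time_s = tt,
                                             pacing_freq = f))
      }
    }
  }

  ## per-frequency alternans on accepted stimulated APD90 sequences
  altern <- vapply(freqs, function(f) {
    ff <- features[features$pacing_freq == f & features$stimulated &
                     features$qc_status == "accepted", , drop = FALSE]
    detect_apd_alternans(ff$apd90[order(ff$t_act_s)],
                         min_beats = arg(detect_apd_alternans, "min_beats"),
                         abs_ms = arg(detect_apd_alternans, "abs_ms"),
                         rel = arg(detect_apd_alternans, "rel"))
  }, logical(1))
  names(altern) <- as.character(freqs)

  ## capture ratios and impaired shortening
  capture <- vapply(freqs, function(f) {
    if (is.null(recordings) || is.null(recordings[[as.character(f)]]))
      return(NA_real_)
    rec <- recordings[[as.character(f)]]
    n_stim <- length(rec$stim_times)
    if (!n_stim) return(NA_real_)
    ff <- features[features$pacing_freq == f, , drop = FALSE]
    sum(ff$stimulated) / n_stim
  }, numeric(1))
  names(capture) <- as.character(freqs)
  summ <- suppressWarnings(summarise_location(features, min_aps = 1))
  imp <- detect_impaired_shortening(summ, capture)

  events <- events[order(events$pacing_freq, events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(events = events, apd_alternans = altern,
                 impaired_shortening = imp,
                 capture_ratios = capture,
                 tissue_arrhythmia = nrow(events) > 0),
            class = "abnormality_report")
}

#' @export
print.abnormality_report <- function(x, ...) {
  cat(sprintf("<abnormality_report> tissue arrhythmia: %s (%d event(s))\n",
              x$tissue_arrhythmia, nrow(x$events)))
  if (nrow(x$events)) print(table(x$events$type))
  cat("APD alternans by frequency:\n")
  print(x$apd_alternans)
  cat(sprintf("impaired shortening: %s\n",
              format(x$impaired_shortening$flag)))
  invisible(x)
}

#' Patient-level abnormality summary
#'
#' A patient is positive for each abnormality when any of their locations
#' is positive (indeterminate locations are ignored).
#'
#' @param reports named list of `abnormality_report` objects (one per
#'   location), names are location ids.
#' @param patient_id identifier for the output row.
#' @return one-row data.frame with logical columns `tissue_arrhythmias`,
#'   `impaired_apd_shortening`, `apd_alternans`.
#' @export
summarise_abnormalities <- function(reports, patient_id = "P01") {
  any_na <- function(x) if (all(is.na(x))) NA else any(x, na.rm = TRUE)
  data.frame(
    patient_id = patient_id,
    tissue_arrhythmias = any(vapply(reports, `[[`, logical(1),
                                    "tissue_arrhythmia")),
    impaired_apd_shortening = any_na(vapply(reports, function(r)
      as.logical(r$impaired_shortening$flag), logical(1))),
    apd_alternans = any_na(unlist(lapply(reports, `[[`, "apd_alternans"))))
}
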
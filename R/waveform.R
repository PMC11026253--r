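## Parametric action-potential waveform with analytically known shape
## properties. The curve is piecewise (baseline -> upstroke -> plateau ->
## repolarisation), deliberately not a biophysical ionic model: every feature
## the extractor measures (RMP, APA, dV/dt_max, APD20/50/90, AUC90) has a
## closed form, so the generator can serve as ground truth.

#' Action-potential waveform parameters
#'
#' Defines one stylised ventricular action potential. Durations are measured
#' from activation (upstroke onset). `plateau_fraction` positions the end of
#' the plateau at `plateau_fraction * apd90_ms`, which controls the
#' APD20/APD90 ratio; the repolarisation phase then declines either linearly
#' or as a half-cosine ("sigmoidal") so that the 90% crossing lands exactly
#' at `apd90_ms`.
#'
#' @param rmp_mV resting membrane potential, mV (typically -85 .. -65).
#' @param apa_mV action-potential amplitude, mV; must be > 0.
#' @param upstroke_duration_ms linear upstroke rise time, ms (>= 0; 0 means
#'   an instantaneous step, useful for geometric test cases).
#' @param apd90_ms target duration at 90% repolarisation, ms.
#' @param plateau_fraction unitless in \[0, 1\]; fraction of `apd90_ms` spent
#'   at peak potential before repolarisation starts.
#' @param repolarisation_shape `"sigmoidal"` (half-cosine decline, smooth
#'   shoulders) or `"linear"` (constant-slope decline).
#' @return an object of class `ap_params`.
#' @export
#' @examples
#' p <- ap_params(apa_mV = 100, apd90_ms = 250)
#' ap_ground_truth(p)$apd90_ms
ap_params <- function(rmp_mV = -80, apa_mV = 100, upstroke_duration_ms = 1,
                      apd90_ms = 250, plateau_fraction = 0.5,
                      repolarisation_shape = c("sigmoidal", "linear")) {
  repolarisation_shape <- match.arg(repolarisation_shape)
  check_that(is.finite(apa_mV) && apa_mV > 0, "apa_mV must be > 0 (got %g)", apa_mV)
  check_that(upstroke_duration_ms >= 0, "upstroke_duration_ms must be >= 0")
  check_that(apd90_ms > upstroke_duration_ms,
             "apd90_ms (%g) must exceed upstroke_duration_ms (%g)",
             apd90_ms, upstroke_duration_ms)
  check_that(plateau_fraction >= 0 && plateau_fraction <= 1,
             "plateau_fraction must lie in [0, 1]")
  structure(list(rmp_mV = rmp_mV, apa_mV = apa_mV,
                 upstroke_duration_ms = upstroke_duration_ms,
                 apd90_ms = apd90_ms, plateau_fraction = plateau_fraction,
                 repolarisation_shape = repolarisation_shape),
            class = "ap_params")
}

## Fraction of the decline duration elapsed at the (1 - level) crossing of a
## half-cosine decline, and the normalised area under the decline up to that
## crossing. For level x the crossing is at acos(1 - 2x)/pi of the decline.
.cos_cross <- function(level) acos(1 - 2 * level) / pi

.decline_geometry <- function(shape, apd90_after_plateau) {
  if (shape == "linear") {
    d <- apd90_after_plateau / 0.9
    list(duration = d,
         t20 = 0.2 * d, t50 = 0.5 * d, t90 = 0.9 * d,
         # area of normalised voltage from decline start to the 90% crossing
         area90 = d * (0.9 - 0.9^2 / 2))
  } else {
    c90 <- .cos_cross(0.9)
    d <- apd90_after_plateau / c90
    list(duration = d,
         t20 = .cos_cross(0.2) * d, t50 = 0.5 * d, t90 = c90 * d,
         area90 = d * (0.5 * c90 + sin(pi * c90) / (2 * pi)))
  }
}

#' Analytic ground-truth features of an `ap_params` waveform
#'
#' Returns the shape properties the feature extractor is expected to recover,
#' all in closed form: APD20/50/90 from the piecewise geometry, AUC90 as the
#' exact integral of the supra-baseline voltage to the 90% crossing, and
#' dV/dt_max as the constant slope of the linear upstroke.
#'
#' @param params an `ap_params` object.
#' @return list with `rmp_mV`, `apa_mV`, `dvdt_max_Vps`, `apd20_ms`,
#'   `apd50_ms`, `apd90_ms`, `auc90_mVs`, `plateau_end_ms`, `total_ms`
#'   (activation to full return to baseline).
#' @export
ap_ground_truth <- function(params) {
  stopifnot(inherits(params, "ap_params"))
  u <- params$upstroke_duration_ms
  plateau_end <- max(u, params$plateau_fraction * params$apd90_ms)
  check_that(params$apd90_ms > plateau_end,
             "apd90_ms must exceed the plateau end (%g ms)", plateau_end)
  g <- .decline_geometry(params$repolarisation_shape,
                         params$apd90_ms - plateau_end)
  auc90 <- (u / 2 + (plateau_end - u) + g$area90) * params$apa_mV / 1000
  list(rmp_mV = params$rmp_mV,
       apa_mV = params$apa_mV,
       dvdt_max_Vps = if (u > 0) params$apa_mV / u else Inf,
       apd20_ms = plateau_end + g$t20,
       apd50_ms = plateau_end + g$t50,
       apd90_ms = params$apd90_ms,
       auc90_mVs = auc90,
       plateau_end_ms = plateau_end,
       total_ms = plateau_end + g$duration)
}

#' Normalised waveform value at times after activation
#'
#' @param t_ms times in ms from activation (upstroke onset); may be a vector.
#' @param params an `ap_params` object.
#' @return normalised voltage in \[0, 1\]; multiply by `apa_mV` and add
#'   `rmp_mV` for the membrane potential.
#' @keywords internal
ap_vnorm <- function(t_ms, params) {
  u <- params$upstroke_duration_ms
  plateau_end <- max(u, params$plateau_fraction * params$apd90_ms)
  g <- .decline_geometry(params$repolarisation_shape,
                         params$apd90_ms - plateau_end)
  v <- numeric(length(t_ms))
  if (u > 0) {
    i <- t_ms >= 0 & t_ms < u
    v[i] <- t_ms[i] / u
  }
  i <- t_ms >= u & t_ms <= plateau_end
  v[i] <- 1
  i <- t_ms > plateau_end & t_ms < plateau_end + g$duration
  s <- (t_ms[i] - plateau_end) / g$duration
  v[i] <- if (params$repolarisation_shape == "linear") 1 - s
          else 0.5 * (1 + cos(pi * s))
  v
}

#' Generate a sampled action-potential waveform
#'
#' Samples the parametric curve on a regular grid, with a short baseline pad
#' before activation and after full repolarisation so the series starts and
#' ends at the resting potential.
#'
#' @param params an `ap_params` object.
#' @param sampling_rate sampling rate in Hz; must be >= 1000 to resolve a
#'   ~1 ms upstroke.
#' @param pre_ms,post_ms baseline padding before activation / after return to
#'   baseline, ms.
#' @return list with `voltage_mV` (numeric vector), `sampling_rate`,
#'   `onset_s` (activation time from the start of the series), and `truth`
#'   (see [ap_ground_truth()]).
#' @export
generate_ap_waveform <- function(params, sampling_rate = 10000,
                                 pre_ms = 30, post_ms = 20) {
  stopifnot(inherits(params, "ap_params"))
  check_that(sampling_rate >= 1000,
             "sampling_rate must be >= 1000 Hz to resolve the upstroke (got %g)",
             sampling_rate)
  truth <- ap_ground_truth(params)
  n <- ceiling((pre_ms + truth$total_ms + post_ms) / 1000 * sampling_rate) + 1L
  t_ms <- (seq_len(n) - 1L) / sampling_rate * 1000 - pre_ms
  v <- params$rmp_mV + params$apa_mV * ap_vnorm(t_ms, params)
  list(voltage_mV = v, sampling_rate = sampling_rate,
       onset_s = pre_ms / 1000, truth = truth)
}
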
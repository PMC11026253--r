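## End-to-end orchestration: simulate -> extract -> detect -> quantify ->
## fit -> report, from a single validated config with a mandatory seed.
## Every stage writes plain-text outputs (CSV/JSON/PNG) into the output
## directory and the run manifest records the config, seeds, package
## version and MD5 checksums — enough to reproduce the run bit-identically
## for the deterministic stages.

#' Default pipeline configuration
#'
#' Returns the full default config as a nested list. Sizes are desk-scale
#' (a handful of patients for the trace and histology arms, the standard
#' 25 x 3 x 5 cohort for the model arm) so a full run completes in well
#' under a minute; every entry can be overridden.
#'
#' @return nested list of class `run_config`.
#' @export
run_config <- function() {
  structure(list(
    seed = 1,
    output_dir = "rvotep_run",
    waveform = list(rmp_mV = -80, apa_mV = 100, upstroke_duration_ms = 1,
                    apd90_ms = 250, plateau_fraction = 0.5,
                    repolarisation_shape = "sigmoidal"),
    traces = list(n_patients = 2, locations_per_patient = 2,
                  freqs = c(1, 2), n_beats = 10, sampling_rate = 5000,
                  noise_sd = 0.5, artifact_amp = 20),
    abnormalities = list(ead_prob = 0, extrasystole_prob = 0,
                         couplet_prob = 0, alternans_depth_ms = 0,
                         capture_failure_freqs_hz = numeric(0)),
    detectors = list(blanking_ms = 5, capture_window_ms = 50,
                     apa_threshold_mV = 75, ead_min_prominence_mV = 5,
                     couplet_max_interval_s = 0.5, alternans_min_beats = 6,
                     alternans_abs_ms = 5, alternans_rel = 0.05),
    histology = list(n_patients = 2, sections_per_patient = 3,
                     width_px = 240, height_px = 240,
                     collagen_fraction = 0.159, endocardium_band_px = 10,
                     gap_fraction = 0.05, min_saturation = 0.25,
                     max_value = 0.95, min_thickness_px = 8,
                     min_sections = 30),
    cohort = list(n_patients = 25, locations_per_patient = 3,
                  freqs = c(0.5, 1, 2, 3, 4)),
    models = list(estimation = "REML", p_method = "satterthwaite")),
    class = "run_config")
}

## merge user overrides over defaults, rejecting unknown keys
.merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    check_that(k %in% names(defaults), "unknown config key '%s'", full)
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]], full)
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' @param config either a nested list of overrides or a path to a YAML
#'   file; unknown keys raise a validation error naming the key.
#' @return a complete validated `run_config`.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "run_config")) return(config)
  cfg <- .merge_config(unclass(run_config()), config)
  check_that(is.numeric(cfg$seed) && length(cfg$seed) == 1,
             "config 'seed' is mandatory and must be a single integer")
  structure(cfg, class = "run_config")
}

#' Run the full pipeline
#'
#' Stages: simulate the cohort feature table; simulate paced recordings,
#' extract features and detect abnormalities; simulate histology sections
#' and quantify percent-fibrosis; fit the association models; write the
#' results-table CSV and a run manifest with checksums. Any stage failure
#' halts with the stage name in the error message.
#'
#' @param config overrides, YAML path, or a `run_config`.
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_config(config)
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "traces"), showWarnings = FALSE)
  dir.create(file.path(out, "histology"), showWarnings = FALSE)
  written <- character(0)
  add <- function(p) written <<- c(written, p)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ## --- cohort simulation + association models -------------------------
  stage("simulate-cohort", {
    cohort <- generate_cohort(cohort_model(),
                              n_patients = cfg$cohort$n_patients,
                              locations_per_patient = cfg$cohort$locations_per_patient,
                              freqs = cfg$cohort$freqs, seed = cfg$seed)
    write_cohort(cohort, file.path(out, "cohort.csv"))
    add(file.path(out, "cohort.csv"))
  })
  stage("fit-models", {
    fits <- lapply(.ap_dependents, function(d)
      fit_ap_mixed_model(cohort, model_spec(
        d, estimation = cfg$models$estimation,
        p_method = cfg$models$p_method)))
    tab <- render_results_table(fits)
    utils::write.csv(tab, file.path(out, "model_results.csv"),
                     row.names = FALSE)
    add(file.path(out, "model_results.csv"))
    jsonlite::write_json(
      list(adj_r2 = as.list(attr(tab, "adj_r2"))),
      file.path(out, "model_meta.json"), auto_unbox = TRUE, digits = NA)
    add(file.path(out, "model_meta.json"))
  })

  ## --- trace simulation, feature extraction, abnormality detection ----
  if (cfg$traces$n_patients > 0) stage("simulate-traces", {
    wf <- do.call(ap_params, cfg$waveform)
    ab <- do.call(abnormality_config, cfg$abnormalities)
    feats <- list()
    reports <- list()
    patient_rows <- list()
    i <- 0L
    for (p in seq_len(cfg$traces$n_patients)) {
      pid <- sprintf("P%02d", p)
      loc_reports <- list()
      for (l in seq_len(cfg$traces$locations_per_patient)) {
        lid <- sprintf("L%02d", l)
        recs <- list()
        loc_feats <- list()
        for (f in cfg$traces$freqs) {
          i <- i + 1L
          sim <- generate_recording(
            wf, pacing_freq = f, n_beats = cfg$traces$n_beats,
            abnormalities = ab, noise_sd = cfg$traces$noise_sd,
            artifact_amp = cfg$traces$artifact_amp,
            seed = cfg$seed + 17L * i,
            sampling_rate = cfg$traces$sampling_rate)
          rec <- sim$recording
          rec$patient_id <- pid
          rec$location_id <- lid
          pr <- file.path(out, "traces", sprintf("%s_%s_%gHz", pid, lid, f))
          add(write_trace(rec, pr, seed = cfg$seed + 17L * i))
          recs[[as.character(f)]] <- rec
          loc_feats[[as.character(f)]] <- extract_features(
            rec, blanking_ms = cfg$detectors$blanking_ms,
            capture_window_ms = cfg$detectors$capture_window_ms,
            apa_threshold_mV = cfg$detectors$apa_threshold_mV)
        }
        ff <- do.call(rbind, loc_feats)
        feats[[paste(pid, lid)]] <- ff
        rep <- abnormality_report(
          ff, recs,
          min_prominence_mV = cfg$detectors$ead_min_prominence_mV,
          couplet_max_interval_s = cfg$detectors$couplet_max_interval_s,
          min_beats = cfg$detectors$alternans_min_beats,
          abs_ms = cfg$detectors$alternans_abs_ms,
          rel = cfg$detectors$alternans_rel)
        loc_reports[[lid]] <- rep
        jp <- file.path(out, sprintf("abnormalities_%s_%s.json", pid, lid))
        jsonlite::write_json(
          list(patient_id = pid, location_id = lid,
               events = rep$events,
               apd_alternans = as.list(rep$apd_alternans),
               impaired_shortening = rep$impaired_shortening,
               tissue_arrhythmia = rep$tissue_arrhythmia),
          jp, auto_unbox = TRUE, digits = NA, na = "null")
        add(jp)
      }
      patient_rows[[pid]] <- summarise_abnormalities(loc_reports, pid)
    }
    all_feats <- do.call(rbind, feats)
    utils::write.csv(all_feats, file.path(out, "ap_features.csv"),
                     row.names = FALSE)
    add(file.path(out, "ap_features.csv"))
    summ <- suppressWarnings(summarise_location(all_feats))
    utils::write.csv(summ, file.path(out, "location_summary.csv"),
                     row.names = FALSE)
    add(file.path(out, "location_summary.csv"))
    pt <- do.call(rbind, patient_rows)
    utils::write.csv(pt, file.path(out, "patient_abnormalities.csv"),
                     row.names = FALSE)
    add(file.path(out, "patient_abnormalities.csv"))
  })

  ## --- histology simulation and quantification ------------------------
  if (cfg$histology$n_patients > 0) stage("quantify-fibrosis", {
    hc <- cfg$histology
    per_section <- list()
    per_patient <- list()
    j <- 0L
    for (p in seq_len(hc$n_patients)) {
      pid <- sprintf("P%02d", p)
      vals <- numeric(0)
      for (s in seq_len(hc$sections_per_patient)) {
        j <- j + 1L
        sec <- generate_histology_image(
          histology_truth(hc$collagen_fraction, hc$endocardium_band_px,
                          hc$gap_fraction),
          width_px = hc$width_px, height_px = hc$height_px,
          seed = cfg$seed + 31L * j)
        ip <- file.path(out, "histology", sprintf("%s_S%02d.png", pid, s))
        write_histology_image(sec, ip)
        add(ip)
        q <- quantify_section(sec$image, sprintf("%s_S%02d", pid, s),
                              min_saturation = hc$min_saturation,
                              max_value = hc$max_value,
                              min_thickness_px = hc$min_thickness_px)
        q$patient_id <- pid
        per_section[[j]] <- q
        vals <- c(vals, q$percent_fibrosis)
      }
      agg <- suppressWarnings(aggregate_patient(vals,
                                                min_sections = hc$min_sections))
      agg$patient_id <- pid
      per_patient[[pid]] <- agg
    }
    utils::write.csv(do.call(rbind, per_section),
                     file.path(out, "fibrosis_sections.csv"),
                     row.names = FALSE)
    add(file.path(out, "fibrosis_sections.csv"))
    utils::write.csv(do.call(rbind, per_patient),
                     file.path(out, "fibrosis_patients.csv"),
                     row.names = FALSE)
    add(file.path(out, "fibrosis_patients.csv"))
  })

  ## --- manifest --------------------------------------------------------
  written <- sort(unique(written))
  sums <- tools::md5sum(written)
  manifest <- list(
    package = "rvotep",
    package_version = as.character(utils::packageVersion("rvotep")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = unclass(cfg),
    outputs = as.list(stats::setNames(unname(sums),
                                      sub(paste0("^", out, "/?"), "", names(sums)))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Validate input files without running the pipeline
#'
#' Checks each path and reports a verdict instead of crashing: trace CSVs
#' need monotone time and a complete JSON sidecar; images must be readable
#' RGB; anything else is reported as unrecognised.
#'
#' @param paths character vector of file paths.
#' @return data.frame: `file`, `kind`, `valid`, `detail`.
#' @export
validate_inputs <- function(paths) {
  rows <- lapply(paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    if (!file.exists(p))
      return(data.frame(file = p, kind = "missing", valid = FALSE,
                        detail = "file not found"))
    if (ext == "csv") {
      res <- tryCatch({
        read_trace(p)
        list(TRUE, "ok")
      }, error = function(e) list(FALSE, conditionMessage(e)))
      return(data.frame(file = p, kind = "trace", valid = res[[1]],
                        detail = res[[2]]))
    }
    if (ext %in% c("png", "tif", "tiff")) {
      res <- tryCatch({
        read_histology_image(p)
        list(TRUE, "ok")
      }, error = function(e) list(FALSE, conditionMessage(e)))
      return(data.frame(file = p, kind = "image", valid = res[[1]],
                        detail = res[[2]]))
    }
    data.frame(file = p, kind = "unknown", valid = FALSE,
               detail = sprintf("unrecognised extension '%s'", ext))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
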
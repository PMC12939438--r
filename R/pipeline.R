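#' Extract all 21 biosignal features from one recording
#'
#' Runs the EDA chain (preprocess, CDA decomposition + SCR detection,
#' trough-to-peak scoring, 14 features) on the `eda` channel and the HRV
#' chain (QRS detection, RR screening, time- and frequency-domain features)
#' on the `ecg` channel. A missing channel yields `NA` for that block.
#'
#' @param rec A [recording()].
#' @param amp_threshold SCR amplitude threshold (µS).
#' @param ttp_window Trough-to-peak rise-time window (s).
#' @param rr_series Optional pre-computed `rr_series` to use instead of the
#'   ECG channel (e.g. when RR was acquired directly).
#' @return One-row data.frame: `patient_id`, 14 EDA features, 7 HRV
#'   features, and QC columns `qc_n_beats`, `qc_rr_dropped`.
#' @export
extract_features <- function(rec, amp_threshold = 0.05,
                             ttp_window = c(1, 5), rr_series = NULL) {
  eda_feats <- as.data.frame(
    setNames(as.list(rep(NA_real_, 14)), eda_feature_names()))
  eda_feats$nSCR_CDA <- NA_integer_
  eda_feats$nSCR_TTP <- NA_integer_
  hrv_feats <- as.data.frame(
    setNames(as.list(rep(NA_real_, 7)), hrv_feature_names()))
  qc <- data.frame(qc_n_beats = NA_integer_, qc_rr_dropped = NA_integer_)

  if (!is.null(rec$channels$eda)) {
    pre <- preprocess_eda(rec$channels$eda)
    dec <- decompose_cda(pre)
    cda_ev <- detect_scr_cda(dec, amp_threshold)
    ttp_ev <- analyze_ttp(pre, amp_threshold, ttp_window)
    eda_feats <- extract_eda_features(cda_ev, ttp_ev)
  }
  rrs <- rr_series
  if (is.null(rrs) && !is.null(rec$channels$ecg)) {
    peaks <- detect_r_peaks(rec$channels$ecg)
    rrs <- build_rr(peaks, rec$channels$ecg$fs)
  }
  if (!is.null(rrs)) {
    hrv_feats <- extract_hrv_features(rrs)
    qc <- data.frame(qc_n_beats = rrs$n_beats,
                     qc_rr_dropped = rrs$n_dropped)
  }
  cbind(data.frame(patient_id = rec$patient_id, stringsAsFactors = FALSE),
        eda_feats, hrv_feats, qc)
}

# Write a recording as one CSV when channels share a rate, otherwise one
# file per channel (<id>_ecg.csv / <id>_eda.csv).
write_recording_files <- function(rec, dir) {
  fs <- unique(vapply(rec$channels, function(ch) ch$fs, numeric(1)))
  if (length(fs) == 1) {
    write_recording_csv(rec, file.path(dir, paste0(rec$patient_id, ".csv")))
  } else {
    for (nm in names(rec$channels))
      write_recording_csv(
        recording(rec$patient_id, rec$channels[nm]),
        file.path(dir, paste0(rec$patient_id, "_", nm, ".csv")))
  }
  invisible(dir)
}

# Counterpart of write_recording_files: single <id>.csv or per-channel
# <id>_<channel>.csv files merged into one recording.
read_recording_files <- function(patient_id, dir) {
  single <- file.path(dir, paste0(patient_id, ".csv"))
  if (file.exists(single))
    return(read_recording(single, "csv", patient_id = patient_id))
  chans <- list()
  for (nm in c("ecg", "eda")) {
    p <- file.path(dir, paste0(patient_id, "_", nm, ".csv"))
    if (file.exists(p))
      chans[nm] <- read_recording(p, "csv", patient_id = patient_id)$channels[nm]
  }
  if (length(chans) == 0)
    stop("no recording files found for patient ", patient_id, call. = FALSE)
  recording(as.character(patient_id), chans)
}

#' Validate a pipeline run configuration
#'
#' @param config Named list (or path to a YAML file) with at least `mode`
#'   (`"simulate"` or `"analyze"`) and `out_dir`; simulate mode requires
#'   `seed` (plus optional `n_patients`, `duration_s`, `fs_ecg`, `fs_eda`);
#'   analyze mode requires `input_dir` containing `cohort.csv` and
#'   `recordings/<patient_id>.csv`. Optional knobs: `amp_threshold`,
#'   `ttp_window`, `groupings`, `strata`, `write_recordings`.
#' @return The validated config list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$mode) || !config$mode %in% c("simulate", "analyze"))
    stop("config `mode` must be \"simulate\" or \"analyze\"", call. = FALSE)
  if (is.null(config$out_dir))
    stop("config `out_dir` is required", call. = FALSE)
  if (config$mode == "simulate" && is.null(config$seed))
    stop("config `seed` is mandatory in simulate mode", call. = FALSE)
  if (config$mode == "analyze") {
    if (is.null(config$input_dir))
      stop("config `input_dir` is required in analyze mode", call. = FALSE)
    if (!dir.exists(config$input_dir))
      stop("config `input_dir` does not exist: ", config$input_dir,
           call. = FALSE)
    if (!file.exists(file.path(config$input_dir, "cohort.csv")))
      stop("cohort.csv not found under input_dir", call. = FALSE)
  }
  config
}

#' Run the end-to-end pipeline
#'
#' In `simulate` mode a synthetic cohort is generated from the config's
#' seed; in `analyze` mode a cohort table and per-patient CSV recordings are
#' loaded from `input_dir` and trimmed to the common shortest length.
#' Features are then extracted per patient (failures are isolated, logged
#' and yield `NA` features) and the group-comparison framework is run.
#' Artifacts written under `out_dir`: `cohort.csv`, `features.csv`,
#' `rr/<patient_id>.csv`, the three comparison CSVs and `run_log.txt` with
#' seed, package version and per-patient QC.
#'
#' @param config See [validate_run_config()].
#' @return The [run_comparisons()] report, invisibly; features and cohort
#'   are attached as attributes `features` and `cohort`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "rr"), showWarnings = FALSE)
  log_lines <- c(sprintf("edahrv_version=%s",
                         as.character(utils::packageVersion("edahrv"))),
                 sprintf("mode=%s", config$mode),
                 sprintf("seed=%s", config$seed %||% "NA"))

  if (config$mode == "simulate") {
    spec <- cohort_spec(
      n_patients = config$n_patients %||% 64,
      duration_s = config$duration_s %||% 180,
      fs_ecg = config$fs_ecg %||% 1000,
      fs_eda = config$fs_eda %||% 100,
      seed = config$seed)
    sim <- generate_cohort(spec)
    cohort <- sim$cohort
    recordings <- sim$recordings
    if (isTRUE(config$write_recordings)) {
      dir.create(file.path(out, "recordings"), showWarnings = FALSE)
      for (r in recordings) write_recording_files(r, file.path(out,
                                                               "recordings"))
    }
  } else {
    cohort <- read.csv(file.path(config$input_dir, "cohort.csv"))
    rec_dir <- file.path(config$input_dir, "recordings")
    recordings <- lapply(cohort$patient_id, read_recording_files, rec_dir)
    recordings <- trim_to_common_length(recordings)
  }

  rows <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    rows[[i]] <- tryCatch({
      f <- extract_features(rec,
                            amp_threshold = config$amp_threshold %||% 0.05,
                            ttp_window = config$ttp_window %||% c(1, 5))
      log_lines <- c(log_lines, sprintf(
        "patient=%s status=ok n_beats=%s nSCR_CDA=%s nSCR_TTP=%s",
        rec$patient_id, f$qc_n_beats, f$nSCR_CDA, f$nSCR_TTP))
      if (!is.na(f$qc_n_beats) && !is.null(rec$channels$ecg)) {
        rrs <- build_rr(detect_r_peaks(rec$channels$ecg),
                        rec$channels$ecg$fs)
        write.csv(data.frame(t = rrs$t, rr = rrs$rr),
                  file.path(out, "rr", paste0(rec$patient_id, ".csv")),
                  row.names = FALSE)
      }
      f
    }, error = function(e) {
      log_lines <<- c(log_lines, sprintf("patient=%s status=failed error=%s",
                                         rec$patient_id,
                                         conditionMessage(e)))
      cbind(data.frame(patient_id = rec$patient_id),
            as.data.frame(setNames(as.list(rep(NA_real_, 21)),
                                   c(eda_feature_names(),
                                     hrv_feature_names()))),
            data.frame(qc_n_beats = NA_integer_,
                       qc_rr_dropped = NA_integer_))
    })
  }
  features <- do.call(rbind, rows)
  write.csv(features, file.path(out, "features.csv"), row.names = FALSE)
  write.csv(cohort, file.path(out, "cohort.csv"), row.names = FALSE)

  report <- run_comparisons(
    features[, c("patient_id", eda_feature_names(), hrv_feature_names())],
    cohort,
    groupings = config$groupings %||% c("pain_intensity_class", "pain_type"),
    strata = config$strata %||% c("bone_metastases", "btcp", "med_over_60"))
  write_comparison_report(report, out)
  writeLines(log_lines, file.path(out, "run_log.txt"))
  attr(report, "features") <- features
  attr(report, "cohort") <- cohort
  invisible(report)
}
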
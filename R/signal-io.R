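#' Convert raw ADC counts to microsiemens (EDA transfer function)
#'
#' Vendor transfer function for the finger EDA sensor:
#' `uS = ((raw / 2^n_bits) * vcc) / 0.132`.
#'
#' @param raw Integer counts in `[0, 2^n_bits - 1]`.
#' @param n_bits Converter resolution.
#' @param vcc Operating voltage (V), default 3.3.
#' @param divisor Sensor constant (default 0.132).
#' @return Numeric vector in microsiemens.
#' @export
adc_to_microsiemens <- function(raw, n_bits, vcc = 3.3, divisor = 0.132) {
  check_adc_range(raw, n_bits)
  ((raw / 2^n_bits) * vcc) / divisor
}

#' Convert raw ADC counts to millivolts (ECG transfer function)
#'
#' Vendor transfer function for the single-lead ECG sensor:
#' `mV = ((raw / 2^n_bits - 0.5) * vcc) / gain * 1000`.
#'
#' @inheritParams adc_to_microsiemens
#' @param gain Sensor gain, default 1100.
#' @return Numeric vector in millivolts.
#' @export
adc_to_millivolts <- function(raw, n_bits, vcc = 3.3, gain = 1100) {
  check_adc_range(raw, n_bits)
  ((raw / 2^n_bits - 0.5) * vcc) / gain * 1000
}

check_adc_range <- function(raw, n_bits) {
  if (any(raw < 0) || any(raw > 2^n_bits - 1))
    stop(sprintf("raw counts outside [0, %d] for a %d-bit converter",
                 2^n_bits - 1, n_bits), call. = FALSE)
  invisible(raw)
}

# Inverse transfer functions, used to build raw-count fixtures.
microsiemens_to_adc <- function(us, n_bits, vcc = 3.3, divisor = 0.132) {
  pmin(2^n_bits - 1, pmax(0, round(us * divisor / vcc * 2^n_bits)))
}
millivolts_to_adc <- function(mv, n_bits, vcc = 3.3, gain = 1100) {
  pmin(2^n_bits - 1, pmax(0, round((mv / 1000 * gain / vcc + 0.5) * 2^n_bits)))
}

#' Write a recording as plain CSV
#'
#' Column 1 is time in seconds; remaining columns are the channels in
#' physical units (`ecg` in mV, `eda` in microsiemens), one header row.
#'
#' @param rec A [recording()] whose channels share one sampling rate.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  fs <- unique(vapply(rec$channels, function(ch) ch$fs, numeric(1)))
  if (length(fs) != 1)
    stop("CSV export requires all channels at one sampling rate; ",
         "write channels separately otherwise", call. = FALSE)
  n <- unique(vapply(rec$channels, function(ch) length(ch$samples),
                     integer(1)))
  if (length(n) != 1)
    stop("channels differ in length; trim before export", call. = FALSE)
  df <- data.frame(time = sprintf("%.17g", (seq_len(n) - 1) / fs))
  # full 17-digit precision so samples survive a write/read round trip
  for (nm in names(rec$channels))
    df[[nm]] <- sprintf("%.17g", rec$channels[[nm]]$samples)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a recording as OpenSignals-style tab-separated text
#'
#' Emits a `#`-prefixed header (with a JSON device block carrying
#' `"sampling rate"`, `"resolution"` and channel labels) followed by
#' tab-separated raw ADC rows. Channels must be in `adc` units (see
#' [signal_channel()]).
#'
#' @inheritParams write_recording_csv
#' @return `path`, invisibly.
#' @export
write_recording_opensignals <- function(rec, path) {
  for (ch in rec$channels)
    if (ch$units != "adc")
      stop("OpenSignals export expects adc-unit channels", call. = FALSE)
  fs <- unique(vapply(rec$channels, function(ch) ch$fs, numeric(1)))
  if (length(fs) != 1)
    stop("all channels must share one sampling rate", call. = FALSE)
  labels <- toupper(names(rec$channels))
  header <- list(device = list(
    "sampling rate" = fs,
    resolution = vapply(rec$channels, function(ch) ch$n_bits, numeric(1),
                        USE.NAMES = FALSE),
    column = c("nSeq", labels),
    label = labels))
  lines <- c(
    "# OpenSignals Text File Format",
    paste0("# ", jsonlite::toJSON(header, auto_unbox = TRUE)),
    "# EndOfHeader")
  n <- length(rec$channels[[1]]$samples)
  mat <- cbind(seq_len(n) - 1,
               do.call(cbind, lapply(rec$channels, function(ch) ch$samples)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.table(mat, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a recording from disk
#'
#' Supports two dialects: plain CSV (optional uniform `time` column,
#' channels in physical units) and OpenSignals text (`#` header lines with a
#' JSON device block, tab-separated raw ADC rows; channels come back in
#' `adc` units with their resolution, ready for [adc_to_microsiemens()] /
#' [adc_to_millivolts()]).
#'
#' @param path File path.
#' @param format `"csv"` or `"opensignals"`.
#' @param fs Sampling rate in Hz; required for CSV files without a time
#'   column, ignored otherwise.
#' @param patient_id Defaults to the file name without extension.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("csv", "opensignals"),
                           fs = NULL, patient_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty file: ", path, call. = FALSE)
  patient_id <- patient_id %||% sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") read_recording_csv(path, fs, patient_id)
  else read_recording_opensignals(path, patient_id)
}

read_recording_csv <- function(path, fs, patient_id) {
  df <- read.csv(path)
  if (nrow(df) == 0) stop("no data rows in ", path, call. = FALSE)
  if ("time" %in% names(df)) {
    dt <- diff(df$time)
    if (any(dt <= 0))
      stop("non-monotonic time column in ", path, call. = FALSE)
    if (max(abs(dt - median(dt))) > 0.01 * median(dt))
      stop("irregular sampling (time steps deviate > 1%) in ", path,
           call. = FALSE)
    fs <- 1 / median(dt)
    # snap to integer Hz when within rounding noise of the time column
    if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
  } else if (is.null(fs)) {
    stop("CSV has no time column; supply `fs`", call. = FALSE)
  }
  present <- intersect(c("ecg", "eda"), names(df))
  if (length(present) == 0)
    stop("missing channel columns (expected `ecg` and/or `eda`) in ", path,
         call. = FALSE)
  chans <- lapply(setNames(present, present), function(nm)
    signal_channel(df[[nm]], fs, units = if (nm == "eda") "uS" else "mV"))
  recording(patient_id, chans)
}

read_recording_opensignals <- function(path, patient_id) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (length(hdr) == 0)
    stop("unparseable OpenSignals header in ", path, call. = FALSE)
  json_line <- grep("^#\\s*\\{", lines, value = TRUE)
  if (length(json_line) == 0)
    stop("unparseable OpenSignals header (no JSON block) in ", path,
         call. = FALSE)
  meta <- tryCatch(
    jsonlite::fromJSON(sub("^#\\s*", "", json_line[1])),
    error = function(e) stop("unparseable OpenSignals header in ", path,
                             call. = FALSE))
  dev <- meta[["device"]] %||% meta[[1]]
  fs <- dev[["sampling rate"]]
  res <- dev[["resolution"]]
  labels <- dev[["label"]] %||% setdiff(dev[["column"]], "nSeq")
  if (is.null(fs) || is.null(res))
    stop("OpenSignals header lacks sampling rate or resolution in ", path,
         call. = FALSE)
  dat <- read.table(text = lines[-hdr], sep = "\t")
  if (ncol(dat) != length(labels) + 1)
    stop("column count does not match header labels in ", path,
         call. = FALSE)
  res <- rep_len(res, length(labels))
  chans <- list()
  for (j in seq_along(labels)) {
    nm <- tolower(labels[j])
    if (!nm %in% c("ecg", "eda")) next
    chans[[nm]] <- signal_channel(dat[[j + 1]], fs, units = "adc",
                                  n_bits = res[j])
  }
  if (length(chans) == 0)
    stop("missing channel columns (expected ECG and/or EDA labels) in ",
         path, call. = FALSE)
  recording(patient_id, chans)
}

#' Trim a set of recordings to the common shortest duration
#'
#' Every channel of every recording is truncated from the end to the
#' duration of the shortest recording in the set, so that all patients
#' contribute the same observation window (recordings share their onset as
#' the only common anchor).
#'
#' @param recordings Non-empty list of [recording()] objects.
#' @return The list with all channels truncated; durations agree within one
#'   sample period of the coarsest channel.
#' @export
trim_to_common_length <- function(recordings) {
  if (length(recordings) == 0)
    stop("empty recording set", call. = FALSE)
  durs <- vapply(recordings, function(r)
    min(vapply(r$channels, channel_duration, numeric(1))), numeric(1))
  target <- min(durs)
  lapply(recordings, function(r) {
    r$channels <- lapply(r$channels, function(ch) {
      n_keep <- min(length(ch$samples), floor(target * ch$fs + 1e-9))
      ch$samples <- ch$samples[seq_len(n_keep)]
      ch
    })
    r
  })
}
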
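#' Construct a signal channel
#'
#' A `signal_channel` holds one uniformly sampled biosignal trace together
#' with its sampling rate and physical units. Raw analog-to-digital channels
#' (units `"adc"`) additionally carry the converter resolution so they can be
#' mapped to physical units later (see [adc_to_microsiemens()]).
#'
#' @param samples Numeric vector of samples; must be free of `NA`/`NaN`.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param units One of `"uS"` (microsiemens, EDA), `"mV"` (millivolts, ECG)
#'   or `"adc"` (raw counts).
#' @param n_bits Converter resolution in bits; required when `units = "adc"`.
#' @param min_duration_s Minimum accepted duration in seconds. Recordings
#'   shorter than this are rejected as unusable segments.
#'
#' @return An object of class `signal_channel`.
#' @export
signal_channel <- function(samples, fs, units = c("uS", "mV", "adc"),
                           n_bits = NULL, min_duration_s = 10) {
  units <- match.arg(units)
  if (!is.numeric(samples) || length(samples) == 0)
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("`samples` contains NA/NaN/Inf values after loading", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)", call. = FALSE)
  if (length(samples) < fs * min_duration_s)
    stop(sprintf("channel too short: %.2f s < minimum usable segment of %g s",
                 length(samples) / fs, min_duration_s), call. = FALSE)
  if (units == "adc" && is.null(n_bits))
    stop("`n_bits` is required for adc channels", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), fs = fs, units = units,
         n_bits = n_bits),
    class = "signal_channel")
}

#' @export
print.signal_channel <- function(x, ...) {
  cat(sprintf("<signal_channel> %d samples @ %g Hz (%.1f s), units %s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$units))
  invisible(x)
}

channel_duration <- function(ch) length(ch$samples) / ch$fs

#' Construct a patient recording
#'
#' Bundles one patient's synchronized channels (any subset of `ecg`, `eda`)
#' under a patient identifier.
#'
#' @param patient_id Character scalar.
#' @param channels Named list of [signal_channel()] objects; names must be a
#'   subset of `c("ecg", "eda")` and at least one channel must be present.
#'
#' @return An object of class `recording`.
#' @export
recording <- function(patient_id, channels) {
  if (!is.character(patient_id) || length(patient_id) != 1)
    stop("`patient_id` must be a character scalar", call. = FALSE)
  if (!is.list(channels) || length(channels) == 0)
    stop("`channels` must contain at least one channel", call. = FALSE)
  bad <- setdiff(names(channels), c("ecg", "eda"))
  if (length(bad) || is.null(names(channels)))
    stop("channel names must be among {ecg, eda}", call. = FALSE)
  for (ch in channels)
    if (!inherits(ch, "signal_channel"))
      stop("all channels must be signal_channel objects", call. = FALSE)
  structure(list(patient_id = patient_id, channels = channels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> patient %s: %s\n", x$patient_id,
              paste(names(x$channels), collapse = ", ")))
  for (nm in names(x$channels)) {
    cat(" ", nm, ": ")
    print(x$channels[[nm]])
  }
  invisible(x)
}
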
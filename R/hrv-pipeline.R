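#' Detect R-peaks in a single-lead ECG (Pan-Tompkins style)
#'
#' Classic detector chain: zero-phase band-pass 5–15 Hz, five-point
#' derivative, squaring, 150 ms moving-window integration, then dual
#' adaptive thresholds over the integrated signal with a 200 ms refractory
#' period and search-back at half threshold when an expected beat is
#' missed. Accepted integration peaks are mapped back to the raw signal's
#' local maximum to localize the R wave.
#'
#' @param channel A [signal_channel()] in millivolts, `fs >= 100` Hz.
#' @param min_beats Minimum number of detected beats for a usable recording.
#' @return Integer vector of strictly increasing R-peak sample indices.
#' @export
detect_r_peaks <- function(channel, min_beats = 10) {
  if (channel$units != "mV")
    stop("`channel` must be in millivolts", call. = FALSE)
  fs <- channel$fs
  if (fs < 100) stop("ECG sampling rate must be >= 100 Hz", call. = FALSE)
  x <- channel$samples
  bf <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  der <- stats::filter(xf, c(1, 2, 0, -2, -1) / 8, sides = 2)
  der[is.na(der)] <- 0
  sq <- as.numeric(der)^2
  nw <- max(1, round(0.150 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / nw, nw), sides = 1))
  mwi[is.na(mwi)] <- 0

  # candidate peaks: local maxima of the integrated signal
  dm <- diff(mwi)
  sg <- sign(dm)
  for (i in seq_along(sg)) if (sg[i] == 0 && i > 1) sg[i] <- sg[i - 1]
  cand <- which(diff(sg) < 0) + 1
  cand <- cand[mwi[cand] > 0]
  if (length(cand) < min_beats)
    stop(sprintf("fewer than %d beats detected; recording unusable",
                 min_beats), call. = FALSE)

  refr <- round(0.2 * fs)
  init <- mwi[seq_len(min(length(mwi), 2 * fs))]
  spki <- max(init)
  npki <- mean(init) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)
  qrs <- integer(0)
  noise_cand <- integer(0)
  rr_hist <- numeric(0)
  for (ci in seq_along(cand)) {
    i <- cand[ci]
    v <- mwi[i]
    if (length(qrs) && i - qrs[length(qrs)] < refr) next
    if (v > thr1) {
      if (length(qrs)) rr_hist <- c(rr_hist, i - qrs[length(qrs)])
      qrs <- c(qrs, i)
      spki <- 0.125 * v + 0.875 * spki
    } else {
      noise_cand <- c(noise_cand, i)
      npki <- 0.125 * v + 0.875 * npki
      # search-back: missed beat if no QRS for 1.66 * average RR
      if (length(qrs) && length(rr_hist)) {
        rr_avg <- mean(tail(rr_hist, 8))
        if (i - qrs[length(qrs)] > 1.66 * rr_avg) {
          gap <- noise_cand[noise_cand > qrs[length(qrs)] + refr &
                              noise_cand <= i]
          if (length(gap)) {
            best <- gap[which.max(mwi[gap])]
            if (mwi[best] > 0.5 * thr1) {
              rr_hist <- c(rr_hist, best - qrs[length(qrs)])
              qrs <- sort(c(qrs, best))
              spki <- 0.25 * mwi[best] + 0.75 * spki
            }
          }
        }
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (length(qrs) < min_beats)
    stop(sprintf("fewer than %d beats detected; recording unusable",
                 min_beats), call. = FALSE)

  # map integration peaks back to the raw R wave (integration window delay)
  back <- round(0.225 * fs)
  r_idx <- vapply(qrs, function(i) {
    lo <- max(1, i - back)
    lo - 1 + which.max(x[lo:i])
  }, numeric(1))
  r_idx <- sort(unique(r_idx))
  # collapse detections closer than the refractory period
  if (length(r_idx) > 1) {
    keep <- c(TRUE, diff(r_idx) >= refr)
    r_idx <- r_idx[keep]
  }
  as.integer(r_idx)
}

#' Build an RR interval series from R-peak indices
#'
#' `rr_k = (peak_{k+1} - peak_k) / fs`, followed by artifact screening:
#' intervals outside (0.3, 2.0) s, or differing by more than 30% from the
#' running median of the last five accepted intervals, are dropped (not
#' interpolated).
#'
#' @param peaks Strictly increasing R-peak sample indices (>= 11 peaks).
#' @param fs Sampling rate (Hz).
#' @return An object of class `rr_series`: list with `rr` (s), `t` (time of
#'   each interval's closing beat, s), `n_beats`, and `n_dropped`.
#' @export
build_rr <- function(peaks, fs) {
  if (length(peaks) < 11)
    stop("need at least 11 R-peaks to build an RR series", call. = FALSE)
  if (any(diff(peaks) <= 0))
    stop("`peaks` must be strictly increasing", call. = FALSE)
  rr_all <- diff(peaks) / fs
  t_all <- peaks[-1] / fs
  rr <- numeric(0)
  tt <- numeric(0)
  for (i in seq_along(rr_all)) {
    r <- rr_all[i]
    if (r <= 0.3 || r >= 2.0) next
    if (length(rr) >= 3) {
      med <- median(tail(rr, 5))
      if (abs(r - med) > 0.3 * med) next
    }
    rr <- c(rr, r)
    tt <- c(tt, t_all[i])
  }
  if (length(rr) == 0)
    stop("all RR intervals rejected by artifact screening", call. = FALSE)
  structure(list(rr = rr, t = tt, n_beats = length(rr),
                 n_dropped = length(rr_all) - length(rr)),
            class = "rr_series")
}

#' Construct an RR series from known intervals
#'
#' Wraps a plain RR interval vector (e.g. from an external beat annotator
#' or a simulation) in the container used by the HRV feature functions,
#' with beat times defaulting to the cumulative sum.
#'
#' @param rr RR intervals (s), all positive.
#' @param t Times of each interval's closing beat (s); strictly increasing.
#' @return An object of class `rr_series`.
#' @export
rr_series <- function(rr, t = cumsum(rr)) {
  if (any(rr <= 0)) stop("RR intervals must be positive", call. = FALSE)
  if (length(t) != length(rr) || any(diff(t) <= 0))
    stop("`t` must be strictly increasing and match `rr`", call. = FALSE)
  structure(list(rr = rr, t = t, n_beats = length(rr), n_dropped = 0L),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d intervals over %.1f s (mean RR %.3f s, %d dropped)\n",
              x$n_beats, diff(range(x$t)), mean(x$rr), x$n_dropped))
  invisible(x)
}

#' Time-domain HRV features
#'
#' Mean heart rate (bpm), SDNN (sample standard deviation of the RR
#' intervals, ms) and RMSSD (root mean square of successive differences,
#' ms).
#'
#' @param rrs An [build_rr()] `rr_series` with at least 10 intervals.
#' @return One-row data.frame with `mean_hr`, `sdnn`, `rmssd`.
#' @export
time_domain_features <- function(rrs) {
  rr <- rrs$rr
  if (length(rr) < 10)
    stop("need at least 10 RR intervals", call. = FALSE)
  data.frame(mean_hr = 60 / mean(rr),
             sdnn = sd(rr) * 1000,
             rmssd = sqrt(mean(diff(rr)^2)) * 1000)
}

# Welch power spectral density (one-sided, density scaling): Hann-windowed
# segments with per-segment mean removal and 50% overlap. Returns freq (Hz)
# and power density (x^2 per Hz) such that integrating over (0, fs/2]
# approximates the signal variance.
welch_psd <- function(x, fs, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1, floor(seg_len * (1 - overlap)))
  starts <- seq(1, n - seg_len + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)))
  u <- sum(w^2)
  nf <- floor(seg_len / 2) + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    xs <- x[s0:(s0 + seg_len - 1)]
    xs <- (xs - mean(xs)) * w
    X <- fft(xs)
    p <- Mod(X[seq_len(nf)])^2 / (fs * u)
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]  # one-sided (DC/Nyquist not doubled)
    acc <- acc + p
  }
  list(freq = seq(0, by = fs / seg_len, length.out = nf),
       power = acc / length(starts))
}

# Integrate a PSD over [f1, f2] by the trapezoid rule, interpolating the
# density at the exact band edges.
band_power <- function(freq, power, f1, f2) {
  if (f2 <= freq[1] || f1 >= freq[length(freq)]) return(0)
  grid <- sort(unique(c(f1, freq[freq > f1 & freq < f2], f2)))
  pracma::trapz(grid, approx(freq, power, xout = grid, rule = 2)$y)
}

#' Frequency-domain HRV features
#'
#' The RR series is linearly interpolated to a uniform 4 Hz tachogram (in
#' ms), mean-removed, and its PSD estimated by Welch's method (60 s Hann
#' segments, 50% overlap). Band powers (ms^2) are obtained by trapezoidal
#' integration over VLF 0.0033–0.04 Hz, LF 0.04–0.15 Hz and HF
#' 0.15–0.36 Hz; the LF/HF ratio indexes sympatho-vagal balance and is
#' missing when HF power is zero.
#'
#' @param rrs An `rr_series` spanning at least `min_span_s` seconds.
#' @param tachogram_fs Uniform resampling rate (Hz).
#' @param seg_s Welch segment length (s).
#' @param min_span_s Minimum RR span (s).
#' @return One-row data.frame with `vlf_power`, `lf_power`, `hf_power`
#'   (ms^2) and `lf_hf_ratio`.
#' @export
frequency_domain_features <- function(rrs, tachogram_fs = 4, seg_s = 60,
                                      min_span_s = 120) {
  span <- diff(range(rrs$t))
  if (span < min_span_s)
    stop(sprintf("RR series spans %.1f s; at least %g s are required for spectral analysis",
                 span, min_span_s), call. = FALSE)
  t_grid <- seq(min(rrs$t), max(rrs$t), by = 1 / tachogram_fs)
  tach <- approx(rrs$t, rrs$rr * 1000, xout = t_grid)$y
  tach <- tach - mean(tach)
  psd <- welch_psd(tach, tachogram_fs, seg_len = round(seg_s * tachogram_fs))
  vlf <- band_power(psd$freq, psd$power, 0.0033, 0.04)
  lf <- band_power(psd$freq, psd$power, 0.04, 0.15)
  hf <- band_power(psd$freq, psd$power, 0.15, 0.36)
  data.frame(vlf_power = vlf, lf_power = lf, hf_power = hf,
             lf_hf_ratio = if (hf > 0) lf / hf else NA_real_)
}

#' All seven HRV features from an ECG channel or RR series
#'
#' Convenience wrapper chaining [detect_r_peaks()], [build_rr()],
#' [time_domain_features()] and [frequency_domain_features()].
#'
#' @param x A millivolt [signal_channel()] or an `rr_series`.
#' @return One-row data.frame with `mean_hr`, `sdnn`, `rmssd`, `vlf_power`,
#'   `lf_power`, `hf_power`, `lf_hf_ratio`.
#' @export
extract_hrv_features <- function(x) {
  rrs <- if (inherits(x, "rr_series")) x
  else build_rr(detect_r_peaks(x), x$fs)
  cbind(time_domain_features(rrs), frequency_domain_features(rrs))
}
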
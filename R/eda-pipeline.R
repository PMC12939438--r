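#' Preprocess an EDA channel
#'
#' Zero-phase low-pass filtering (4th-order Butterworth, default 1 Hz
#' cutoff) followed by resampling to a common analysis rate (default 10 Hz).
#' Negative conductance values are clipped at zero; a warning is raised when
#' more than 1% of samples required clipping.
#'
#' @param channel A [signal_channel()] in microsiemens.
#' @param cutoff_hz Low-pass cutoff (Hz).
#' @param fs_out Output sampling rate (Hz).
#' @return A [signal_channel()] at `fs_out`.
#' @export
preprocess_eda <- function(channel, cutoff_hz = 1, fs_out = 10) {
  if (channel$units != "uS")
    stop("`channel` must be in microsiemens; convert adc counts first",
         call. = FALSE)
  x <- channel$samples
  fs <- channel$fs
  if (length(x) < 12 * max(1, fs / fs_out))
    stop("channel shorter than filter warm-up", call. = FALSE)
  if (cutoff_hz < fs / 2) {
    bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
    x <- filtfilt_reflect(bf, x, pad_n = round(3 * fs / cutoff_hz))
  }
  if (fs != fs_out) {
    t_in <- (seq_along(x) - 1) / fs
    t_out <- seq(0, max(t_in), by = 1 / fs_out)
    x <- approx(t_in, x, xout = t_out)$y
  }
  n_neg <- sum(x < 0)
  if (n_neg > 0) {
    if (n_neg > 0.01 * length(x))
      warning(sprintf("%.1f%% of samples clipped at 0 uS",
                      100 * n_neg / length(x)), call. = FALSE)
    x[x < 0] <- 0
  }
  signal_channel(x, fs_out, "uS")
}

# Zero-phase filtering with odd-symmetric reflection padding and
# level-offset removal around each pass, suppressing the start/end
# transients of a plain forward-backward pass (exact for constant input).
filtfilt_reflect <- function(bf, x, pad_n) {
  n <- length(x)
  p <- min(pad_n, n - 1)
  xp <- c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[n] - rev(x[(n - p):(n - 1)]))
  one_pass <- function(v) {
    as.numeric(signal::filter(bf, v - v[1])) + v[1]
  }
  y <- rev(one_pass(rev(one_pass(xp))))
  y[p + seq_len(n)]
}

# Nonnegative least squares ||K d - s||^2, d >= 0, where K is the causal
# Toeplitz convolution operator of kernel `k`, solved by FISTA projected
# gradient. Matrix-vector products are FFT convolutions, so one iteration is
# O(n log n). The Lipschitz constant is bounded by sum(k)^2 (the 1-norm *
# inf-norm bound for a lower-triangular Toeplitz operator).
nnls_deconvolve <- function(s, k, max_iter = 800, rel_tol = 1e-6,
                            abs_rmse_tol = 5e-4, init = NULL) {
  n <- length(s)
  nfft <- stats::nextn(n + length(k) - 1, c(2, 3, 5))
  Kf <- fft(c(k, numeric(nfft - length(k))))
  conv_K <- function(d)
    Re(fft(fft(c(d, numeric(nfft - n))) * Kf, inverse = TRUE))[seq_len(n)] /
    nfft
  conv_Kt <- function(r)
    Re(fft(fft(c(r, numeric(nfft - n))) * Conj(Kf),
           inverse = TRUE))[seq_len(n)] / nfft
  L <- sum(k)^2
  x <- if (!is.null(init)) pmax(init, 0) else pmax(s, 0) / sum(k)
  y <- x
  tk <- 1
  obj_best <- Inf
  for (it in seq_len(max_iter)) {
    g <- conv_Kt(conv_K(y) - s)
    x_new <- pmax(y - g / L, 0)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y <- x_new + ((tk - 1) / tk_new) * (x_new - x)
    x <- x_new
    tk <- tk_new
    if (it %% 20 == 0) {
      obj <- sum((conv_K(x) - s)^2)
      if (obj <= length(s) * abs_rmse_tol^2) break
      if (obj > obj_best) {        # FISTA ripple: restart the momentum
        y <- x
        tk <- 1
      }
      if (is.finite(obj_best) &&
          obj_best - obj <= rel_tol * max(obj_best, 1e-12)) break
      obj_best <- min(obj_best, obj)
    }
  }
  resid <- conv_K(x) - s
  rmse <- sqrt(mean(resid^2))
  rng <- diff(range(s))
  if (rng > 0 && rmse > 0.25 * rng)
    stop(sprintf("deconvolution failed to converge (residual RMSE %.4g, %.0f%% of signal range)",
                 rmse, 100 * rmse / rng), call. = FALSE)
  list(driver = x, rmse = rmse, reconstruct = conv_K)
}

#' Continuous decomposition analysis of an EDA trace
#'
#' Deconvolves the preprocessed skin conductance signal with a fixed
#' unit-peak Bateman kernel under a nonnegativity constraint, yielding a
#' sudomotor driver. The tonic driver is estimated from the driver's
#' baseline (minima over a coarse grid, interpolated by a smoothing spline);
#' the phasic driver is the remainder, and tonic/phasic conductance
#' components are obtained by reconvolution, so that tonic + phasic
#' reconstructs the signal up to the solver residual.
#'
#' @param channel Preprocessed [signal_channel()] (see [preprocess_eda()]).
#' @param tau1,tau2 Bateman time constants (s); fixed, not optimized per
#'   subject.
#' @param grid_s Spacing (s) of the baseline grid for the tonic estimate.
#' @return An object of class `eda_decomposition`: list with `tonic`,
#'   `phasic` (µS vectors), `driver`, `phasic_driver` (nonnegative), `fs`,
#'   `residual_rmse` and `method = "CDA"`.
#' @export
decompose_cda <- function(channel, tau1 = 0.75, tau2 = 2.0, grid_s = 10) {
  if (channel$units != "uS")
    stop("`channel` must be in microsiemens", call. = FALSE)
  s <- channel$samples
  fs <- channel$fs
  k <- bateman_kernel(fs, tau1, tau2)
  n <- length(s)
  # Steady-state initial condition: the recording starts mid-activity, so
  # the pre-recording driver is modelled as the constant level that sustains
  # s[1]; its decaying contribution is subtracted before deconvolution and
  # added back on reconstruction. A short pad absorbs edge adjustment.
  pad <- length(k)
  s_pad <- c(rep(s[1], pad), s, rep(s[n], pad))
  m <- length(s_pad)
  d_ss <- s[1] / sum(k)
  bg <- numeric(m)
  bg[seq_along(k)] <- d_ss * (sum(k) - cumsum(k))
  s_eff <- s_pad - bg
  # Warm start: the two-pole kernel has an exact 3-tap FIR inverse
  # (1, -(a1 + a2), a1 a2) / (a2 - a1) advanced by one sample; the
  # projected-gradient iterations then only have to enforce nonnegativity.
  a1 <- exp(-1 / (fs * tau1))
  a2 <- exp(-1 / (fs * tau2))
  sp <- c(s_pad, s_pad[m])
  d0 <- (sp[seq_len(m) + 1] - (a1 + a2) * sp[seq_len(m)] +
           a1 * a2 * c(sp[1], sp[seq_len(m - 1)])) / (a2 - a1)
  d0 <- d0 * bateman_peak(tau1, tau2)
  fit <- nnls_deconvolve(s_eff, k, init = d0)
  d_full <- fit$driver
  d <- d_full[pad + seq_len(n)]

  # Tonic driver: baseline knots on a coarse grid through the inter-impulse
  # troughs of the driver, spline-interpolated. Samples that belong to
  # impulse clusters -- or to the clipped-ringing artifacts flanking them --
  # are masked out so they cannot drag the baseline, then each window
  # contributes the median of its remaining quiet samples.
  b0 <- median(d)
  dev <- stats::mad(d)
  quiet <- if (dev > 0) abs(d - b0) <= 3 * dev else rep(TRUE, n)
  dil <- max(1, round(fs))  # dilate the active mask by 1 s on both sides
  act <- as.numeric(stats::filter(as.numeric(!quiet), rep(1, 2 * dil + 1),
                                  sides = 2))
  act[is.na(act)] <- 0
  quiet <- act == 0
  grid_n <- max(1, round(grid_s * fs))
  starts <- seq(1, n, by = grid_n)
  mins <- vapply(starts, function(i0) {
    w <- i0:min(n, i0 + grid_n - 1)
    wq <- w[quiet[w]]
    if (length(wq) >= grid_n / 10) median(d[wq]) else NA_real_
  }, numeric(1))
  centers <- pmin(n, starts + grid_n / 2)
  if (anyNA(mins)) {
    if (all(is.na(mins))) mins <- rep(b0, length(mins))
    else mins <- approx(centers[!is.na(mins)], mins[!is.na(mins)],
                        xout = centers, rule = 2)$y
  }
  td <- if (length(mins) >= 5) {
    sp <- smooth.spline(centers, mins, df = max(3, min(8, length(mins) - 1)))
    predict(sp, seq_len(n))$y
  } else {
    approx(centers, mins, xout = seq_len(n), rule = 2)$y
  }
  td <- pmax(0, td)
  pd <- pmax(d - td, 0)

  # The tonic component is the reconvolved smooth baseline driver (with the
  # same steady-state initial condition); phasic is the complement, so
  # tonic + phasic reproduces the preprocessed signal exactly and clipped
  # solver ringing around impulses cannot leak into either component.
  td_pad <- c(rep(td[1], pad), td, rep(td[length(td)], pad))
  bg_t <- numeric(length(td_pad))
  bg_t[seq_along(k)] <- td[1] * (sum(k) - cumsum(k))
  tonic <- (reconv_causal(td_pad, k, length(td_pad)) +
              bg_t)[pad + seq_len(n)]
  phasic <- s - tonic
  structure(
    list(tonic = tonic, phasic = phasic, driver = d, phasic_driver = pd,
         fs = fs, residual_rmse = fit$rmse, tau1 = tau1, tau2 = tau2,
         method = "CDA"),
    class = "eda_decomposition")
}

# Causal convolution of a driver with kernel k, truncated to n samples.
reconv_causal <- function(v, k, n) {
  convolve(v, rev(k), type = "open")[seq_len(n)]
}

#' @export
print.eda_decomposition <- function(x, ...) {
  cat(sprintf("<eda_decomposition> %s, %d samples @ %g Hz, residual RMSE %.4g uS\n",
              x$method, length(x$tonic), x$fs, x$residual_rmse))
  invisible(x)
}

#' Detect SCRs from a CDA decomposition
#'
#' Segments the phasic driver into impulse clusters and keeps one event per
#' cluster whose reconvolved phasic peak rises at least `amp_threshold`
#' above the phasic level at cluster onset. Onset is the driver rise time;
#' amplitude is the phasic peak above that local baseline.
#'
#' @param decomposition An `eda_decomposition` from [decompose_cda()].
#' @param amp_threshold Minimum SCR amplitude (µS), default 0.05.
#' @param min_gap_s Clusters closer than this (s) are merged.
#' @param edge_guard_s Clusters starting within this many seconds of either
#'   recording edge are discarded (zero-phase filtering and deconvolution
#'   edge transients are not interpretable as responses).
#' @return A data.frame of events: `onset_s`, `peak_s`, `amplitude`,
#'   `method`; zero rows when no SCR qualifies.
#' @export
detect_scr_cda <- function(decomposition, amp_threshold = 0.05,
                           min_gap_s = 1, edge_guard_s = 2) {
  pd <- decomposition$phasic_driver
  phasic <- decomposition$phasic
  fs <- decomposition$fs
  empty <- scr_events(numeric(0), numeric(0), numeric(0), "CDA")
  if (all(pd <= 0)) return(empty)
  eps <- max(0.01 * max(pd), 1e-8)
  act <- pd > eps
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cl <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(cl) == 0) return(empty)
  # merge clusters separated by less than min_gap_s (driver ripple)
  if (nrow(cl) > 1) {
    keep <- logical(nrow(cl))
    keep[1] <- TRUE
    j <- 1
    for (i in 2:nrow(cl)) {
      if ((cl$start[i] - cl$end[j]) / fs < min_gap_s) {
        cl$end[j] <- cl$end[i]
      } else {
        j <- i
        keep[i] <- TRUE
      }
    }
    cl <- cl[keep, , drop = FALSE]
  }
  onset <- peak <- amp <- numeric(0)
  n <- length(phasic)
  guard_lo <- edge_guard_s * fs
  guard_hi <- n - edge_guard_s * fs
  for (i in seq_len(nrow(cl))) {
    i0 <- cl$start[i]
    if (i0 <= guard_lo || i0 >= guard_hi) next
    i1 <- min(n, cl$end[i] + round(2 * fs))  # allow the peak after driver off
    if (i < nrow(cl)) i1 <- min(i1, cl$start[i + 1] - 1)
    seg <- phasic[i0:i1]
    a <- max(seg) - phasic[i0]
    if (a >= amp_threshold) {
      onset <- c(onset, (i0 - 1) / fs)
      peak <- c(peak, (i0 - 1 + which.max(seg) - 1) / fs)
      amp <- c(amp, a)
    }
  }
  scr_events(onset, peak, amp, "CDA")
}

scr_events <- function(onset_s, peak_s, amplitude, method) {
  data.frame(onset_s = onset_s, peak_s = peak_s, amplitude = amplitude,
             method = rep_len(method, length(onset_s)),
             stringsAsFactors = FALSE)
}

#' Trough-to-peak SCR scoring
#'
#' Pairs each local maximum of the preprocessed signal with its preceding
#' local minimum; the SCR amplitude is the peak-minus-trough difference.
#' Events are kept when the amplitude reaches `amp_threshold` and the
#' trough-to-peak rise time falls inside `window`. When consecutive
#' qualifying peaks share a trough, the larger-amplitude response is kept.
#'
#' @param channel Preprocessed [signal_channel()] in microsiemens.
#' @param amp_threshold Minimum amplitude (µS), default 0.05.
#' @param window Rise-time window `c(min_s, max_s)`, default 1–5 s.
#' @return A data.frame of events as in [detect_scr_cda()], `method =
#'   "TTP"`; onsets are the trough times.
#' @export
analyze_ttp <- function(channel, amp_threshold = 0.05, window = c(1, 5)) {
  x <- channel$samples
  fs <- channel$fs
  n <- length(x)
  d <- diff(x)
  sgn <- sign(d)
  # carry forward through plateaus so flat tops still register as extrema
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  turns <- diff(sgn)
  peaks <- which(turns < 0) + 1
  troughs <- which(turns > 0) + 1
  empty <- scr_events(numeric(0), numeric(0), numeric(0), "TTP")
  if (length(peaks) == 0 || length(troughs) == 0) return(empty)
  onset <- peak_t <- amp <- tr_idx <- numeric(0)
  for (p in peaks) {
    prev <- troughs[troughs < p]
    if (length(prev) == 0) next
    tr <- max(prev)
    a <- x[p] - x[tr]
    rise <- (p - tr) / fs
    if (a >= amp_threshold && rise >= window[1] && rise <= window[2]) {
      onset <- c(onset, (tr - 1) / fs)
      peak_t <- c(peak_t, (p - 1) / fs)
      amp <- c(amp, a)
      tr_idx <- c(tr_idx, tr)
    }
  }
  if (length(onset) == 0) return(empty)
  # overlapping responses (shared trough): keep the larger amplitude
  by_tr <- split(seq_along(tr_idx), tr_idx)
  sel <- sort(vapply(by_tr, function(ii) ii[which.max(amp[ii])], numeric(1)))
  scr_events(onset[sel], peak_t[sel], amp[sel], "TTP")
}

#' Assemble the fourteen per-patient EDA features
#'
#' For each detection method (CDA and TTP): the SCR count, the maximum,
#' minimum and mean SCR amplitude (µS), and the maximum, minimum and mean
#' inter-onset interval (s). Amplitude statistics are missing (`NA`) when no
#' SCR was detected; interval statistics require at least two SCRs.
#'
#' @param cda_events,ttp_events Event data.frames from [detect_scr_cda()]
#'   and [analyze_ttp()], sorted by onset.
#' @return A one-row data.frame with columns `nSCR_CDA`, `maxSCR_CDA`,
#'   `minSCR_CDA`, `meanSCR_CDA`, `maxOnsetInt_CDA`, `minOnsetInt_CDA`,
#'   `meanOnsetInt_CDA` and their `_TTP` twins.
#' @export
extract_eda_features <- function(cda_events, ttp_events) {
  one <- function(ev, suffix) {
    n <- nrow(ev)
    amps <- ev$amplitude
    out <- list(nSCR = n,
                maxSCR = if (n >= 1) max(amps) else NA_real_,
                minSCR = if (n >= 1) min(amps) else NA_real_,
                meanSCR = if (n >= 1) mean(amps) else NA_real_)
    ints <- if (n >= 2) diff(ev$onset_s) else numeric(0)
    out$maxOnsetInt <- if (n >= 2) max(ints) else NA_real_
    out$minOnsetInt <- if (n >= 2) min(ints) else NA_real_
    out$meanOnsetInt <- if (n >= 2) mean(ints) else NA_real_
    names(out) <- paste(names(out), suffix, sep = "_")
    out
  }
  as.data.frame(c(one(cda_events, "CDA"), one(ttp_events, "TTP")))
}
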
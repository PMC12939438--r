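#' Bateman skin-conductance impulse response
#'
#' Difference-of-exponentials kernel modelling a single skin conductance
#' response (SCR): a fast rise with time constant `tau1` and a slow decay
#' with `tau2`. The kernel is normalized to unit peak so that an SCR
#' injected with amplitude `a` produces a noise-free peak of exactly `a`
#' microsiemens above baseline.
#'
#' @param fs Sampling rate in Hz.
#' @param tau1,tau2 Rise and decay time constants in seconds; `tau1 < tau2`.
#' @param support_s Kernel support (s); the tail beyond this is truncated
#'   (default 20 s leaves a relative tail below 5e-5 for the default
#'   constants).
#'
#' @return Numeric vector of kernel samples starting at t = 0.
#' @export
bateman_kernel <- function(fs, tau1 = 0.75, tau2 = 2.0, support_s = 20) {
  if (tau1 >= tau2)
    stop("`tau1` must be smaller than `tau2`", call. = FALSE)
  t <- seq(0, support_s, by = 1 / fs)
  k <- exp(-t / tau2) - exp(-t / tau1)
  k / bateman_peak(tau1, tau2)
}

# Analytic peak value of the un-normalized Bateman kernel.
bateman_peak <- function(tau1, tau2) {
  t_peak <- log(tau2 / tau1) * tau1 * tau2 / (tau2 - tau1)
  exp(-t_peak / tau2) - exp(-t_peak / tau1)
}

#' Synthesize an EDA trace from known SCR ground truth
#'
#' Builds `tonic + sum_i amplitude_i * B(t - onset_i) + noise`, where `B` is
#' the unit-peak [bateman_kernel()] evaluated analytically (no truncation),
#' the tonic component is a linear drift plus a very-low-frequency sinusoid,
#' and the noise is white Gaussian.
#'
#' @param onsets SCR onset times in seconds, sorted increasing.
#' @param amplitudes Positive SCR peak amplitudes in microsiemens, one per
#'   onset.
#' @param tonic_params List with elements `level` (µS), `slope` (µS/min),
#'   `vlf_amp` (µS) and `vlf_freq` (Hz).
#' @param noise_sd Gaussian noise standard deviation (µS).
#' @param fs Sampling rate (Hz, >= 4).
#' @param duration_s Trace duration in seconds.
#' @param tau1,tau2 Bateman time constants (s).
#'
#' @return A list with `trace` (µS vector), `tonic` (noise-free tonic
#'   vector) and `fs`.
#' @export
synthesize_eda <- function(onsets, amplitudes,
                           tonic_params = list(level = 2, slope = 0.02,
                                               vlf_amp = 0.1,
                                               vlf_freq = 0.002),
                           noise_sd = 0.01, fs = 100, duration_s = 180,
                           tau1 = 0.75, tau2 = 2.0) {
  if (fs < 4) stop("`fs` must be at least 4 Hz", call. = FALSE)
  if (tau1 >= tau2) stop("`tau1` must be smaller than `tau2`", call. = FALSE)
  if (length(onsets) != length(amplitudes))
    stop("`onsets` and `amplitudes` must have equal length", call. = FALSE)
  if (length(onsets) > 1 && any(diff(onsets) <= 0))
    stop("`onsets` must be strictly increasing", call. = FALSE)
  if (any(amplitudes <= 0))
    stop("`amplitudes` must be positive", call. = FALSE)

  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  tonic <- tonic_params$level + (tonic_params$slope / 60) * t +
    tonic_params$vlf_amp * sin(2 * pi * tonic_params$vlf_freq * t)
  phasic <- numeric(length(t))
  peak <- bateman_peak(tau1, tau2)
  for (i in seq_along(onsets)) {
    idx <- which(t >= onsets[i])
    if (length(idx) == 0) next
    tt <- t[idx] - onsets[i]
    phasic[idx] <- phasic[idx] +
      amplitudes[i] * (exp(-tt / tau2) - exp(-tt / tau1)) / peak
  }
  noise <- if (noise_sd > 0) rnorm(length(t), 0, noise_sd) else 0
  list(trace = tonic + phasic + noise, tonic = tonic, fs = fs)
}

#' Synthesize an RR interval series with band-limited modulation
#'
#' Generates inter-beat intervals `rr_k = mean_rr + lf_amp sin(2 pi lf_freq
#' t_k) + hf_amp sin(2 pi hf_freq t_k) + jitter`, with `t_k` the cumulative
#' beat time, until `duration_s` is covered. Sinusoidal modulation in the LF
#' (around 0.1 Hz) and HF (around 0.25 Hz) bands yields a controllable
#' downstream spectral signature.
#'
#' @param mean_rr Mean RR interval (s), positive.
#' @param lf_amp,hf_amp Modulation amplitudes (s).
#' @param lf_freq,hf_freq Modulation frequencies (Hz).
#' @param jitter_sd White jitter standard deviation (s).
#' @param duration_s Series duration (s).
#' @param seed Optional integer; when supplied the caller's RNG state is
#'   preserved.
#'
#' @return Numeric vector of RR intervals (s) whose cumulative sum does not
#'   exceed `duration_s`.
#' @export
synthesize_rr <- function(mean_rr = 0.85, lf_amp = 0.03, hf_amp = 0.025,
                          lf_freq = 0.1, hf_freq = 0.25, jitter_sd = 0.02,
                          duration_s = 180, seed = NULL) {
  if (mean_rr <= 0) stop("`mean_rr` must be positive", call. = FALSE)
  if (mean_rr - lf_amp - hf_amp <= 0)
    stop("modulation amplitudes produce nonpositive RR intervals",
         call. = FALSE)
  gen <- function() {
    rr <- numeric(0)
    t_k <- 0
    repeat {
      r <- mean_rr + lf_amp * sin(2 * pi * lf_freq * t_k) +
        hf_amp * sin(2 * pi * hf_freq * t_k) +
        (if (jitter_sd > 0) rnorm(1, 0, jitter_sd) else 0)
      if (r <= 0)
        stop("parameters produced a nonpositive RR interval", call. = FALSE)
      if (t_k + r > duration_s) break
      rr <- c(rr, r)
      t_k <- t_k + r
    }
    rr
  }
  if (is.null(seed)) gen() else with_preserved_rng(seed, gen())
}

#' Render a synthetic single-lead ECG from an RR series
#'
#' Places a fixed PQRST template (Gaussian bumps; R peak 1 mV, centred
#' exactly at each beat time) at the cumulative beat times of `rr`. Intended
#' for end-to-end QRS-detector tests: the true R-peak times are the beat
#' times.
#'
#' @param rr RR interval series (s).
#' @param fs Sampling rate (Hz).
#' @param duration_s Trace duration (s).
#' @param first_beat_s Time of the first beat (s).
#' @param noise_sd Additive white noise sd (mV).
#' @param amplitude R-wave amplitude (mV); may be a vector of per-beat
#'   amplitudes (recycled).
#'
#' @return List with `trace` (mV), `fs`, and `beat_times_s` (true R peaks).
#' @export
synthesize_ecg <- function(rr, fs = 1000, duration_s = NULL,
                           first_beat_s = 0.5, noise_sd = 0.005,
                           amplitude = 1.0) {
  beats <- first_beat_s + c(0, cumsum(rr))
  if (is.null(duration_s)) duration_s <- max(beats) + 1
  beats <- beats[beats < duration_s - 0.5]
  amplitude <- rep_len(amplitude, length(beats))
  n <- round(duration_s * fs)
  trace <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  # PQRST template sampled on [-0.3, 0.45] s around the R peak
  tt <- seq(-0.3, 0.45, by = 1 / fs)
  template <- 0.15 * exp(-(tt + 0.2)^2 / (2 * 0.025^2)) -  # P
    0.10 * exp(-(tt + 0.040)^2 / (2 * 0.008^2)) +          # Q
    1.00 * exp(-tt^2 / (2 * 0.009^2)) -                    # R
    0.15 * exp(-(tt - 0.040)^2 / (2 * 0.008^2)) +          # S
    0.30 * exp(-(tt - 0.25)^2 / (2 * 0.040^2))             # T
  off <- round(-0.3 * fs)
  for (b in seq_along(beats)) {
    i0 <- round(beats[b] * fs) + 1 + off
    idx <- seq(i0, i0 + length(tt) - 1)
    keep <- idx >= 1 & idx <= n
    trace[idx[keep]] <- trace[idx[keep]] + amplitude[b] * template[keep]
  }
  list(trace = trace, fs = fs, beat_times_s = beats)
}

#' Default per-group effect configuration for the synthetic cohort
#'
#' SCR rates per pain type are calibrated so that 3-minute recordings yield
#' median SCR counts in the direction and magnitude of the reported group
#' medians (about 35, 39.5 and 5 responses for nociceptive, neuropathic and
#' mixed pain); mixed-pain patients also draw smaller SCR amplitudes, and
#' mild-intensity patients draw larger ones than moderate/severe. RR
#' parameters place LF and HF modulation inside the conventional bands.
#'
#' @return Named list of effect parameters; see [cohort_spec()].
#' @export
default_effect_config <- function() {
  list(
    scr_rate = c(nociceptive = 11.7, neuropathic = 13.2, mixed = 1.7),  # /min
    scr_amp_meanlog = c(nociceptive = -1.6, neuropathic = -1.7,
                        mixed = -2.3),                                  # log uS
    scr_amp_sdlog = 0.8,
    amp_shift_intensity = c(mild = 1.0, moderate = -0.3, severe = -0.6),
    tonic_level_mean = 2.0, tonic_level_sd = 0.5,                       # uS
    eda_noise_sd = 0.01,                                                # uS
    rr_mean = 0.85, rr_mean_sd = 0.08,                                  # s
    rr_lf_amp = 0.03, rr_hf_amp = 0.025, rr_jitter_sd = 0.02,           # s
    lf_freq = 0.1, hf_freq = 0.25                                       # Hz
  )
}

#' Specify a synthetic cohort
#'
#' Collects cohort size, recording parameters, covariate distributions and
#' per-group autonomic effect parameters into a validated specification for
#' [generate_cohort()]. Default categorical probabilities follow the
#' marginal distribution of a 64-patient cancer-pain cohort (pain intensity
#' 30.2/25.4/44.4% mild/moderate/severe; pain type 64.1/21.9/14.1%
#' nociceptive/neuropathic/mixed).
#'
#' @param n_patients Positive integer cohort size.
#' @param duration_s Recording duration (s), default 180.
#' @param fs_ecg,fs_eda Channel sampling rates (Hz).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the spec (identical spec + seed gives bit-identical output).
#' @param group_probabilities List with `pain_intensity` (named over mild,
#'   moderate, severe) and `pain_type` (named over nociceptive, neuropathic,
#'   mixed); each must sum to 1 within 1e-9.
#' @param covariate_probabilities Named Bernoulli rates for `btcp`,
#'   `bone_metastases` and `med_over_60`.
#' @param effect_config See [default_effect_config()].
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, duration_s = 180, fs_ecg = 1000,
                        fs_eda = 100, seed = 1,
                        group_probabilities = list(
                          pain_intensity = c(mild = 0.302, moderate = 0.254,
                                             severe = 0.444),
                          pain_type = c(nociceptive = 41, neuropathic = 14,
                                        mixed = 9) / 64),
                        covariate_probabilities = c(btcp = 0.438,
                                                    bone_metastases = 0.359,
                                                    med_over_60 = 0.531),
                        effect_config = default_effect_config()) {
  spec <- structure(
    list(n_patients = n_patients, duration_s = duration_s, fs_ecg = fs_ecg,
         fs_eda = fs_eda, seed = seed,
         group_probabilities = lapply(group_probabilities,
                                      function(p) p / sum(p)),
         covariate_probabilities = covariate_probabilities,
         effect_config = effect_config),
    class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  fail <- function(field, msg)
    stop(sprintf("invalid cohort_spec field `%s`: %s", field, msg),
         call. = FALSE)
  if (!is.numeric(spec$n_patients) || spec$n_patients < 1 ||
      spec$n_patients != round(spec$n_patients))
    fail("n_patients", "must be a positive integer")
  if (!is.numeric(spec$duration_s) || spec$duration_s <= 0)
    fail("duration_s", "must be positive")
  if (spec$fs_ecg <= 0) fail("fs_ecg", "must be positive")
  if (spec$fs_eda <= 0) fail("fs_eda", "must be positive")
  if (is.null(spec$seed) || !is.numeric(spec$seed))
    fail("seed", "an integer seed is required")
  gp <- spec$group_probabilities
  for (nm in c("pain_intensity", "pain_type")) {
    p <- gp[[nm]]
    if (is.null(p)) fail("group_probabilities", paste0("missing ", nm))
    if (any(p < 0) || any(p > 1))
      fail("group_probabilities", paste0(nm, " outside [0, 1]"))
    if (abs(sum(p) - 1) > 1e-9)
      fail("group_probabilities", paste0(nm, " does not sum to 1"))
  }
  need <- setdiff(names(gp$pain_intensity), c("mild", "moderate", "severe"))
  if (length(need) || length(gp$pain_intensity) != 3)
    fail("group_probabilities", "pain_intensity must be named mild/moderate/severe")
  need <- setdiff(names(gp$pain_type),
                  c("nociceptive", "neuropathic", "mixed"))
  if (length(need) || length(gp$pain_type) != 3)
    fail("group_probabilities",
         "pain_type must be named nociceptive/neuropathic/mixed")
  cp <- spec$covariate_probabilities
  for (nm in c("btcp", "bone_metastases", "med_over_60")) {
    if (is.na(cp[nm])) fail("covariate_probabilities", paste0("missing ", nm))
    if (cp[nm] < 0 || cp[nm] > 1)
      fail("covariate_probabilities", paste0(nm, " outside [0, 1]"))
  }
  ec <- spec$effect_config
  if (any(ec$scr_rate < 0)) fail("effect_config", "scr_rate must be >= 0")
  if (ec$scr_amp_sdlog <= 0)
    fail("effect_config", "scr_amp_sdlog must be > 0")
  if (ec$rr_mean <= 0.3 || ec$rr_mean >= 2.0)
    fail("effect_config", "rr_mean must lie in (0.3, 2.0) s")
  invisible(spec)
}

# Draw the covariate block of a cohort from the spec's marginals, using the
# current RNG stream.
sample_covariates <- function(spec) {
  n <- spec$n_patients
  gi <- spec$group_probabilities$pain_intensity
  gt <- spec$group_probabilities$pain_type
  cp <- spec$covariate_probabilities
  intensity <- sample(names(gi), n, replace = TRUE, prob = gi)
  nrs_range <- list(mild = 1:3, moderate = 4:6, severe = 7:10)
  cohort <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    age = pmin(95, pmax(18, round(rnorm(n, 61, 13.3)))),
    sex = sample(c("male", "female"), n, TRUE, prob = c(0.64, 0.36)),
    cancer_type = sample(c("breast", "gastrointestinal", "lung",
                           "bone_soft_tissue", "other"), n, TRUE,
                         prob = c(6, 11, 10, 11, 26) / 64),
    nrs = vapply(intensity, function(cl) sample(nrs_range[[cl]], 1),
                 integer(1)),
    pain_intensity_class = intensity,
    pain_type = sample(names(gt), n, replace = TRUE, prob = gt),
    btcp = runif(n) < cp["btcp"],
    bone_metastases = runif(n) < cp["bone_metastases"],
    med_over_60 = runif(n) < cp["med_over_60"],
    ecog = sample(1:4, n, TRUE, prob = c(33, 11, 7, 13) / 64),
    stringsAsFactors = FALSE)
  rownames(cohort) <- NULL
  cohort
}

#' Draw only the covariate table of a synthetic cohort
#'
#' Samples the per-patient clinical covariates from the spec's marginal
#' distributions without synthesizing any signals. Useful for statistical
#' calibration studies where feature values are supplied separately.
#'
#' @param spec A [cohort_spec()]; only the cohort-level fields are used.
#' @return A covariate data.frame as in [generate_cohort()].
#' @export
draw_cohort_table <- function(spec) {
  validate_cohort_spec(spec)
  with_preserved_rng(spec$seed, sample_covariates(spec))
}

# SCR onset times: homogeneous Poisson process at `rate` events/min on
# [5, duration - 8] s, thinned to enforce a 1 s minimum gap.
draw_scr_onsets <- function(rate_per_min, duration_s, min_gap = 1) {
  lo <- 5
  hi <- duration_s - 8
  if (hi <= lo || rate_per_min <= 0) return(numeric(0))
  n <- rpois(1, rate_per_min * (hi - lo) / 60)
  if (n == 0) return(numeric(0))
  on <- sort(runif(n, lo, hi))
  keep <- rep(TRUE, n)
  last <- on[1]
  for (i in seq_len(n)[-1]) {
    if (on[i] - last < min_gap) keep[i] <- FALSE else last <- on[i]
  }
  on[keep]
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-patient covariates from the spec's categorical and Bernoulli
#' distributions, then synthesizes each patient's EDA trace (tonic drift +
#' Bateman SCR train + noise) and RR series (sinusoidally modulated), with
#' SCR rate and amplitude controlled by the patient's pain type and
#' intensity class. Optionally renders an ECG channel from the RR series.
#'
#' @param spec A [cohort_spec()].
#' @param channels Which signal channels to synthesize; rendering ECG is the
#'   slow part and can be skipped when only EDA features are needed.
#'
#' @return List with `cohort` (covariate data.frame with columns patient_id,
#'   age, sex, cancer_type, nrs, pain_intensity_class, pain_type, btcp,
#'   bone_metastases, med_over_60, ecog), `recordings` (list of
#'   [recording()]), and `ground_truth` (per patient: `scr_onsets`,
#'   `scr_amplitudes`, `tonic`, `rr`, `beat_times_s`).
#' @export
generate_cohort <- function(spec, channels = c("eda", "ecg")) {
  validate_cohort_spec(spec)
  if (length(channels) == 0 || length(setdiff(channels, c("eda", "ecg"))))
    stop("`channels` must be a non-empty subset of {eda, ecg}", call. = FALSE)
  ec <- spec$effect_config
  with_preserved_rng(spec$seed, {
    n <- spec$n_patients
    cohort <- sample_covariates(spec)
    intensity <- cohort$pain_intensity_class
    ptype <- cohort$pain_type

    recordings <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      onsets <- draw_scr_onsets(ec$scr_rate[[ptype[i]]], spec$duration_s)
      meanlog <- ec$scr_amp_meanlog[[ptype[i]]] +
        ec$amp_shift_intensity[[intensity[i]]]
      amps <- if (length(onsets)) rlnorm(length(onsets), meanlog,
                                         ec$scr_amp_sdlog) else numeric(0)
      tonic_params <- list(
        level = max(0.5, rnorm(1, ec$tonic_level_mean, ec$tonic_level_sd)),
        slope = rnorm(1, 0, 0.03), vlf_amp = runif(1, 0.02, 0.15),
        vlf_freq = runif(1, 0.001, 0.004))
      eda <- synthesize_eda(onsets, amps, tonic_params,
                            noise_sd = ec$eda_noise_sd, fs = spec$fs_eda,
                            duration_s = spec$duration_s)
      mean_rr_i <- min(1.4, max(0.5, rnorm(1, ec$rr_mean, ec$rr_mean_sd)))
      rr <- synthesize_rr(mean_rr_i, ec$rr_lf_amp, ec$rr_hf_amp,
                          ec$lf_freq, ec$hf_freq, ec$rr_jitter_sd,
                          spec$duration_s)
      chans <- list()
      beat_times <- NULL
      if ("eda" %in% channels)
        chans$eda <- signal_channel(eda$trace, spec$fs_eda, "uS")
      if ("ecg" %in% channels) {
        ecg <- synthesize_ecg(rr, fs = spec$fs_ecg,
                              duration_s = spec$duration_s)
        chans$ecg <- signal_channel(ecg$trace, spec$fs_ecg, "mV")
        beat_times <- ecg$beat_times_s
      }
      recordings[[i]] <- recording(cohort$patient_id[i], chans)
      truth[[i]] <- list(scr_onsets = onsets, scr_amplitudes = amps,
                         tonic = eda$tonic, rr = rr,
                         beat_times_s = beat_times)
    }
    list(cohort = cohort, recordings = recordings, ground_truth = truth)
  })
}
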
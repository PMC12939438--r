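test_that("preprocessing is DC-invariant and resamples to 10 Hz", {
  ch <- signal_channel(rep(2, 6000), 100, "uS")
  out <- preprocess_eda(ch)
  expect_equal(out$fs, 10)
  expect_true(all(abs(out$samples - 2) < 1e-9))
  # duration preserved within one output sample
  expect_lt(abs(length(out$samples) / 10 - 60), 1 / 10 + 1e-9)
})

test_that("the low-pass stage attenuates a 50 Hz tone by at least 40 dB", {
  t <- (0:11999) / 200
  ch <- signal_channel(2 + 0.5 * sin(2 * pi * 50 * t), 200, "uS")
  out <- preprocess_eda(ch, fs_out = 200)  # keep rate: isolate the filter
  interior <- out$samples[1001:11000]      # steady state, no edge transient
  resid_amp <- sqrt(2) * sd(interior - mean(interior))
  expect_lt(resid_amp / 0.5, 10^(-40 / 20))
})

test_that("CDA separates a single SCR from a flat tonic level", {
  ch <- make_eda_channel(60, 1)
  pre <- preprocess_eda(ch)
  dec <- decompose_cda(pre)
  expect_lte(max(abs(dec$tonic - 2)), 0.1)
  expect_equal(max(dec$phasic), 1, tolerance = 0.1)
  # nonnegative driver and faithful reconstruction
  expect_true(all(dec$phasic_driver >= -1e-8))
  resid <- pre$samples - (dec$tonic + dec$phasic)
  expect_lte(sqrt(mean(resid^2)), 0.05 * diff(range(pre$samples)))
})

test_that("a pure tonic drift yields a null phasic driver and no SCRs", {
  s <- synthesize_eda(numeric(0), numeric(0),
                      list(level = 2, slope = 0.2, vlf_amp = 0.2,
                           vlf_freq = 0.003),
                      noise_sd = 0, fs = 100, duration_s = 180)
  dec <- decompose_cda(preprocess_eda(signal_channel(s$trace, 100, "uS")))
  expect_lte(max(dec$phasic_driver), 0.05)
  expect_equal(nrow(detect_scr_cda(dec)), 0)
  # the tonic estimate varies no faster than a realistic (noisy) raw trace
  sn <- synthesize_eda(c(40, 100, 150), c(0.3, 0.6, 0.4),
                       noise_sd = 0.01, fs = 100, duration_s = 180)
  decn <- decompose_cda(preprocess_eda(signal_channel(sn$trace, 100, "uS")))
  tv <- function(x) sum(abs(diff(x)))
  expect_lte(tv(decn$tonic), tv(sn$trace))
})

test_that("CDA recovers the count of well-separated SCRs", {
  ons <- c(20, 35, 60, 90, 130)
  ch <- make_eda_channel(ons, rep(0.4, 5))
  dec <- decompose_cda(preprocess_eda(ch))
  ev <- detect_scr_cda(dec)
  expect_equal(nrow(ev), 5)
  expect_true(all(diff(ev$onset_s) > 0))
  expect_equal(ev$onset_s, ons, tolerance = 2.5)
})

test_that("SCR detection respects the amplitude threshold", {
  ch_small <- make_eda_channel(60, 0.04)
  ev <- detect_scr_cda(decompose_cda(preprocess_eda(ch_small)),
                       amp_threshold = 0.05)
  expect_equal(nrow(ev), 0)
  # raising the threshold never increases the count
  ch <- make_eda_channel(c(30, 70, 110, 150), c(0.08, 0.2, 0.5, 1.0),
                         noise_sd = 0.01)
  dec <- decompose_cda(preprocess_eda(ch))
  counts <- vapply(c(0.02, 0.05, 0.1, 0.3, 0.7, 1.5),
                   function(th) nrow(detect_scr_cda(dec, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("trough-to-peak scoring recovers isolated SCR amplitudes", {
  ch <- make_eda_channel(c(30, 70), c(0.5, 0.8))
  ev <- analyze_ttp(preprocess_eda(ch))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$amplitude, c(0.5, 0.8), tolerance = 0.1 * 0.8)
  expect_true(all(ev$peak_s > ev$onset_s))
})

test_that("trough-to-peak scoring ignores ramps and sub-threshold noise", {
  ramp <- signal_channel(seq(1, 3, length.out = 1200), 10, "uS")
  expect_equal(nrow(analyze_ttp(ramp)), 0)
  set.seed(4)
  noise <- signal_channel(2 + rnorm(1800, 0, 0.005), 10, "uS")
  expect_equal(nrow(analyze_ttp(noise)), 0)
  # threshold monotonicity holds for TTP as well
  ch <- preprocess_eda(make_eda_channel(c(30, 70, 110), c(0.1, 0.4, 0.9),
                                        noise_sd = 0.01))
  counts <- vapply(c(0.02, 0.08, 0.3, 1), function(th)
    nrow(analyze_ttp(ch, th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the fourteen EDA features follow their definitions", {
  ttp <- data.frame(onset_s = c(10, 30, 60), peak_s = c(12, 32, 62),
                    amplitude = c(0.2, 0.4, 0.6), method = "TTP")
  none <- ttp[0, ]
  f <- extract_eda_features(none, ttp)
  expect_equal(f$nSCR_TTP, 3)
  expect_equal(f$maxSCR_TTP, 0.6)
  expect_equal(f$minSCR_TTP, 0.2)
  expect_equal(f$meanSCR_TTP, 0.4)
  expect_equal(f$maxOnsetInt_TTP, 30)
  expect_equal(f$minOnsetInt_TTP, 20)
  expect_equal(f$meanOnsetInt_TTP, 25)
  expect_equal(f$nSCR_CDA, 0)
  expect_true(all(is.na(f[paste0(c("maxSCR", "minSCR", "meanSCR",
                                   "maxOnsetInt", "minOnsetInt",
                                   "meanOnsetInt"), "_CDA")])))
  # single event: amplitude stats collapse, interval stats missing
  one <- ttp[1, ]
  f1 <- extract_eda_features(one, one)
  expect_equal(f1$maxSCR_CDA, f1$minSCR_CDA)
  expect_equal(f1$meanSCR_TTP, 0.2)
  expect_true(is.na(f1$meanOnsetInt_TTP))
  # ordering invariant whenever events exist
  f2 <- extract_eda_features(ttp, ttp)
  expect_true(f2$minSCR_CDA <= f2$meanSCR_CDA &&
                f2$meanSCR_CDA <= f2$maxSCR_CDA)
})
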
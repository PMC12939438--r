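test_that("Bateman synthesis is unit-peak normalized", {
  s <- synthesize_eda(onsets = 10, amplitudes = 1, flat_tonic(2),
                      noise_sd = 0, fs = 1000, duration_s = 30)
  expect_equal(max(s$trace) - 2, 1, tolerance = 1e-6)
})

test_that("well-separated SCRs reproduce their injected peak heights", {
  s <- synthesize_eda(onsets = c(10, 40), amplitudes = c(0.5, 0.8),
                      flat_tonic(2), noise_sd = 0, fs = 100,
                      duration_s = 70)
  t <- seq(0, 70 - 0.01, by = 0.01)
  expect_equal(max(s$trace[t >= 10 & t < 35]) - 2, 0.5, tolerance = 1e-3)
  expect_equal(max(s$trace[t >= 40]) - 2, 0.8, tolerance = 1e-3)
})

test_that("an empty SCR train leaves only the tonic component", {
  s <- synthesize_eda(numeric(0), numeric(0), flat_tonic(1.5),
                      noise_sd = 0, fs = 50, duration_s = 60)
  expect_identical(s$trace, s$tonic)
  expect_true(all(s$trace == 1.5))
})

test_that("EDA synthesis rejects malformed SCR trains", {
  expect_error(synthesize_eda(c(10, 5), c(1, 1)), "increasing")
  expect_error(synthesize_eda(10, -1), "positive")
  expect_error(synthesize_eda(10, 1, tau1 = 3, tau2 = 2), "tau1")
  expect_error(synthesize_eda(10, 1, fs = 2), "fs")
})

test_that("unmodulated RR synthesis is a constant series", {
  rr <- synthesize_rr(mean_rr = 1, lf_amp = 0, hf_amp = 0, jitter_sd = 0,
                      duration_s = 60)
  expect_true(all(rr == 1))
  expect_lte(sum(rr), 60)
  td <- time_domain_features(make_rr_series(rr))
  expect_equal(td$mean_hr, 60)
  expect_equal(td$sdnn, 0)
  expect_equal(td$rmssd, 0)
})

test_that("RR synthesis rejects parameters implying nonpositive intervals", {
  expect_error(synthesize_rr(mean_rr = 0.1, lf_amp = 0.08, hf_amp = 0.05),
               "nonpositive")
  expect_error(synthesize_rr(mean_rr = -1), "positive")
})

test_that("the ECG renderer places R peaks exactly at beat times", {
  e <- synthesize_ecg(rep(0.8, 20), fs = 500, noise_sd = 0)
  idx <- round(e$beat_times_s * 500) + 1
  expect_true(all(e$trace[idx] >= 0.99))
})

test_that("cohort generation is deterministic and spec-sized", {
  spec <- cohort_spec(6, duration_s = 30, seed = 42)
  a <- generate_cohort(spec, channels = "eda")
  b <- generate_cohort(spec, channels = "eda")
  expect_identical(a, b)
  expect_equal(nrow(a$cohort), 6)
  expect_length(a$recordings, 6)
  expect_length(a$ground_truth, 6)
  expect_named(a$cohort,
               c("patient_id", "age", "sex", "cancer_type", "nrs",
                 "pain_intensity_class", "pain_type", "btcp",
                 "bone_metastases", "med_over_60", "ecog"))
  # ground-truth invariants
  for (gt in a$ground_truth) {
    expect_true(all(diff(gt$scr_onsets) > 0) || length(gt$scr_onsets) < 2)
    expect_true(all(gt$scr_amplitudes > 0))
    expect_true(all(gt$scr_onsets >= 0 & gt$scr_onsets <= 30))
  }
})

test_that("covariate frequencies converge to the spec probabilities", {
  spec <- cohort_spec(3000, seed = 9)
  tab <- draw_cohort_table(spec)
  freq <- table(tab$pain_type)[c("nociceptive", "neuropathic", "mixed")] /
    3000
  target <- spec$group_probabilities$pain_type
  expect_true(all(abs(freq - target) < 0.03))
  # at the study size the expected pain-type split is about 41/14/9
  expect_equal(unname(64 * target), c(41, 14, 9), tolerance = 0.01)
  expect_true(all(tab$nrs >= 1 & tab$nrs <= 10))
  cls <- cut(tab$nrs, c(0, 3, 6, 10),
             labels = c("mild", "moderate", "severe"))
  expect_identical(as.character(cls), tab$pain_intensity_class)
})

test_that("a zero SCR rate yields empty ground truth and pure tonic EDA", {
  ec <- default_effect_config()
  ec$scr_rate[] <- 0
  ec$eda_noise_sd <- 0
  spec <- cohort_spec(4, duration_s = 60, seed = 5, effect_config = ec)
  sim <- generate_cohort(spec, channels = "eda")
  for (i in 1:4) {
    expect_length(sim$ground_truth[[i]]$scr_onsets, 0)
    expect_equal(sim$recordings[[i]]$channels$eda$samples,
                 sim$ground_truth[[i]]$tonic)
  }
})

test_that("invalid cohort specs name the offending field", {
  expect_error(cohort_spec(0, seed = 1), "n_patients")
  expect_error(cohort_spec(4, seed = 1,
                           covariate_probabilities = c(btcp = 1.4,
                                                       bone_metastases = 0.3,
                                                       med_over_60 = 0.5)),
               "covariate_probabilities")
  bad_gp <- list(pain_intensity = c(mild = 0.5, moderate = 0.4,
                                    severe = 0.2),
                 pain_type = c(nociceptive = 0.6, neuropathic = 0.3,
                               mixed = 0.1))
  spec <- cohort_spec(4, seed = 1)
  spec$group_probabilities <- bad_gp
  expect_error(validate_cohort_spec(spec), "sum to 1")
  ec <- default_effect_config()
  ec$rr_mean <- 2.5
  expect_error(cohort_spec(4, seed = 1, effect_config = ec), "rr_mean")
})
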
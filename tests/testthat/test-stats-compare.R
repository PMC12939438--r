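test_that("Kruskal-Wallis matches independent oracles on small instances", {
  # no ties: direct rank-formula oracle, exact
  set.seed(1)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    g <- sample(rep(c("a", "b", "c"), length.out = n))
    if (length(unique(g)) < 2) next
    v <- sample(seq_len(n))  # distinct values: no ties
    kw <- kruskal_wallis(v, g)
    expect_equal(kw$H, kw_oracle_no_ties(v, g), tolerance = 1e-12)
  }
  # with ties: base R implementation as independent cross-check
  for (i in 1:50) {
    v <- sample(1:5, 18, replace = TRUE)
    g <- rep(c("a", "b", "c"), each = 6)
    if (length(unique(v)) == 1) next
    kw <- kruskal_wallis(v, g)
    ref <- kruskal.test(v, factor(g))
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(kw$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(kw$df, unname(ref$parameter))
  }
})

test_that("Kruskal-Wallis handles symmetric and degenerate input", {
  kw <- kruskal_wallis(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(kw$H, 0)
  expect_equal(kw$p_value, 1)
  expect_error(kruskal_wallis(rep(2, 9), rep(c("a", "b", "c"), each = 3)),
               "identical")
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("Dunn z statistics square to H for two groups without ties", {
  set.seed(2)
  for (i in 1:30) {
    v <- sample(seq_len(16))
    g <- rep(c("a", "b"), each = 8)
    z <- dunn_posthoc(v, g)$z
    expect_equal(z^2, kruskal_wallis(v, g)$H, tolerance = 1e-9)
  }
})

test_that("Dunn post hoc separates what differs and only that", {
  v <- c(1:10, 101:110)
  g <- rep(c("lo", "hi"), each = 10)
  d <- dunn_posthoc(v, g)
  expect_gt(abs(d$z), 3)
  expect_lt(d$p_raw, 0.001)
  # identical multisets: z = 0, p = 1
  d0 <- dunn_posthoc(c(1:5, 1:5), rep(c("a", "b"), each = 5))
  expect_equal(d0$z, 0)
  expect_equal(d0$p_raw, 1)
  # only one deviant group: that pair's p is smallest, BH keeps the order
  set.seed(3)
  v3 <- c(rnorm(12), rnorm(12), rnorm(12, 5))
  g3 <- rep(c("a", "b", "c"), each = 12)
  d3 <- dunn_posthoc(v3, g3)
  ab <- which(d3$group1 == "a" & d3$group2 == "b")
  expect_equal(which.max(d3$p_raw), ab)
  # BH preserves the significance ordering (up to ties it introduces)
  expect_true(all(diff(d3$p_adjusted[order(d3$p_raw)]) >= -1e-12))
  expect_true(all(d3$p_adjusted >= d3$p_raw))
})

test_that("Benjamini-Hochberg adjustment is a step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(2:12, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    # monotone nondecreasing in sorted order
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    # invariant to input permutation
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm], tolerance = 1e-12)
  }
})

test_that("the normality screen flags heavy tails and spares tiny groups", {
  set.seed(5)
  heavy <- rt(300, df = 1)
  g <- rep(c("a", "b", "c"), each = 100)
  sc <- shapiro_screen(heavy, g)
  expect_true(sc$non_normal_flag)
  # group below n = 3 yields a missing p, flag decided from the rest
  sc2 <- shapiro_screen(c(rnorm(40), 1, 2), c(rep("a", 40), "b", "b"))
  expect_true(is.na(sc2$p_by_group["b"]))
  expect_false(is.na(sc2$p_by_group["a"]))
  # the screen's per-group type-I rate stays near its nominal level
  hits <- 0
  runs <- 400
  for (i in seq_len(runs)) {
    p <- shapiro_screen(rnorm(50), rep("a", 50))$p_by_group
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits / runs, 0.02)
  expect_lt(hits / runs, 0.09)
})

test_that("comparisons run per feature, grouping and stratum", {
  set.seed(6)
  n <- 60
  cohort <- data.frame(
    patient_id = sprintf("P%03d", 1:n),
    pain_intensity_class = sample(c("mild", "moderate", "severe"), n, TRUE),
    pain_type = sample(c("nociceptive", "neuropathic", "mixed"), n, TRUE,
                       prob = c(0.5, 0.3, 0.2)),
    bone_metastases = rep(c(TRUE, FALSE), each = n / 2),
    btcp = rep(c(TRUE, FALSE), n / 2),
    med_over_60 = sample(c(TRUE, FALSE), n, TRUE))
  features <- data.frame(
    patient_id = cohort$patient_id,
    nSCR_CDA = rpois(n, 10) + 20 * (cohort$pain_type != "mixed"),
    maxSCR_CDA = rlnorm(n, -1, 0.5))
  rep <- run_comparisons(features, cohort)
  # every computable test carries the chi-square mapping and all pairs
  comp <- rep$tests[rep$tests$computable, ]
  expect_true(all(abs(comp$p_value -
                        kw_pvalue(comp$H, comp$df)) < 1e-12))
  expect_equal(nrow(rep$pairwise),
               sum(choose(comp$df + 1, 2)))
  # the injected pain-type effect dominates: mixed pairs are the smallest
  pw <- rep$pairwise
  pw <- pw[pw$feature == "nSCR_CDA" & pw$grouping == "pain_type" &
             pw$stratum == "none", ]
  mixed_pair <- pw$group1 == "mixed" | pw$group2 == "mixed"
  expect_true(all(sort(pw$p_adjusted[mixed_pair]) <=
                    sort(pw$p_adjusted[!mixed_pair])[1]))
  kw_row <- rep$tests[rep$tests$feature == "nSCR_CDA" &
                        rep$tests$grouping == "pain_type" &
                        rep$tests$stratum == "none", ]
  expect_lt(kw_row$p_value, 0.05)
  # group summaries report median and Q3 - Q1
  gr <- rep$groups[rep$groups$feature == "nSCR_CDA" &
                     rep$groups$grouping == "pain_type" &
                     rep$groups$stratum == "none", ]
  v_mixed <- features$nSCR_CDA[cohort$pain_type == "mixed"]
  expect_equal(gr$median[gr$group == "mixed"], median(v_mixed))
  expect_equal(gr$iqr[gr$group == "mixed"],
               unname(diff(quantile(v_mixed, c(0.25, 0.75)))))
})

test_that("a stratum that empties a group is reported as not computable", {
  n <- 30
  cohort <- data.frame(
    patient_id = sprintf("P%03d", 1:n),
    pain_intensity_class = rep(c("mild", "moderate", "severe"), 10),
    pain_type = c(rep("nociceptive", 15), rep(c("neuropathic", "mixed"),
                                              length.out = 15)),
    bone_metastases = c(rep(TRUE, 15), rep(FALSE, 15)),
    btcp = FALSE, med_over_60 = FALSE)
  set.seed(7)
  features <- data.frame(patient_id = cohort$patient_id,
                         nSCR_CDA = rpois(n, 10))
  rep <- run_comparisons(features, cohort, strata = "bone_metastases")
  bad <- rep$tests[rep$tests$stratum == "bone_metastases" &
                     rep$tests$stratum_level == "TRUE" &
                     rep$tests$grouping == "pain_type", ]
  expect_false(bad$computable)
  expect_match(bad$note, "empty group")
  # orphan patients are rejected up front
  features$patient_id[1] <- "ghost"
  expect_error(run_comparisons(features, cohort), "ghost")
})
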
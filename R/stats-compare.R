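#' Upper-tail chi-square p-value for a Kruskal-Wallis statistic
#'
#' @param H Kruskal-Wallis statistic.
#' @param df Degrees of freedom (number of groups minus one).
#' @return `P(chi^2_df >= H)`.
#' @export
kw_pvalue <- function(H, df) pchisq(H, df, lower.tail = FALSE)

# Pooled midranks and the tie bookkeeping shared by the Kruskal-Wallis and
# Dunn statistics.
rank_pool <- function(values) {
  r <- rank(values)
  tie_tab <- table(values)
  list(ranks = r, n = length(values),
       tie_cubes = sum(tie_tab^3 - tie_tab))
}

#' Kruskal-Wallis rank test
#'
#' H is computed on pooled midranks with the standard tie-correction
#' divisor `1 - sum(t^3 - t) / (N^3 - N)`; the p-value is the upper tail of
#' the chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param values Numeric vector of observations.
#' @param group Grouping vector (coerced to factor) of the same length.
#' @return List with `H`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(values, group) {
  group <- droplevels(as.factor(group))
  stopifnot(length(values) == length(group))
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]
  group <- droplevels(group[ok])
  k <- nlevels(group)
  n <- length(values)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (n < k + 1) stop("too few observations", call. = FALSE)
  if (length(unique(values)) == 1)
    stop("all values identical; statistic undefined under tie correction",
         call. = FALSE)
  rp <- rank_pool(values)
  rbar <- tapply(rp$ranks, group, mean)
  ni <- tabulate(group)
  H <- (12 / (n * (n + 1))) * sum(ni * (rbar - (n + 1) / 2)^2)
  H <- H / (1 - rp$tie_cubes / (n^3 - n))
  list(H = unname(H), df = k - 1, p_value = kw_pvalue(H, k - 1), n = n)
}

#' Dunn's post hoc pairwise comparisons
#'
#' For each pair of groups, `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) *
#' (1/n_i + 1/n_j))` with midranks pooled over all groups and tie term
#' `T = sum(t^3 - t) / (12 (N - 1))`. Two-sided p-values from the normal
#' tail; `p_adjusted` applies Benjamini-Hochberg within this family of
#' pairs.
#'
#' @inheritParams kruskal_wallis
#' @return data.frame with `group1`, `group2`, `z`, `p_raw`, `p_adjusted`.
#' @export
dunn_posthoc <- function(values, group) {
  group <- droplevels(as.factor(group))
  stopifnot(length(values) == length(group))
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]
  group <- droplevels(group[ok])
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(unique(values)) == 1)
    stop("all values identical; statistic undefined under tie correction",
         call. = FALSE)
  rp <- rank_pool(values)
  n <- rp$n
  rbar <- tapply(rp$ranks, group, mean)
  ni <- tabulate(group)
  tie_term <- rp$tie_cubes / (12 * (n - 1))
  pairs <- utils::combn(levels(group), 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- match(pairs[1, j], levels(group))
    i2 <- match(pairs[2, j], levels(group))
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[i1] + 1 / ni[i2]))
    z[j] <- (rbar[i1] - rbar[i2]) / se
    p_raw[j] <- 2 * pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z,
             p_raw = p_raw, p_adjusted = bh_adjust(p_raw),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment: sorted ascending,
#' `adj_(i) = min_{j >= i} p_(j) * m / j`, capped at 1, returned in the
#' input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' Shapiro-Wilk normality screen by group
#'
#' Reports each group's Shapiro-Wilk p-value and a `non_normal_flag` that is
#' `TRUE` when any group's p falls below `alpha`. Groups with fewer than 3
#' observations (or degenerate, all-identical values) get a missing p and do
#' not contribute to the flag. The screen is reporting only: the
#' nonparametric comparison path is taken regardless.
#'
#' @inheritParams kruskal_wallis
#' @param alpha Flagging threshold, default 0.05.
#' @return List with `p_by_group` (named numeric) and `non_normal_flag`.
#' @export
shapiro_screen <- function(values, group, alpha = 0.05) {
  group <- droplevels(as.factor(group))
  ok <- !is.na(values) & !is.na(group)
  values <- values[ok]
  group <- droplevels(group[ok])
  p <- vapply(levels(group), function(g) {
    v <- values[group == g]
    if (length(v) < 3 || length(v) > 5000 || length(unique(v)) == 1)
      return(NA_real_)
    shapiro.test(v)$p.value
  }, numeric(1))
  list(p_by_group = p,
       non_normal_flag = isTRUE(any(p < alpha, na.rm = TRUE)))
}

#' Run the full feature-by-group comparison framework
#'
#' Joins the per-patient feature table with the cohort covariates and, for
#' every feature and every grouping (pain-intensity class and pain type),
#' runs a Shapiro-Wilk screen, the Kruskal-Wallis test and Dunn's post hoc
#' comparisons with Benjamini-Hochberg adjustment. The same analyses are
#' repeated inside each level of the stratifying clinical variables (bone
#' metastases, breakthrough pain, morphine-equivalent dose class). Patients
#' with a missing value for a feature are dropped for that feature only. A
#' comparison whose stratum leaves a group empty (or otherwise degenerate)
#' is reported as not computable rather than silently skipped.
#'
#' @param features data.frame with `patient_id` and numeric feature columns.
#' @param cohort Covariate data.frame with `patient_id` and the grouping /
#'   stratifying columns.
#' @param groupings Character vector of cohort columns to compare across.
#' @param strata Character vector of dichotomous cohort columns to stratify
#'   by (in addition to the unstratified analysis).
#' @param alpha Significance threshold used for flagging.
#' @return An object of class `comparison_report`: list of data.frames
#'   `tests` (feature, grouping, stratum, stratum_level, H, df, p_value,
#'   non_normal_flag, n_used, computable, note), `pairwise` (z, raw and
#'   BH-adjusted p per group pair) and `groups` (per-group n, median, IQR).
#' @export
run_comparisons <- function(features, cohort,
                            groupings = c("pain_intensity_class",
                                          "pain_type"),
                            strata = c("bone_metastases", "btcp",
                                       "med_over_60"),
                            alpha = 0.05) {
  if (!"patient_id" %in% names(features))
    stop("`features` must carry patient_id", call. = FALSE)
  orphans <- setdiff(features$patient_id, cohort$patient_id)
  if (length(orphans))
    stop("features contain patient_ids absent from the cohort: ",
         paste(head(orphans, 5), collapse = ", "), call. = FALSE)
  dat <- merge(features, cohort, by = "patient_id")
  feat_cols <- setdiff(names(features), "patient_id")
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, logical(1))]

  layers <- data.frame(stratum = "none", stratum_level = NA_character_,
                       stringsAsFactors = FALSE)
  for (sv in strata) {
    lv <- sort(unique(as.character(dat[[sv]])))
    layers <- rbind(layers, data.frame(stratum = sv, stratum_level = lv,
                                       stringsAsFactors = FALSE))
  }

  tests <- list()
  pairwise <- list()
  groups <- list()
  for (li in seq_len(nrow(layers))) {
    st <- layers$stratum[li]
    lv <- layers$stratum_level[li]
    sub <- if (st == "none") dat else dat[as.character(dat[[st]]) == lv, ]
    for (grp in groupings) {
      g_all <- as.factor(sub[[grp]])
      for (fc in feat_cols) {
        v <- sub[[fc]]
        ok <- !is.na(v) & !is.na(g_all)
        vv <- v[ok]
        gg <- droplevels(g_all[ok])
        base <- data.frame(feature = fc, grouping = grp, stratum = st,
                           stratum_level = lv, stringsAsFactors = FALSE)
        n_levels_expected <- nlevels(droplevels(as.factor(dat[[grp]])))
        note <- NULL
        if (nlevels(gg) < max(2, n_levels_expected))
          note <- "empty group in this stratum"
        else if (length(vv) < nlevels(gg) + 1)
          note <- "too few observations"
        else if (length(unique(vv)) == 1)
          note <- "all values identical"
        if (!is.null(note)) {
          tests[[length(tests) + 1]] <- cbind(
            base, data.frame(H = NA_real_, df = NA_integer_,
                             p_value = NA_real_, non_normal_flag = NA,
                             n_used = length(vv), computable = FALSE,
                             note = note))
          next
        }
        kw <- kruskal_wallis(vv, gg)
        sh <- shapiro_screen(vv, gg, alpha)
        tests[[length(tests) + 1]] <- cbind(
          base, data.frame(H = kw$H, df = kw$df, p_value = kw$p_value,
                           non_normal_flag = sh$non_normal_flag,
                           n_used = kw$n, computable = TRUE,
                           note = ""))
        pairwise[[length(pairwise) + 1]] <- cbind(
          base[rep(1, choose(nlevels(gg), 2)), , drop = FALSE],
          dunn_posthoc(vv, gg))
        med <- tapply(vv, gg, median)
        iqr <- tapply(vv, gg, function(z)
          unname(diff(quantile(z, c(0.25, 0.75)))))
        groups[[length(groups) + 1]] <- cbind(
          base[rep(1, nlevels(gg)), , drop = FALSE],
          data.frame(group = levels(gg), n = as.integer(table(gg)),
                     median = as.numeric(med), iqr = as.numeric(iqr),
                     stringsAsFactors = FALSE))
      }
    }
  }
  rbind_reset <- function(lst) {
    if (!length(lst)) return(NULL)
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }
  structure(list(tests = rbind_reset(tests),
                 pairwise = rbind_reset(pairwise),
                 groups = rbind_reset(groups),
                 alpha = alpha),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  tst <- x$tests
  sig <- tst[tst$computable & tst$p_value < x$alpha, , drop = FALSE]
  cat(sprintf("<comparison_report> %d comparisons (%d not computable), %d significant at alpha = %g\n",
              nrow(tst), sum(!tst$computable), nrow(sig), x$alpha))
  if (nrow(sig)) {
    lab <- ifelse(sig$stratum == "none", "overall",
                  paste0(sig$stratum, "=", sig$stratum_level))
    for (i in order(sig$p_value))
      cat(sprintf("  %-16s by %-20s [%s] H = %.2f, p = %.3f\n",
                  sig$feature[i], sig$grouping[i], lab[i], sig$H[i],
                  sig$p_value[i]))
  }
  invisible(x)
}

#' Write a comparison report as tidy CSV files
#'
#' @param report A [run_comparisons()] result.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_comparison_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(report$tests, file.path(dir, "comparison_tests.csv"),
            row.names = FALSE)
  write.csv(report$pairwise, file.path(dir, "comparison_pairwise.csv"),
            row.names = FALSE)
  write.csv(report$groups, file.path(dir, "comparison_groups.csv"),
            row.names = FALSE)
  invisible(dir)
}
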
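# Test-retest reliability battery: random-intercept ICC with parametric
# bootstrap CI, variance reduction by consecutive-trial averaging,
# age-normative prediction bands from the healthy reference cohort, and
# paired longitudinal change tests.

#' Qualitative ICC band
#'
#' Conventional interpretation bands: below 0.50 poor, 0.50-0.75
#' moderate, 0.75-0.90 good, 0.90 and above excellent.
#'
#' @param icc numeric ICC value(s).
#' @return character label(s).
#' @export
icc_band <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.50, 0.75, 0.90, Inf),
      labels = c("poor", "moderate", "good", "excellent"),
      right = FALSE)
}

#' Intraclass correlation from a random-intercept mixed model
#'
#' Fits `score ~ 1 + (1 | subject)` by REML and reports
#' `ICC = sigma2_between / (sigma2_between + sigma2_within)` with a
#' 95% CI from a parametric bootstrap of the fitted model. Degenerate
#' inputs are handled directly: exact repeats (zero within-subject
#' variance) give ICC 1; zero between-subject variance gives ICC 0 with
#' a degenerate-CI note.
#'
#' @param data long-format data.frame of repeated scores.
#' @param score score column name.
#' @param subject subject identifier column name.
#' @param nboot parametric-bootstrap replicates for the CI (0 skips it).
#' @param seed integer seed for the bootstrap.
#' @return object of class `icc_report`: `icc`, `ci`, variance
#'   components, `band`, counts and any `note`.
#' @export
icc_random_intercept <- function(data, score = "score",
                                 subject = "subject_id",
                                 nboot = 500L, seed = 1L) {
  stopifnot(all(c(score, subject) %in% names(data)))
  data <- data[stats::complete.cases(data[c(score, subject)]), ]
  counts <- table(data[[subject]])
  if (sum(counts >= 2L) < 5L) {
    stop("need at least 2 observations for at least 5 subjects")
  }
  y <- data[[score]]
  g <- factor(data[[subject]])
  report <- function(icc, ci, vb, vw, note = NULL) {
    structure(list(icc = icc, ci = ci, var_between = vb, var_within = vw,
                   band = as.character(icc_band(icc)),
                   n_subjects = nlevels(g), n_obs = length(y), note = note),
              class = "icc_report")
  }
  within_var <- tapply(y, g, stats::var)
  if (all(within_var[!is.na(within_var)] == 0)) {
    return(report(1, c(1, 1), stats::var(tapply(y, g, mean)), 0,
                  note = "exact repeats: zero within-subject variance"))
  }
  d <- data.frame(.y = y, .g = g)
  fit <- lme4::lmer(.y ~ 1 + (1 | .g), data = d, REML = TRUE)
  icc_of <- function(m) {
    vc <- as.data.frame(lme4::VarCorr(m))
    vb <- vc$vcov[vc$grp == ".g"]
    vw <- vc$vcov[vc$grp == "Residual"]
    vb / (vb + vw)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  vb <- vc$vcov[vc$grp == ".g"]
  vw <- vc$vcov[vc$grp == "Residual"]
  icc <- vb / (vb + vw)
  note <- NULL
  ci <- c(NA_real_, NA_real_)
  if (vb == 0) {
    note <- "zero between-subject variance: degenerate CI"
    ci <- c(0, 0)
  } else if (nboot > 0L) {
    bs <- suppressMessages(suppressWarnings(
      lme4::bootMer(fit, icc_of, nsim = nboot, seed = seed,
                    type = "parametric")))
    ci <- stats::quantile(bs$t, c(0.025, 0.975), na.rm = TRUE,
                          names = FALSE)
  }
  report(icc, ci, vb, vw, note)
}

#' @export
print.icc_report <- function(x, ...) {
  cat(sprintf(
    "<icc_report> ICC = %.3f [%.3f, %.3f] (%s); %d subjects, %d obs\n",
    x$icc, x$ci[1], x$ci[2], x$band, x$n_subjects, x$n_obs))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Average consecutive trials in non-overlapping blocks
#'
#' Block means of `n` consecutive scores; a trailing remainder shorter
#' than `n` is dropped. Non-overlapping blocks keep block means
#' independent under iid noise, so averaging reduces noise variance by
#' exactly `1 - 1/n` in expectation.
#'
#' @param series time-ordered numeric scores.
#' @param n block size (default 4 consecutive trials).
#' @return numeric vector of block means (possibly empty).
#' @export
window_average <- function(series, n = 4L) {
  k <- length(series) %/% n
  if (k == 0L) {
    message("series shorter than one block; returning empty")
    return(numeric(0))
  }
  colMeans(matrix(series[seq_len(k * n)], nrow = n))
}

#' Within-subject variance reduction from block averaging
#'
#' `100 * (1 - var(block means) / var(raw series))` for one subject's
#' series; `NA` when the raw variance is zero or fewer than two blocks
#' exist. Under iid noise the expected reduction is `100 * (1 - 1/n)`;
#' a slow real trend is preserved by averaging and bounds the reduction
#' below that.
#'
#' @param series time-ordered numeric scores for one subject.
#' @param n block size.
#' @return percent reduction, or `NA_real_`.
#' @export
variance_reduction <- function(series, n = 4L) {
  v_raw <- stats::var(series)
  if (is.na(v_raw) || v_raw == 0) return(NA_real_)
  avg <- suppressMessages(window_average(series, n))
  if (length(avg) < 2L) return(NA_real_)
  100 * (1 - stats::var(avg) / v_raw)
}

#' Median variance reduction across subjects
#'
#' @param data long-format data.frame, time-ordered within subject.
#' @param score,subject,time column names.
#' @param n block size.
#' @return list with per-subject reductions and their median.
#' @export
median_variance_reduction <- function(data, score = "score",
                                      subject = "subject_id",
                                      time = "session_time", n = 4L) {
  data <- data[order(data[[subject]], data[[time]]), ]
  per <- vapply(split(data[[score]], data[[subject]]),
                variance_reduction, numeric(1), n = n)
  list(per_subject = per, median = stats::median(per, na.rm = TRUE))
}

#' Per-subject yearly medians
#'
#' Collapses repeated measurements to one median score (and median age)
#' per subject per calendar year, the granularity used for the
#' age-normative reference curves.
#'
#' @param data data.frame with subject, time (ISO-8601), age and score.
#' @param subject,time,age,score column names.
#' @return data.frame with one row per subject-year.
#' @export
yearly_medians <- function(data, subject = "subject_id",
                           time = "session_time", age = "age",
                           score = "score") {
  year <- substr(as.character(data[[time]]), 1, 4)
  key <- interaction(data[[subject]], year, drop = TRUE)
  out <- data.frame(
    subject_id = tapply(as.character(data[[subject]]), key, `[`, 1),
    year = tapply(year, key, `[`, 1),
    age = tapply(data[[age]], key, stats::median),
    score = tapply(data[[score]], key, stats::median),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$subject_id, out$year), ]
}

#' Age-normative prediction band from a healthy reference cohort
#'
#' Regresses score on age in the reference cohort (typically per-subject
#' yearly medians from healthy donors) and constructs the new-observation
#' prediction band at the requested level (default 90%). Query trials are
#' flagged only when they fall ABOVE the band — the impaired side, since
#' all scores are oriented so higher means worse.
#'
#' @param reference data.frame with `age` and `score` columns.
#' @param level band coverage (default 0.90).
#' @return object of class `norm_band`.
#' @export
age_norm_band <- function(reference, level = 0.90) {
  stopifnot(all(c("age", "score") %in% names(reference)))
  reference <- reference[stats::complete.cases(reference[c("age", "score")]), ]
  if (nrow(reference) < 10L) stop("reference cohort must have n >= 10")
  rng <- range(reference$age)
  if (diff(rng) < 10) {
    warning("reference age range under 10 years: band may be unstable")
  }
  fit <- stats::lm(score ~ age, data = reference)
  structure(list(fit = fit, level = level, age_range = rng,
                 n = nrow(reference)),
            class = "norm_band")
}

#' Evaluate an age-normative band at query trials
#'
#' @param band a `norm_band`.
#' @param query data.frame with `age` and `score` columns.
#' @return the query with `predicted`, `lo`, `hi` and logical
#'   `above_band` columns appended.
#' @export
flag_above_band <- function(band, query) {
  stopifnot(inherits(band, "norm_band"),
            all(c("age", "score") %in% names(query)))
  pr <- stats::predict(band$fit, newdata = query,
                       interval = "prediction", level = band$level)
  query$predicted <- pr[, "fit"]
  query$lo <- pr[, "lwr"]
  query$hi <- pr[, "upr"]
  query$above_band <- query$score > query$hi
  query
}

#' Paired longitudinal change test
#'
#' Wilcoxon signed-rank test of follow-up minus baseline scores across
#' subjects; raw p-value, no multiplicity adjustment. All-zero
#' differences return `NA` with a note.
#'
#' @param baseline,followup per-subject scores aligned by subject.
#' @return data.frame in the [compare_groups()] result layout.
#' @export
paired_change_test <- function(baseline, followup) {
  stopifnot(length(baseline) == length(followup))
  ok <- stats::complete.cases(baseline, followup)
  baseline <- baseline[ok]; followup <- followup[ok]
  if (length(baseline) < 5L) stop("need at least 5 complete pairs")
  if (all(followup - baseline == 0)) {
    return(data.frame(group1 = "baseline", group2 = "followup",
                      test = "signed-rank", statistic = NA_real_,
                      p = NA_real_, n1 = length(baseline),
                      n2 = length(followup),
                      note = "all differences zero",
                      stringsAsFactors = FALSE))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(followup, baseline, paired = TRUE, exact = FALSE))
  data.frame(group1 = "baseline", group2 = "followup",
             test = "signed-rank", statistic = unname(wt$statistic),
             p = wt$p.value, n1 = length(baseline), n2 = length(followup),
             note = NA_character_, stringsAsFactors = FALSE)
}
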
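# Cohort protocol: SDMT-stratified train/validation split, trial-selection
# rules, proportional-odds composite fitting over the ordered impairment
# continuum HD < RR-MS < P-MS, composite scoring, odds ratios and
# rank-based group comparisons.

MS_DIAGNOSES <- c("RR-MS", "SP-MS", "PP-MS")

# Collapse the 8-category diagnosis vocabulary onto the 3-level ordered
# modelling continuum; non-MS, non-HD groups map to NA (score-only).
composite_class <- function(diagnosis) {
  out <- rep(NA_character_, length(diagnosis))
  out[diagnosis == "HD"] <- "HD"
  out[diagnosis == "RR-MS"] <- "RR-MS"
  out[diagnosis %in% c("SP-MS", "PP-MS")] <- "P-MS"
  factor(out, levels = c("HD", "RR-MS", "P-MS"), ordered = TRUE)
}

#' Stratified train/validation split of the MS cohort
#'
#' Splits MS subjects (RR-MS, SP-MS, PP-MS) into training and validation
#' sets, stratified on quartiles of the SDMT distribution so cognitive
#' disability is balanced across cohorts. Healthy donors are model
#' anchors reused in both roles and never enter the split. Within each
#' stratum `ceiling(frac * n)` subjects go to training; singleton strata
#' go to training with a warning.
#'
#' @param subjects subject `data.frame` (needs `subject_id`, `diagnosis`,
#'   `sdmt`).
#' @param frac training fraction (default 2/3).
#' @param seed integer seed; required for reproducibility.
#' @return list with `train` and `validation` character vectors of
#'   subject ids (a disjoint partition of the MS subjects with SDMT).
#' @export
split_train_validation <- function(subjects, frac = 2 / 3, seed) {
  ms <- subjects[subjects$diagnosis %in% MS_DIAGNOSES & !is.na(subjects$sdmt),
                 , drop = FALSE]
  if (nrow(ms) < 2L) stop("need at least 2 MS subjects with SDMT")
  qs <- stats::quantile(ms$sdmt, probs = c(0.25, 0.5, 0.75))
  stratum <- findInterval(ms$sdmt, unique(qs))
  train <- character(0)
  with_seed(seed, {
    for (s in unique(stratum)) {
      ids <- ms$subject_id[stratum == s]
      if (length(ids) == 1L) {
        warning("stratum of size 1 assigned to training")
        train <- c(train, ids)
      } else {
        k <- ceiling(frac * length(ids))
        train <- c(train, sample(ids, k))
      }
    }
  })
  list(train = sort(train),
       validation = sort(setdiff(ms$subject_id, train)))
}

#' Apply the trial-selection rules
#'
#' Training uses up to the first 10 chronologically consecutive sessions
#' per subject; validation uses exactly the first session, mirroring the
#' intended clinical deployment where early results matter most.
#'
#' @param records biomarker table (`subject_id`, `session_time`, ...).
#' @param role `"train"` or `"validation"`.
#' @param max_train training cap on sessions per subject.
#' @return the selected rows, ordered by subject and session time.
#' @export
select_trials <- function(records, role = c("train", "validation"),
                          max_train = 10L) {
  role <- match.arg(role)
  ord <- order(records$subject_id, records$session_time)
  records <- records[ord, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$subject_id),
                        function(idx) {
    n <- if (role == "train") min(length(idx), max_train) else 1L
    idx[seq_len(n)]
  }), use.names = FALSE)
  records[sort(keep), , drop = FALSE]
}

#' Fit a proportional-odds composite model
#'
#' Fits a cumulative-logit (proportional-odds) ordinal regression of the
#' 3-level impairment continuum HD < RR-MS < P-MS on z-standardized
#' digital biomarkers, and reports 10-fold cross-validated classification
#' accuracy. The linear predictor of the fit is the composite score;
#' its orientation is fixed so that higher values mean greater
#' impairment (mean score of P-MS above HD on the training data).
#'
#' @param train training table with a `diagnosis` column and the feature
#'   columns; complete cases only are used.
#' @param features character vector of feature column names.
#' @param folds number of cross-validation folds.
#' @param seed integer seed for fold assignment.
#' @return an object of class `ordinal_composite`: polr coefficients and
#'   thresholds, standardization constants, orientation sign, Hessian-based
#'   covariance, CV accuracy and fit metadata.
#' @export
fit_ordinal_composite <- function(train, features, folds = 10L, seed = 1L) {
  stopifnot(all(features %in% names(train)))
  cls <- composite_class(train$diagnosis)
  keep <- !is.na(cls) & stats::complete.cases(train[features])
  d <- train[keep, features, drop = FALSE]
  cls <- cls[keep]
  if (nlevels(droplevels(cls)) < 3L) {
    stop("all three classes (HD, RR-MS, P-MS) must be present")
  }
  center <- vapply(d, mean, numeric(1))
  scale <- vapply(d, stats::sd, numeric(1))
  if (any(scale == 0)) {
    stop("constant feature(s): ", paste(features[scale == 0], collapse = ", "))
  }
  z <- as.data.frame(scale(d, center = center, scale = scale))
  dat <- cbind(z, .class = cls)
  fit <- tryCatch(
    MASS::polr(.class ~ ., data = dat, Hess = TRUE, method = "logistic"),
    error = function(e) stop("proportional-odds fit failed: ",
                             conditionMessage(e), call. = FALSE))
  co <- stats::coef(fit)
  if (any(!is.finite(co))) stop("proportional-odds fit diverged")
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  # cross-validated accuracy
  n <- nrow(dat)
  fold_id <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  hits <- logical(n)
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    cvfit <- tryCatch(
      MASS::polr(.class ~ ., data = dat[!hold, , drop = FALSE],
                 method = "logistic"),
      error = function(e) NULL)
    if (is.null(cvfit)) { hits[hold] <- NA; next }
    pred <- stats::predict(cvfit, newdata = dat[hold, , drop = FALSE],
                           type = "class")
    hits[hold] <- as.character(pred) == as.character(cls[hold])
  }
  # orient the linear predictor so greater impairment scores higher
  lp <- as.matrix(z) %*% co
  orientation <- if (mean(lp[cls == "P-MS"]) >= mean(lp[cls == "HD"])) 1 else -1
  structure(list(features = features,
                 coefficients = co,
                 zeta = fit$zeta,
                 center = center,
                 scale = scale,
                 orientation = orientation,
                 vcov = vc,
                 cv_accuracy = mean(hits, na.rm = TRUE),
                 n = n, folds = folds, seed = seed),
            class = "ordinal_composite")
}

#' @export
print.ordinal_composite <- function(x, ...) {
  cat(sprintf(
    "<ordinal_composite> %d features, n = %d, CV accuracy = %.3f\n",
    length(x$features), x$n, x$cv_accuracy))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Score observations with a fitted composite model
#'
#' The composite score is the orientation-fixed linear predictor:
#' standardized features times the fitted coefficients. An observation at
#' the training feature means scores exactly 0. Rows with any missing
#' feature score `NA`.
#'
#' @param model an `ordinal_composite`.
#' @param newdata data.frame containing the model's feature columns.
#' @return numeric vector of composite scores (higher = more impaired).
#' @export
composite_score <- function(model, newdata) {
  miss <- setdiff(model$features, names(newdata))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  x <- as.matrix(newdata[model$features])
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  drop(model$orientation * (z %*% model$coefficients))
}

#' Per-feature odds ratios with Wald confidence intervals
#'
#' Exponentiated proportional-odds coefficients with Wald-type 95%
#' confidence intervals and Wald p-values, per standard-deviation change
#' in each (standardized) biomarker.
#'
#' @param model an `ordinal_composite`.
#' @param level confidence level.
#' @return data.frame with `feature`, `or`, `lo`, `hi`, `p`.
#' @export
odds_ratios <- function(model, level = 0.95) {
  co <- model$coefficients
  if (is.null(model$vcov)) {
    warning("covariance unavailable; confidence intervals not computed")
    se <- rep(NA_real_, length(co))
  } else {
    se <- sqrt(diag(model$vcov))[seq_along(co)]
  }
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(feature = model$features,
             or = exp(co),
             lo = exp(co - zq * se),
             hi = exp(co + zq * se),
             p = 2 * stats::pnorm(-abs(co / se)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank-based group comparisons of composite scores
#'
#' All pairwise contrasts among the supplied groups using the Wilcoxon
#' rank-sum test (or the signed-rank test for paired data). Raw p-values
#' are returned without multiplicity adjustment.
#'
#' @param scores numeric vector of per-subject scores.
#' @param labels group labels aligned with `scores`.
#' @param paired logical; when `TRUE` exactly two groups of equal length
#'   (aligned pairs) are required.
#' @return data.frame with one row per contrast: groups, test name,
#'   statistic, raw p-value and group sizes.
#' @export
compare_groups <- function(scores, labels, paired = FALSE) {
  labels <- as.character(labels)
  groups <- unique(labels)
  out <- list()
  for (pair in utils::combn(groups, 2, simplify = FALSE)) {
    x <- scores[labels == pair[1]]
    y <- scores[labels == pair[2]]
    if (length(x) < 2L || length(y) < 2L) {
      message("skipping contrast ", pair[1], " vs ", pair[2],
              ": fewer than 2 observations in a group")
      next
    }
    if (paired && length(x) != length(y)) {
      stop("paired comparison requires aligned groups of equal size")
    }
    if (paired && all(x - y == 0)) {
      out[[length(out) + 1L]] <- data.frame(
        group1 = pair[1], group2 = pair[2], test = "signed-rank",
        statistic = NA_real_, p = NA_real_, n1 = length(x),
        n2 = length(y), stringsAsFactors = FALSE)
      next
    }
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, paired = paired, exact = FALSE))
    out[[length(out) + 1L]] <- data.frame(
      group1 = pair[1], group2 = pair[2],
      test = if (paired) "signed-rank" else "rank-sum",
      statistic = unname(wt$statistic), p = wt$p.value,
      n1 = length(x), n2 = length(y), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Serialize / restore a composite model as versioned JSON
#'
#' @param model an `ordinal_composite`.
#' @param path JSON file path.
#' @return the path (write) or the restored model (read).
#' @export
write_composite_json <- function(model, path) {
  obj <- list(format = "tapmem-ordinal-composite", version = "1.0",
              features = model$features,
              coefficients = as.list(model$coefficients),
              thresholds = as.list(model$zeta),
              center = as.list(model$center),
              scale = as.list(model$scale),
              orientation = model$orientation,
              cv_accuracy = model$cv_accuracy,
              n = model$n, seed = model$seed)
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                           digits = NA)), path)
  invisible(path)
}

#' @rdname write_composite_json
#' @export
read_composite_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  structure(list(features = obj$features,
                 coefficients = unlist(obj$coefficients),
                 zeta = unlist(obj$thresholds),
                 center = unlist(obj$center),
                 scale = unlist(obj$scale),
                 orientation = obj$orientation,
                 vcov = NULL,
                 cv_accuracy = obj$cv_accuracy,
                 n = obj$n, seed = obj$seed),
            class = "ordinal_composite")
}
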
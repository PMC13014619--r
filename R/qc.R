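# SDMT quality control: linear prediction of SDMT from spatial biomarkers,
# AIC-stepwise reduction, exact new-observation prediction intervals used
# as a concordance envelope, and the agreement statistics (Spearman rho,
# Lin's CCC) with participant-level bootstrap confidence intervals.

#' Candidate spatial predictors for the SDMT model
#'
#' The eight spatial-stage biomarkers: both iSMPT-S values, both adjusted
#' latencies, both impairment scores and both mistake counts.
#'
#' @return character vector of column names.
#' @export
spatial_features <- function() {
  c("iSMPT_S_static", "iSMPT_S_dynamic", "StaticSRLa", "DynamicSRLa",
    "StaticSRI", "DynamicSRI", "StaticSRM", "DynamicSRM")
}

#' Fit the SDMT prediction model
#'
#' Ordinary least squares of observed SDMT on all candidate spatial
#' biomarkers (complete cases). The returned object retains the full
#' training design, so exact t-based prediction intervals (residual
#' variance plus leverage) are available at any query point.
#'
#' @param train data.frame with the feature columns and an SDMT column.
#' @param features candidate predictors (default [spatial_features()]).
#' @param outcome name of the observed-SDMT column.
#' @return object of class `sdmt_model` wrapping the `lm` fit.
#' @export
fit_sdmt_model <- function(train, features = spatial_features(),
                           outcome = "sdmt") {
  stopifnot(all(c(features, outcome) %in% names(train)))
  d <- train[stats::complete.cases(train[c(features, outcome)]),
             c(features, outcome), drop = FALSE]
  if (nrow(d) <= length(features) + 2L) {
    stop("need n > number of candidate predictors + 2 (have n = ",
         nrow(d), ")")
  }
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(features, collapse = " + ")))
  # do.call embeds the data in the call so later stepwise refits can
  # re-evaluate it outside this frame
  fit <- do.call(stats::lm, list(fml, data = d))
  aliased <- is.na(stats::coef(fit))
  if (any(aliased)) {
    stop("collinear predictor(s): ",
         paste(names(stats::coef(fit))[aliased], collapse = ", "))
  }
  structure(list(fit = fit, features = features, outcome = outcome,
                 ranges = lapply(d[features], range)),
            class = "sdmt_model")
}

#' @export
print.sdmt_model <- function(x, ...) {
  cat(sprintf("<sdmt_model> %d predictor(s), n = %d, R^2 = %.3f\n",
              length(x$features), stats::nobs(x$fit),
              summary(x$fit)$r.squared))
  invisible(x)
}

#' Bidirectional AIC-stepwise reduction of the SDMT model
#'
#' Starts from the full fit and searches both directions for the
#' AIC-minimizing predictor subset; the reduced model's AIC never
#' exceeds the full model's.
#'
#' @param model an `sdmt_model`.
#' @return a reduced `sdmt_model`.
#' @export
stepwise_reduce <- function(model) {
  stopifnot(inherits(model, "sdmt_model"))
  red <- MASS::stepAIC(model$fit, direction = "both", trace = 0)
  kept <- intersect(model$features, attr(stats::terms(red), "term.labels"))
  structure(list(fit = red, features = kept, outcome = model$outcome,
                 ranges = model$ranges[kept]),
            class = "sdmt_model")
}

#' Predict SDMT with a prediction envelope and flag discordant scores
#'
#' Computes the point prediction and the exact t-quantile prediction
#' interval for a new observation (residual variance plus leverage term)
#' at each query row. When observed SDMT values are supplied, rows whose
#' observation falls outside the envelope are flagged `"discordant"` —
#' the internal quality-control signal for potentially unreliable trials.
#' Queries outside the training feature range trigger an extrapolation
#' warning but still receive a verdict.
#'
#' @param model an `sdmt_model`.
#' @param newdata data.frame with the model's feature columns.
#' @param observed optional numeric vector of observed SDMT scores.
#' @param level envelope coverage (default 0.95).
#' @return data.frame with `predicted`, `lo`, `hi`, and, when `observed`
#'   is given, `observed` and `flag` (`"concordant"`/`"discordant"`).
#' @export
predict_with_interval <- function(model, newdata, observed = NULL,
                                  level = 0.95) {
  stopifnot(inherits(model, "sdmt_model"))
  miss <- setdiff(model$features, names(newdata))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  outside <- vapply(model$features, function(f) {
    any(newdata[[f]] < model$ranges[[f]][1] |
        newdata[[f]] > model$ranges[[f]][2], na.rm = TRUE)
  }, logical(1))
  if (any(outside)) {
    warning("extrapolating beyond the training range of: ",
            paste(model$features[outside], collapse = ", "))
  }
  pr <- stats::predict(model$fit, newdata = newdata,
                       interval = "prediction", level = level)
  out <- data.frame(predicted = pr[, "fit"], lo = pr[, "lwr"],
                    hi = pr[, "upr"])
  if (!is.null(observed)) {
    stopifnot(length(observed) == nrow(out))
    out$observed <- observed
    out$flag <- ifelse(is.na(observed), NA_character_,
                       ifelse(observed < out$lo | observed > out$hi,
                              "discordant", "concordant"))
  }
  out
}

#' Spearman rank correlation
#'
#' Rank-order correlation with average ranks for ties. Returns `NA` when
#' either vector is constant (undefined).
#'
#' @param x,y numeric vectors.
#' @return rho in \[-1, 1\] or `NA_real_`.
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Lin's concordance correlation coefficient
#'
#' Measures 1:1 agreement between measured and predicted values:
#' `ccc = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' population (n-denominator) moments, per Lin's original estimator.
#' Penalizes both imprecision and location/scale shift, so `|ccc| <= |r|`.
#'
#' @param x,y numeric vectors.
#' @return CCC in \[-1, 1\] or `NA_real_` when total variance is zero.
#' @export
lins_ccc <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- vx + vy + (mx - my)^2
  if (denom == 0) return(NA_real_)
  2 * sxy / denom
}

#' Participant-level percentile bootstrap confidence interval
#'
#' Resamples subjects (not rows) with replacement — each drawn subject
#' contributes all of its rows — recomputes the statistic per replicate,
#' and returns the percentile interval. Repeated observations per subject
#' therefore travel together, respecting within-subject correlation.
#'
#' @param data data.frame containing a subject identifier column.
#' @param statistic function `data.frame -> numeric scalar`.
#' @param unit subject identifier column name.
#' @param B bootstrap replicates (default 2000).
#' @param seed integer seed.
#' @param level confidence level.
#' @return list with `lo`, `hi`, `estimate`, `B`, and the replicate vector.
#' @export
bootstrap_ci <- function(data, statistic, unit = "subject_id", B = 2000L,
                         seed = 1L, level = 0.95) {
  stopifnot(unit %in% names(data))
  parts <- split(data, data[[unit]])
  if (length(parts) < 10L) stop("need at least 10 subjects")
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(length(parts), replace = TRUE)
      statistic(do.call(rbind, parts[idx]))
    }, numeric(1))
  })
  frac_na <- mean(is.na(reps))
  if (frac_na > 0.10) {
    warning(sprintf(
      "statistic undefined in %.0f%% of replicates; interval may be wide",
      100 * frac_na))
  }
  alpha <- (1 - level) / 2
  qs <- stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(lo = qs[1], hi = qs[2], estimate = statistic(data), B = B,
       replicates = reps)
}
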
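# Derivation of the 14 digital biomarkers from validated trial records:
# iSMPT (per-trial minimal inter-tap interval), adjusted recall latencies,
# verbal/spatial recall impairment under partial-credit scoring, and
# self-corrected mistake counts.

#' Individualized sensory-motor processing threshold (iSMPT)
#'
#' The minimum over all within-attempt inter-tap intervals of a trial,
#' interpreted as the subject's fastest sensory-motor response floor: the
#' quickest tap a subject produces carries the least cognitive load, so
#' its latency approximates pure sensory-motor delay.
#'
#' @param trial a `trial_record`.
#' @return seconds (strictly positive), or `NA_real_` when no attempt has
#'   at least two taps.
#' @export
ismpt <- function(trial) {
  iv <- unlist(inter_tap_intervals(trial))
  if (length(iv) == 0L) return(NA_real_)
  min(iv)
}

#' Adjusted recall latency (RLa)
#'
#' Mean inter-tap interval of the trial minus the trial's iSMPT, leaving
#' the delay attributable to cognitive demand after the subject-specific
#' sensory-motor floor is removed. Equals the mean of per-interval
#' excesses over iSMPT, and is therefore non-negative by construction.
#'
#' @param trial a `trial_record`.
#' @return seconds, or `NA_real_` when iSMPT is undefined.
#' @export
adjusted_latency <- function(trial) {
  iv <- unlist(inter_tap_intervals(trial))
  if (length(iv) == 0L) return(NA_real_)
  mean(iv) - min(iv)
}

#' Verbal recall impairment (VRI)
#'
#' Percent-correct over the first attempt of a verbal trial, inverted
#' (100 - pct) and log10-transformed with a +1 shift so that perfect
#' recall maps to exactly 0. Only the first attempt is used: repeats are
#' triggered by errors and would dilute the accuracy signal.
#'
#' @param trial a verbal `trial_record`.
#' @return VRI on the log10 scale, or `NA_real_` with no attempted pairs.
#' @export
verbal_recall_impairment <- function(trial) {
  stopifnot(inherits(trial, "trial_record"))
  if (is_spatial_stage(trial$stage)) {
    stop("verbal_recall_impairment applies to verbal trials")
  }
  if (length(trial$attempts) == 0L) return(NA_real_)
  ev <- trial$attempts[[1L]]$events
  sel <- ev[ev$action == "select", , drop = FALSE]
  if (nrow(sel) == 0L) return(NA_real_)
  pct <- 100 * sum(sel$correct) / nrow(sel)
  log10(100 - pct + 1)
}

# Incorrect selection taps in one attempt (partial-credit "mistakes").
attempt_mistakes <- function(a) {
  ev <- a$events
  sum(ev$action == "select" & !ev$correct)
}

# Shared partial-credit engine. `weight` is 1 (static) or 2 (dynamic).
spatial_partial_credit <- function(trial, weight) {
  stopifnot(inherits(trial, "trial_record"))
  lev <- vapply(trial$attempts, function(a) a$level, integer(1))
  ok <- vapply(trial$attempts, function(a) a$passed, logical(1))
  if (length(lev) == 0L) return(NA_real_)
  passed_levels <- unique(lev[ok])
  score <- weight * sum(passed_levels)
  failed_levels <- setdiff(unique(lev), passed_levels)
  if (length(failed_levels)) {
    top <- max(failed_levels)
    mist <- vapply(trial$attempts[lev == top], attempt_mistakes, numeric(1))
    score <- score + max(0, weight * top - weight * mean(mist))
  }
  score
}

#' Partial-credit score of a static spatial trial
#'
#' Passed levels contribute their full square count (4 + 5 + 6 + 7 + 8 =
#' 30 maximum). For the highest failed level, credit is the level's
#' square count minus the mean number of incorrect taps across all
#' attempts at that level, floored at 0 — so near-misses score higher
#' than outright failures.
#'
#' @param trial a `spatial_static` trial record.
#' @return raw score in \[0, 30\].
#' @export
static_partial_credit <- function(trial) {
  if (trial$stage != "spatial_static") {
    stop("static_partial_credit applies to spatial_static trials")
  }
  spatial_partial_credit(trial, weight = 1)
}

#' Partial-credit score of a dynamic spatial trial
#'
#' As [static_partial_credit()], but every level's tile count is
#' double-weighted (2 x 4 ... 2 x 8 = 60 maximum) and each mistake costs
#' two points, reflecting the added serial-order demand.
#'
#' @param trial a `spatial_dynamic` trial record.
#' @return raw score in \[0, 60\].
#' @export
dynamic_partial_credit <- function(trial) {
  if (trial$stage != "spatial_dynamic") {
    stop("dynamic_partial_credit applies to spatial_dynamic trials")
  }
  spatial_partial_credit(trial, weight = 2)
}

#' Spatial recall impairment (SRI)
#'
#' Inverts a raw partial-credit score against its stage maximum and
#' log10-transforms it with a +1 shift, so a flawless run maps to 0 and
#' SRI rises monotonically with impairment.
#'
#' @param raw raw partial-credit score.
#' @param max stage maximum (30 static, 60 dynamic).
#' @return SRI on the log10 scale.
#' @export
spatial_recall_impairment <- function(raw, max) {
  if (any(raw < 0 | raw > max, na.rm = TRUE)) {
    stop("raw score must lie in [0, max]")
  }
  log10(max - raw + 1)
}

#' Spatial recall mistakes (SRM)
#'
#' Counts self-corrected errors — an incorrect square tapped and then
#' deselected — over all attempts of a spatial trial, log10-transformed
#' with a +1 shift. Distinct from the partial-credit mistake count, which
#' uses all incorrect taps whether or not they were corrected.
#'
#' @param trial a spatial `trial_record`.
#' @return SRM on the log10 scale.
#' @export
spatial_recall_mistakes <- function(trial) {
  stopifnot(inherits(trial, "trial_record"))
  if (!is_spatial_stage(trial$stage)) {
    stop("spatial_recall_mistakes applies to spatial trials")
  }
  count <- 0L
  for (a in trial$attempts) {
    ev <- a$events
    open_correct <- list()  # target -> correct flag of most recent open select
    for (i in seq_len(nrow(ev))) {
      key <- as.character(ev$target[i])
      if (ev$action[i] == "select") {
        open_correct[[key]] <- ev$correct[i]
      } else {
        if (identical(open_correct[[key]], FALSE)) count <- count + 1L
        open_correct[[key]] <- NULL
      }
    }
  }
  log10(count + 1)
}

biomarker_names <- function() {
  c("iSMPT_V_imm", "iSMPT_V_del", "iSMPT_S_static", "iSMPT_S_dynamic",
    "ImmVRLa", "DelVRLa", "StaticSRLa", "DynamicSRLa",
    "ImmVRI", "DelVRI", "StaticSRI", "DynamicSRI",
    "StaticSRM", "DynamicSRM")
}

stage_max <- c(spatial_static = 30, spatial_dynamic = 60)

#' Assemble the 14-biomarker vector for one subject-session
#'
#' Takes the (up to four) stage trial records of one session, validates
#' each against the integrity rules, and derives per-stage iSMPT,
#' adjusted latency, impairment and (spatial) mistake biomarkers. Absent
#' or invalid stages yield missing fields; nothing is imputed.
#'
#' @param trials list of `trial_record`s from one session (one per stage).
#' @param rules an [integrity_rules()] list.
#' @return a one-row `data.frame`: `subject_id`, `session_time`, the 14
#'   biomarker columns, and one `valid_<stage>` flag per stage.
#' @export
biomarker_vector <- function(trials, rules = integrity_rules()) {
  stopifnot(length(trials) >= 1L)
  trials <- lapply(trials, validate_trial, rules = rules)
  stages <- vapply(trials, function(x) x$stage, character(1))
  if (anyDuplicated(stages)) stop("one trial per stage expected")
  out <- as.list(rep(NA_real_, length(biomarker_names())))
  names(out) <- biomarker_names()
  flags <- as.list(rep(FALSE, 4))
  names(flags) <- paste0("valid_", tapmem_stages())
  for (trial in trials) {
    if (!isTRUE(trial$valid)) next
    flags[[paste0("valid_", trial$stage)]] <- TRUE
    m <- ismpt(trial)
    la <- adjusted_latency(trial)
    switch(trial$stage,
      verbal_immediate = {
        out$iSMPT_V_imm <- m; out$ImmVRLa <- la
        out$ImmVRI <- verbal_recall_impairment(trial)
      },
      verbal_delayed = {
        out$iSMPT_V_del <- m; out$DelVRLa <- la
        out$DelVRI <- verbal_recall_impairment(trial)
      },
      spatial_static = {
        out$iSMPT_S_static <- m; out$StaticSRLa <- la
        raw <- static_partial_credit(trial)
        out$StaticSRI <- spatial_recall_impairment(raw, 30)
        out$StaticSRM <- spatial_recall_mistakes(trial)
      },
      spatial_dynamic = {
        out$iSMPT_S_dynamic <- m; out$DynamicSRLa <- la
        raw <- dynamic_partial_credit(trial)
        out$DynamicSRI <- spatial_recall_impairment(raw, 60)
        out$DynamicSRM <- spatial_recall_mistakes(trial)
      })
  }
  cbind(data.frame(subject_id = trials[[1L]]$subject_id,
                   session_time = trials[[1L]]$session_time,
                   stringsAsFactors = FALSE),
        as.data.frame(out), as.data.frame(flags))
}

#' Quadrant stratification on iSMPT-S and adjusted recall latency
#'
#' Median-splits each axis (within the supplied values; ties go to the
#' "low" side) and assigns the four-quadrant labels used to dissociate
#' sensory-motor from cognitive slowing: Q1 = high iSMPT-S and high
#' adjusted latency (combined impairment), Q2 = low iSMPT-S, high latency
#' (cognitive slowing), Q3 = low/low (preserved), Q4 = high iSMPT-S, low
#' latency (sensory-motor delay with preserved cognition).
#'
#' @param ismpt_s numeric vector of spatial iSMPT values.
#' @param srla numeric vector of adjusted spatial recall latencies.
#' @return factor with levels `Q1`-`Q4`.
#' @export
quadrant_stratify <- function(ismpt_s, srla) {
  stopifnot(length(ismpt_s) == length(srla))
  if (sum(stats::complete.cases(ismpt_s, srla)) < 4L) {
    stop("need at least 4 subjects with both measures")
  }
  m1 <- stats::median(ismpt_s, na.rm = TRUE)
  m2 <- stats::median(srla, na.rm = TRUE)
  if (all(ismpt_s == m1, na.rm = TRUE) || all(srla == m2, na.rm = TRUE)) {
    warning("degenerate split: all values identical on one axis")
  }
  hi1 <- ismpt_s > m1
  hi2 <- srla > m2
  lab <- ifelse(hi1 & hi2, "Q1",
         ifelse(!hi1 & hi2, "Q2",
         ifelse(!hi1 & !hi2, "Q3", "Q4")))
  factor(lab, levels = c("Q1", "Q2", "Q3", "Q4"))
}

#' Write / read a biomarker table
#'
#' One row per subject-session with the 14 biomarker columns named as in
#' [biomarker_vector()], plus identifiers and stage-validity flags.
#'
#' @param table biomarker `data.frame`.
#' @param path CSV file path.
#' @return the path (write) or the table (read).
#' @export
write_biomarkers <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_biomarkers
#' @export
read_biomarkers <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(subject_id = "character"))
}
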
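# Raw trial-log data model: tap events, attempts, trial records, JSON I/O
# and trial-level integrity checks. Everything downstream consumes the
# `trial_record` objects defined here.

#' Test stages and diagnosis vocabulary
#'
#' `tapmem_stages()` returns the four test-stage identifiers; the verbal
#' test has an immediate and a (post-break) delayed recall stage, the
#' spatial test a static (pattern only) and a dynamic (pattern + serial
#' order) stage. `tapmem_diagnoses()` returns the eight-category diagnosis
#' vocabulary used in subject metadata.
#'
#' @return character vector.
#' @export
tapmem_stages <- function() {
  c("verbal_immediate", "verbal_delayed", "spatial_static", "spatial_dynamic")
}

#' @rdname tapmem_stages
#' @export
tapmem_diagnoses <- function() {
  c("HD", "NIND", "OIND", "RIS", "CIS", "RR-MS", "SP-MS", "PP-MS")
}

# Grid geometry: 4x4, cells indexed 0..15 row-major.
cell_row <- function(cell) cell %/% 4L
cell_col <- function(cell) cell %% 4L

# TRUE when every pattern cell (after the first) lies within Chebyshev
# distance 1 of at least one other pattern cell.
pattern_adjacent <- function(pattern) {
  n <- length(pattern)
  if (n <= 1L) return(TRUE)
  r <- cell_row(pattern); c <- cell_col(pattern)
  for (i in seq_len(n)) {
    d <- pmax(abs(r[i] - r[-i]), abs(c[i] - c[-i]))
    if (!any(d <= 1L)) return(FALSE)
  }
  TRUE
}

#' Construct a tap-event table
#'
#' Timestamps are integer milliseconds since trial start; intervals derived
#' from them are reported in seconds. `action` is `"select"` or
#' `"deselect"`; `target` is a grid-cell index 0-15 (spatial) or an option
#' index 0-3 (verbal); `correct` records whether a selection matches the
#' expected answer.
#'
#' @param t non-negative integer milliseconds, non-decreasing.
#' @param action character, `"select"`/`"deselect"`.
#' @param target integer target index.
#' @param correct logical.
#' @return a `data.frame` with columns `t`, `action`, `target`, `correct`.
#' @export
tap_events <- function(t, action, target, correct) {
  t <- as.integer(t)
  target <- as.integer(target)
  correct <- as.logical(correct)
  action <- as.character(action)
  n <- length(t)
  stopifnot(length(action) == n, length(target) == n, length(correct) == n)
  if (n && any(t < 0L)) stop("tap timestamps must be non-negative")
  if (n && is.unsorted(t)) stop("tap timestamps must be non-decreasing")
  if (!all(action %in% c("select", "deselect"))) {
    stop("action must be 'select' or 'deselect'")
  }
  # deselect may only follow an open select of the same target
  open <- integer(0)
  for (i in seq_len(n)) {
    if (action[i] == "select") {
      open <- c(open, target[i])
    } else {
      j <- match(target[i], open)
      if (is.na(j)) {
        stop("deselect of target ", target[i], " without a prior select")
      }
      open <- open[-j]
    }
  }
  data.frame(t = t, action = action, target = target, correct = correct,
             stringsAsFactors = FALSE)
}

#' Construct a verbal recall attempt
#'
#' One attempt presents 10 cue words, each answered by a single selection
#' among four options; the attempt passes only when all 10 selections are
#' correct.
#'
#' @param events a `tap_events()` table with exactly 10 select events.
#' @param cues optional opaque cue identifiers (length 10).
#' @return a `verbal_attempt` list with `events`, `cues`, `passed`.
#' @export
verbal_attempt <- function(events, cues = NULL) {
  sel <- events[events$action == "select", , drop = FALSE]
  if (nrow(sel) != 10L) {
    stop("a verbal attempt must contain exactly 10 selections, got ",
         nrow(sel))
  }
  if (any(sel$target < 0L | sel$target > 3L)) {
    stop("verbal option indices must be in 0-3")
  }
  structure(list(events = events, cues = cues,
                 passed = all(sel$correct)),
            class = "tapmem_attempt")
}

#' Construct a spatial recall attempt
#'
#' @param level pattern size, 4-8 squares.
#' @param pattern integer grid cells (0-15) forming the target pattern;
#'   corner-adjacency is enforced (every cell within Chebyshev distance 1
#'   of another pattern cell).
#' @param events a `tap_events()` table of grid-cell toggles.
#' @param passed logical; whether the reproduction was accepted.
#' @return a `spatial_attempt` list.
#' @export
spatial_attempt <- function(level, pattern, events, passed) {
  level <- as.integer(level)
  pattern <- as.integer(pattern)
  if (level < 4L || level > 8L) stop("level must be in 4-8")
  if (length(pattern) != level) {
    stop("pattern must contain exactly `level` cells")
  }
  if (any(pattern < 0L | pattern > 15L)) stop("grid cells must be in 0-15")
  if (anyDuplicated(pattern)) stop("pattern cells must be distinct")
  if (!pattern_adjacent(pattern)) {
    stop("pattern cells must be adjacent by at least a corner")
  }
  if (any(events$target < 0L | events$target > 15L)) {
    stop("spatial targets must be grid cells 0-15")
  }
  structure(list(level = level, pattern = pattern, events = events,
                 passed = isTRUE(passed)),
            class = "tapmem_attempt")
}

is_spatial_stage <- function(stage) startsWith(stage, "spatial")

#' Construct a trial record
#'
#' A trial record is one administration of one test stage: the ordered
#' attempts with their tap events, plus identifying metadata. Structural
#' invariants (attempt cap, level monotonicity, timestamp ordering across
#' the event stream) are enforced at construction; soft integrity checks
#' live in [validate_trial()].
#'
#' @param subject_id opaque subject identifier.
#' @param stage one of [tapmem_stages()].
#' @param session_time ISO-8601 timestamp string.
#' @param attempts list of [verbal_attempt()] or [spatial_attempt()].
#' @param extras named list of unknown fields to preserve on round-trip.
#' @return an object of class `trial_record`.
#' @export
trial_record <- function(subject_id, stage, session_time, attempts,
                         extras = list()) {
  stage <- match.arg(stage, tapmem_stages())
  if (!is.list(attempts)) stop("attempts must be a list")
  spatial <- is_spatial_stage(stage)
  if (spatial) {
    if (length(attempts) > 5L) {
      stop("spatial trials contain at most 5 attempts")
    }
    lev <- vapply(attempts, function(a) a$level, integer(1))
    if (length(lev) > 1L && is.unsorted(lev)) {
      stop("attempt levels must be non-decreasing")
    }
    ok <- vapply(attempts, function(a) a$passed, logical(1))
    if (length(lev) > 1L) {
      for (i in seq_len(length(lev) - 1L)) {
        if (!ok[i] && lev[i + 1L] != lev[i]) {
          stop("a failed attempt must be followed by the same level")
        }
      }
    }
  }
  # timestamps non-decreasing over the whole event stream
  allt <- unlist(lapply(attempts, function(a) a$events$t))
  if (length(allt) > 1L && is.unsorted(allt)) {
    stop("timestamps must be non-decreasing across the trial event stream")
  }
  if (length(extras) == 0L) extras <- list()
  structure(list(subject_id = as.character(subject_id),
                 stage = stage,
                 session_time = as.character(session_time),
                 attempts = attempts,
                 valid = NA,
                 reasons = character(0),
                 extras = extras),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s / %s @ %s: %d attempt(s), valid=%s\n",
              x$subject_id, x$stage, x$session_time, length(x$attempts),
              as.character(x$valid)))
  invisible(x)
}

#' Inter-tap intervals of a trial
#'
#' Consecutive within-attempt tap intervals in seconds. The first interval
#' of each attempt is measured from that attempt's first tap, not from
#' stimulus onset, so gaps between attempts never enter the stream. All
#' tap events (selections and deselections) are included.
#'
#' @param trial a `trial_record`.
#' @return a list, one numeric vector of seconds per attempt (empty for
#'   attempts with fewer than 2 taps).
#' @export
inter_tap_intervals <- function(trial) {
  stopifnot(inherits(trial, "trial_record"))
  lapply(trial$attempts, function(a) {
    if (nrow(a$events) < 2L) return(numeric(0))
    diff(a$events$t) / 1000
  })
}

#' Integrity-rule configuration
#'
#' Thresholds used by [validate_trial()]. Defaults: an inter-tap interval
#' below 150 ms is treated as anticipation, one above 300 s as
#' abandonment, and a whole trial longer than 30 minutes is rejected.
#'
#' @param interval_floor seconds; minimum credible inter-tap interval.
#' @param interval_ceiling seconds; maximum credible inter-tap interval.
#' @param max_duration seconds; maximum total trial duration.
#' @return a list of thresholds.
#' @export
integrity_rules <- function(interval_floor = 0.150,
                            interval_ceiling = 300,
                            max_duration = 1800) {
  list(interval_floor = interval_floor,
       interval_ceiling = interval_ceiling,
       max_duration = max_duration)
}

#' Validate a trial against integrity rules
#'
#' Trial-level exclusion only; no subject-level imputation anywhere in the
#' pipeline. The verdict is recorded on the returned record (`valid`,
#' `reasons`) rather than raised as an error.
#'
#' Reasons: `"missing data"` (no attempts, or an attempt without events),
#' `"completion time"` (total duration above the cap, or an inter-tap gap
#' above the ceiling), `"anticipation"` (an interval below the floor).
#'
#' @param trial a `trial_record`.
#' @param rules an [integrity_rules()] list.
#' @return the trial with `valid` and `reasons` filled in.
#' @export
validate_trial <- function(trial, rules = integrity_rules()) {
  stopifnot(inherits(trial, "trial_record"))
  reasons <- character(0)
  if (length(trial$attempts) == 0L) {
    reasons <- c(reasons, "missing data")
  } else {
    nev <- vapply(trial$attempts, function(a) nrow(a$events), integer(1))
    if (any(nev == 0L)) reasons <- c(reasons, "missing data")
    allt <- unlist(lapply(trial$attempts, function(a) a$events$t))
    if (length(allt) &&
        (max(allt) - min(allt)) / 1000 > rules$max_duration) {
      reasons <- c(reasons, "completion time")
    }
    iv <- unlist(inter_tap_intervals(trial))
    if (length(iv)) {
      if (any(iv > rules$interval_ceiling)) {
        reasons <- c(reasons, "completion time")
      }
      if (any(iv < rules$interval_floor)) {
        reasons <- c(reasons, "anticipation")
      }
    }
  }
  trial$reasons <- unique(reasons)
  trial$valid <- length(trial$reasons) == 0L
  trial
}

# ---- JSON serialization ----------------------------------------------------

TRIAL_SCHEMA_VERSION <- "1.0"

attempt_to_list <- function(a, spatial) {
  ev <- lapply(seq_len(nrow(a$events)), function(i) {
    list(t = a$events$t[i],
         action = a$events$action[i],
         target = a$events$target[i],
         correct = a$events$correct[i])
  })
  out <- list()
  if (spatial) {
    out$level <- a$level
    out$pattern <- as.list(a$pattern)
  } else if (!is.null(a$cues)) {
    out$cues <- as.list(a$cues)
  }
  out$passed <- a$passed
  out$events <- ev
  out
}

#' Write a trial record as canonical JSON
#'
#' The canonical form has a fixed field order and no insignificant
#' whitespace, so `write_trial_log(read_trial_log(path))` is byte-stable
#' on canonical input. Unknown fields captured in `extras` are re-emitted.
#'
#' @param trial a `trial_record`.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return the file path (invisibly) or the JSON string.
#' @export
write_trial_log <- function(trial, path = NULL) {
  stopifnot(inherits(trial, "trial_record"))
  spatial <- is_spatial_stage(trial$stage)
  obj <- list(schema_version = TRIAL_SCHEMA_VERSION,
              subject_id = trial$subject_id,
              stage = trial$stage,
              session_time = trial$session_time,
              attempts = lapply(trial$attempts, attempt_to_list, spatial))
  if (length(trial$extras)) obj <- c(obj, trial$extras)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}

known_attempt_fields <- c("level", "pattern", "cues", "passed", "events")

list_to_attempt <- function(a, spatial, idx) {
  ev <- a$events
  if (is.null(ev)) stop("attempt ", idx, ": missing field 'events'")
  evdf <- tryCatch({
    tap_events(t = vapply(ev, function(e) as.integer(e$t), integer(1)),
               action = vapply(ev, function(e) as.character(e$action),
                               character(1)),
               target = vapply(ev, function(e) as.integer(e$target),
                               integer(1)),
               correct = vapply(ev, function(e) as.logical(e$correct),
                                logical(1)))
  }, error = function(e) {
    stop("attempt ", idx, ": ", conditionMessage(e), call. = FALSE)
  })
  if (spatial) {
    if (is.null(a$level) || is.null(a$pattern)) {
      stop("attempt ", idx, ": spatial attempt requires 'level' and 'pattern'")
    }
    spatial_attempt(a$level, unlist(a$pattern), evdf, isTRUE(a$passed))
  } else {
    verbal_attempt(evdf, cues = if (!is.null(a$cues)) unlist(a$cues))
  }
}

#' Read a trial record from a JSON log
#'
#' Parses one trial-log JSON object (see `inst/extdata/trial_log.schema.json`
#' for the published schema), enforcing all structural invariants. Unknown
#' top-level fields are preserved in the record's `extras` and survive a
#' write/read round trip.
#'
#' @param path path to a trial-log JSON file, or a JSON string.
#' @return a `trial_record`.
#' @export
read_trial_log <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("subject_id", "stage", "session_time", "attempts")) {
    if (is.null(obj[[f]])) stop("trial log: missing field '", f, "'")
  }
  if (!obj$stage %in% tapmem_stages()) {
    stop("trial log: unknown stage '", obj$stage, "'")
  }
  spatial <- is_spatial_stage(obj$stage)
  attempts <- lapply(seq_along(obj$attempts), function(i) {
    list_to_attempt(obj$attempts[[i]], spatial, i)
  })
  known <- c("schema_version", "subject_id", "stage", "session_time",
             "attempts")
  extras <- obj[setdiff(names(obj), known)]
  trial_record(obj$subject_id, obj$stage, obj$session_time, attempts,
               extras = extras)
}

#' Read a subject metadata table
#'
#' CSV with header `subject_id,diagnosis,age,sdmt,edss,neurex,fss7,neurex1`;
#' empty cells are missing. Diagnoses must come from [tapmem_diagnoses()]
#' and ages must be positive.
#'
#' @param path CSV file path.
#' @return a `data.frame` of subject records.
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  need <- c("subject_id", "diagnosis", "age", "sdmt", "edss", "neurex",
            "fss7", "neurex1")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("subject table: missing columns ",
                         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$diagnosis), tapmem_diagnoses())
  if (length(bad)) stop("unknown diagnosis value(s): ",
                        paste(bad, collapse = ", "))
  if (any(!is.na(df$age) & df$age <= 0)) stop("ages must be positive")
  df
}

#' Write a subject metadata table
#'
#' @param subjects data.frame as returned by [read_subjects()].
#' @param path CSV file path.
#' @return the path, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, na = "")
  invisible(path)
}
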
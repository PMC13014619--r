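# Synthetic cohort generator. Emits tap-event trial records with the
# statistical structure the analysis assumes: shifted-exponential
# inter-tap intervals over a subject-specific motor floor, a logistic
# difficulty-accuracy link on memory capacity, an ordered impairment
# gradient HD < RR-MS < P-MS, and an SDMT score tied to the latent
# slowing parameters. Fully deterministic given (config, seed).

#' Latent profile of a simulated participant
#'
#' @param motor_floor seconds; the subject's minimal sensory-motor
#'   inter-tap interval (the quantity iSMPT estimates).
#' @param motor_jitter rate (1/seconds) of the shifted-exponential
#'   interval noise added above the floor.
#' @param cog_latency_scale seconds of additional latency per unit of
#'   cognitive demand (static demand 1, dynamic demand 2).
#' @param memory_capacity location of the logistic per-level pass
#'   probability: a subject passes level L with probability
#'   `plogis(1.4 * (memory_capacity - L))` (dynamic stages are half a
#'   level harder).
#' @param lapse_rate probability of a random error per item.
#' @param self_correct_prob probability that an erroneous tap is
#'   self-corrected (deselected and replaced).
#' @return a `latent_profile` list.
#' @export
latent_profile <- function(motor_floor, motor_jitter, cog_latency_scale,
                           memory_capacity, lapse_rate,
                           self_correct_prob) {
  stopifnot(motor_floor > 0, motor_jitter > 0, cog_latency_scale >= 0,
            lapse_rate >= 0, lapse_rate <= 1,
            self_correct_prob >= 0, self_correct_prob <= 1)
  structure(list(motor_floor = motor_floor, motor_jitter = motor_jitter,
                 cog_latency_scale = cog_latency_scale,
                 memory_capacity = memory_capacity,
                 lapse_rate = lapse_rate,
                 self_correct_prob = self_correct_prob),
            class = "latent_profile")
}

#' Group specification for cohort simulation
#'
#' Mean latent-profile values, between-subject SDs and a sampling age
#' range for one diagnostic group.
#'
#' @param label group label (`HD`, `RR-MS`, `P-MS`, `NIND`, `OIND`,
#'   `RIS/CIS`).
#' @param n subjects to draw.
#' @param means named list of latent-profile means.
#' @param sds named list of between-subject SDs (zero allowed).
#' @param age_range two-element numeric vector of years.
#' @return a `group_spec` list.
#' @export
group_spec <- function(label, n, means, sds, age_range = c(20, 75)) {
  structure(list(label = label, n = as.integer(n), means = means,
                 sds = sds, age_range = age_range),
            class = "group_spec")
}

#' Default group specifications
#'
#' The study conditions the simulator emulates: three groups of 50 on an
#' ordered impairment continuum. Healthy donors have the lowest motor
#' floor (0.24 s), the shortest cognitive latency (0.35 s/demand) and
#' the highest memory capacity (7.0 levels); relapsing-remitting MS is
#' intermediate (0.30 s, 0.55 s, 6.2); progressive MS most impaired
#' (0.40 s, 0.80 s, 5.2). Lapse rates rise along the continuum (2%, 5%,
#' 10%) and roughly a third of errors are self-corrected.
#'
#' @param n subjects per group.
#' @return list of [group_spec()]s.
#' @export
default_group_specs <- function(n = 50L) {
  list(
    group_spec("HD", n,
               means = list(motor_floor = 0.24, motor_jitter = 2.5,
                            cog_latency_scale = 0.35, memory_capacity = 7.0,
                            lapse_rate = 0.02, self_correct_prob = 0.30),
               sds = list(motor_floor = 0.05, motor_jitter = 0.3,
                          cog_latency_scale = 0.10, memory_capacity = 0.8,
                          lapse_rate = 0.01, self_correct_prob = 0.08),
               age_range = c(20, 70)),
    group_spec("RR-MS", n,
               means = list(motor_floor = 0.30, motor_jitter = 2.2,
                            cog_latency_scale = 0.55, memory_capacity = 6.2,
                            lapse_rate = 0.05, self_correct_prob = 0.30),
               sds = list(motor_floor = 0.07, motor_jitter = 0.3,
                          cog_latency_scale = 0.15, memory_capacity = 0.9,
                          lapse_rate = 0.02, self_correct_prob = 0.08),
               age_range = c(22, 75)),
    group_spec("P-MS", n,
               means = list(motor_floor = 0.40, motor_jitter = 2.0,
                            cog_latency_scale = 0.80, memory_capacity = 5.2,
                            lapse_rate = 0.10, self_correct_prob = 0.30),
               sds = list(motor_floor = 0.10, motor_jitter = 0.3,
                          cog_latency_scale = 0.20, memory_capacity = 1.0,
                          lapse_rate = 0.03, self_correct_prob = 0.08),
               age_range = c(28, 80)))
}

#' Simulation configuration
#'
#' @param groups list of [group_spec()]s.
#' @param seed mandatory integer master seed; with the config it fully
#'   determines every emitted record.
#' @param sessions_per_subject sessions to simulate per subject.
#' @param drift_sd SD of the session-to-session jitter applied to
#'   `cog_latency_scale` (independent across sessions).
#' @param sdmt_link coefficients of the SDMT link
#'   `sdmt = a - b * cog_latency_scale - c * motor_floor + noise`.
#' @param sdmt_noise_sd SD of the Gaussian SDMT noise.
#' @return a `sim_config` list.
#' @export
sim_config <- function(groups = default_group_specs(), seed,
                       sessions_per_subject = 1L, drift_sd = 0.03,
                       sdmt_link = c(a = 90, b = 40, c = 45),
                       sdmt_noise_sd = 7) {
  if (missing(seed)) stop("seed is mandatory")
  structure(list(groups = groups, seed = as.integer(seed),
                 sessions_per_subject = as.integer(sessions_per_subject),
                 drift_sd = drift_sd, sdmt_link = sdmt_link,
                 sdmt_noise_sd = sdmt_noise_sd),
            class = "sim_config")
}

rtrunc_norm <- function(n, mean, sd, lower, upper) {
  pmin(pmax(stats::rnorm(n, mean, sd), lower), upper)
}

# Map the simulator group label to a concrete diagnosis code.
draw_diagnosis <- function(label, n) {
  switch(label,
         "P-MS" = sample(c("SP-MS", "PP-MS"), n, replace = TRUE),
         "RIS/CIS" = sample(c("RIS", "CIS"), n, replace = TRUE),
         rep(label, n))
}

#' Draw a cohort of latent profiles and subject records
#'
#' @param config a [sim_config()].
#' @return list with `subjects` (metadata data.frame incl. simulated
#'   SDMT), `profiles` (data.frame of latent truths, for parameter
#'   recovery tests only) and `group` labels.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    subj <- list(); prof <- list()
    sid <- 0L
    for (g in config$groups) {
      if (g$n == 0L) next
      diag <- draw_diagnosis(g$label, g$n)
      for (i in seq_len(g$n)) {
        sid <- sid + 1L
        m <- g$means; s <- g$sds
        p <- latent_profile(
          motor_floor = rtrunc_norm(1, m$motor_floor, s$motor_floor,
                                    0.05, 2),
          motor_jitter = rtrunc_norm(1, m$motor_jitter, s$motor_jitter,
                                     0.5, 10),
          cog_latency_scale = rtrunc_norm(1, m$cog_latency_scale,
                                          s$cog_latency_scale, 0, 5),
          memory_capacity = stats::rnorm(1, m$memory_capacity,
                                         s$memory_capacity),
          lapse_rate = rtrunc_norm(1, m$lapse_rate, s$lapse_rate, 0, 0.5),
          self_correct_prob = rtrunc_norm(1, m$self_correct_prob,
                                          s$self_correct_prob, 0, 1))
        id <- sprintf("S%04d", sid)
        sdmt <- simulate_sdmt(p, link = config$sdmt_link,
                              noise_sd = config$sdmt_noise_sd)
        subj[[sid]] <- data.frame(
          subject_id = id, diagnosis = diag[i], group = g$label,
          age = round(stats::runif(1, g$age_range[1], g$age_range[2]), 1),
          sdmt = sdmt, edss = NA_real_, neurex = NA_real_,
          fss7 = NA_real_, neurex1 = NA_real_, stringsAsFactors = FALSE)
        prof[[sid]] <- data.frame(subject_id = id,
                                  as.data.frame(unclass(p)),
                                  stringsAsFactors = FALSE)
      }
    }
    list(subjects = do.call(rbind, subj), profiles = do.call(rbind, prof))
  })
}

# One shifted-exponential inter-tap interval per tap, in ms.
draw_intervals <- function(n, profile, demand) {
  sec <- profile$motor_floor + profile$cog_latency_scale * demand +
    stats::rexp(n, rate = profile$motor_jitter)
  as.integer(round(sec * 1000))
}

# Random corner-adjacent pattern: iteratively add a cell within Chebyshev
# distance 1 of the current pattern.
gen_pattern <- function(level) {
  cells <- safe_sample(0:15, 1)
  while (length(cells) < level) {
    r <- cell_row(cells); c <- cell_col(cells)
    cand <- setdiff(0:15, cells)
    ok <- vapply(cand, function(x) {
      any(pmax(abs(cell_row(x) - r), abs(cell_col(x) - c)) <= 1L)
    }, logical(1))
    cells <- c(cells, safe_sample(cand[ok], 1))
  }
  as.integer(cells)
}

# Build the event stream of one spatial attempt. Returns the events plus
# bookkeeping counts (incorrect taps, self-corrections).
sim_spatial_attempt_events <- function(profile, pattern, passed, demand,
                                       t_start) {
  level <- length(pattern)
  off <- setdiff(0:15, pattern)
  if (passed) {
    n_wrong <- stats::rbinom(1, level, profile$lapse_rate)
    n_sc <- n_wrong                      # all errors corrected, else no pass
  } else {
    lam <- max(0.3, 0.9 * (level - profile$memory_capacity))
    n_wrong <- min(level, 1L + stats::rpois(1, lam))
    n_sc <- min(stats::rbinom(1, n_wrong, profile$self_correct_prob),
                n_wrong - 1L)            # at least one error stands
  }
  wrong_pos <- safe_sample(seq_len(level), n_wrong)
  sc_pos <- safe_sample(wrong_pos, n_sc)
  wrong_cells <- safe_sample(off, n_wrong, replace = TRUE)
  act <- character(0); tgt <- integer(0); cor <- logical(0)
  wi <- 0L
  for (pos in seq_len(level)) {
    if (pos %in% wrong_pos) {
      wi <- wi + 1L
      wc <- wrong_cells[wi]
      if (pos %in% sc_pos) {             # corrected: wrong, deselect, right
        act <- c(act, "select", "deselect", "select")
        tgt <- c(tgt, wc, wc, pattern[pos])
        cor <- c(cor, FALSE, NA, TRUE)
      } else {                           # uncorrected error stands
        act <- c(act, "select"); tgt <- c(tgt, wc); cor <- c(cor, FALSE)
      }
    } else {
      act <- c(act, "select"); tgt <- c(tgt, pattern[pos])
      cor <- c(cor, TRUE)
    }
  }
  cor[is.na(cor)] <- FALSE               # deselect rows carry no correctness
  iv <- draw_intervals(length(act), profile, demand)
  t <- t_start + cumsum(as.double(iv))
  list(events = tap_events(as.integer(t), act, tgt, cor),
       n_incorrect = n_wrong, n_self_corrected = n_sc,
       t_end = t[length(t)])
}

#' Simulate one spatial test-stage trial
#'
#' Walks the 4-8 level ladder with at most 5 attempts: each attempt
#' presents a fresh corner-adjacent random pattern; the pass/fail draw is
#' logistic in (memory capacity - level), failed attempts repeat the
#' level, and inter-tap intervals are motor floor + cognitive latency
#' times demand (1 static, 2 dynamic) + exponential jitter.
#'
#' @param profile a [latent_profile()].
#' @param stage `"spatial_static"` or `"spatial_dynamic"`.
#' @param subject_id,session_time record metadata.
#' @param seed optional integer seed.
#' @return a `trial_record` with a `sim_truth` attribute holding the
#'   generator's bookkeeping (mistakes and self-corrections injected).
#' @export
simulate_spatial_session <- function(profile, stage = "spatial_static",
                                     subject_id = "sim",
                                     session_time = "2024-01-01T09:00:00Z",
                                     seed = NULL) {
  stage <- match.arg(stage, c("spatial_static", "spatial_dynamic"))
  demand <- if (stage == "spatial_dynamic") 2 else 1
  with_seed(seed, {
    attempts <- list(); truth <- list()
    level <- 4L; n_att <- 0L; t_cursor <- 0
    while (level <= 8L && n_att < 5L) {
      hard <- level + (demand - 1) * 0.5   # serial order adds difficulty
      passed <- stats::runif(1) < stats::plogis(
        1.4 * (profile$memory_capacity - hard))
      pattern <- gen_pattern(level)
      sim <- sim_spatial_attempt_events(profile, pattern, passed, demand,
                                        t_start = t_cursor + 2000)
      n_att <- n_att + 1L
      attempts[[n_att]] <- spatial_attempt(level, pattern, sim$events,
                                           passed)
      truth[[n_att]] <- data.frame(level = level, passed = passed,
                                   n_incorrect = sim$n_incorrect,
                                   n_self_corrected = sim$n_self_corrected)
      t_cursor <- sim$t_end
      if (passed) level <- level + 1L
    }
    trial <- trial_record(subject_id, stage, session_time, attempts)
    attr(trial, "sim_truth") <- do.call(rbind, truth)
    trial
  })
}

#' Simulate a verbal session (immediate + delayed recall)
#'
#' Each attempt presents 10 cues with four options; per-cue correctness
#' is Bernoulli with a capacity-linked logistic probability, attenuated
#' by 10% (on the probability scale) for the delayed stage. Errors
#' trigger repeat attempts, capped at 3.
#'
#' @param profile a [latent_profile()].
#' @param subject_id,session_time record metadata.
#' @param seed optional integer seed.
#' @return list with `immediate` and `delayed` `trial_record`s.
#' @export
simulate_verbal_session <- function(profile, subject_id = "sim",
                                    session_time = "2024-01-01T09:00:00Z",
                                    seed = NULL) {
  p_imm <- stats::plogis(1.2 * (profile$memory_capacity - 3.5)) *
    (1 - profile$lapse_rate)
  p_del <- 0.9 * p_imm
  sim_stage <- function(stage, p_correct) {
    attempts <- list(); t_cursor <- 0
    for (att in 1:3) {
      correct <- stats::runif(10) < p_correct
      iv <- draw_intervals(10, profile, demand = 1)
      t <- t_cursor + 2000 + cumsum(as.double(iv))
      ev <- tap_events(as.integer(t), rep("select", 10),
                       sample(0:3, 10, replace = TRUE), correct)
      attempts[[att]] <- verbal_attempt(ev)
      t_cursor <- t[10]
      if (all(correct)) break
    }
    trial_record(subject_id, stage, session_time, attempts)
  }
  with_seed(seed, list(immediate = sim_stage("verbal_immediate", p_imm),
                       delayed = sim_stage("verbal_delayed", p_del)))
}

#' Simulate an SDMT score from the latent profile
#'
#' `sdmt = a - b * cog_latency_scale - c * motor_floor + N(0, noise_sd)`,
#' truncated to \[0, 110\]. Ties the SDMT anchor to the same latent
#' slowing parameters that drive the tap-interval generator, so the
#' spatial biomarkers carry genuine SDMT signal.
#'
#' @param profile a [latent_profile()].
#' @param link named coefficients `a`, `b`, `c`.
#' @param noise_sd Gaussian noise SD.
#' @param seed optional integer seed.
#' @return numeric SDMT score.
#' @export
simulate_sdmt <- function(profile, link = c(a = 90, b = 40, c = 45),
                          noise_sd = 7, seed = NULL) {
  with_seed(seed, {
    x <- link[["a"]] - link[["b"]] * profile$cog_latency_scale -
      link[["c"]] * profile$motor_floor + stats::rnorm(1, 0, noise_sd)
    min(max(x, 0), 110)
  })
}

profile_from_row <- function(row) {
  latent_profile(row$motor_floor, row$motor_jitter, row$cog_latency_scale,
                 row$memory_capacity, row$lapse_rate,
                 row$self_correct_prob)
}

#' Simulate a full cohort with sessions and derived biomarkers
#'
#' Draws the cohort, simulates `sessions_per_subject` four-stage sessions
#' per subject one week apart (with session-to-session jitter on the
#' cognitive latency), and runs every trial through the biomarker
#' pipeline.
#'
#' @param config a [sim_config()].
#' @return list with `subjects`, `profiles`, `trials` (list of
#'   `trial_record`s) and `biomarkers` (one row per subject-session).
#' @export
simulate_cohort <- function(config) {
  cohort <- sample_cohort(config)
  trials <- list(); rows <- list()
  for (i in seq_len(nrow(cohort$profiles))) {
    prow <- cohort$profiles[i, ]
    base <- profile_from_row(prow)
    for (s in seq_len(config$sessions_per_subject)) {
      sseed <- child_seed(config$seed, i * 1000L + s)
      stime <- paste0(as.Date("2024-01-01") + (s - 1L) * 7L, "T09:00:00Z")
      p <- with_seed(child_seed(config$seed, i * 1000L + s + 500000L), {
        drift <- stats::rnorm(1, 0, config$drift_sd)
        latent_profile(base$motor_floor, base$motor_jitter,
                       max(0, base$cog_latency_scale + drift),
                       base$memory_capacity, base$lapse_rate,
                       base$self_correct_prob)
      })
      vb <- simulate_verbal_session(p, prow$subject_id, stime,
                                    seed = child_seed(sseed, 1))
      st <- simulate_spatial_session(p, "spatial_static", prow$subject_id,
                                     stime, seed = child_seed(sseed, 2))
      dy <- simulate_spatial_session(p, "spatial_dynamic", prow$subject_id,
                                     stime, seed = child_seed(sseed, 3))
      session <- list(vb$immediate, vb$delayed, st, dy)
      trials <- c(trials, session)
      rows[[length(rows) + 1L]] <- biomarker_vector(session)
    }
  }
  biomarkers <- do.call(rbind, rows)
  biomarkers <- merge(biomarkers,
                      cohort$subjects[c("subject_id", "diagnosis", "group",
                                        "age", "sdmt")],
                      by = "subject_id", sort = TRUE)
  list(subjects = cohort$subjects, profiles = cohort$profiles,
       trials = trials, biomarkers = biomarkers)
}

#' Write a simulated cohort to a directory
#'
#' Emits one canonical trial-log JSON per trial, a `subjects.csv`
#' metadata table, and the latent truth as `latent_truth_synthetic.csv`
#' (simulator bookkeeping for parameter-recovery tests only; never an
#' input to the analysis).
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]
    fn <- sprintf("%s_%s_%s.json", tr$subject_id,
                  gsub("[:TZ-]", "", tr$session_time), tr$stage)
    write_trial_log(tr, file.path(dir, fn))
  }
  write_subjects(cohort$subjects[setdiff(names(cohort$subjects), "group")],
                 file.path(dir, "subjects.csv"))
  utils::write.csv(cohort$profiles,
                   file.path(dir, "latent_truth_synthetic.csv"),
                   row.names = FALSE)
  invisible(dir)
}
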
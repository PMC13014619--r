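# Fixture builders used across the suite. All fixtures are constructed in
# code; nothing is read from disk.

# A spatial attempt at `level` with `n_wrong` incorrect taps (uncorrected)
# and optional self-corrected errors, starting at time `t0` ms.
fix_spatial_attempt <- function(level, n_wrong = 0L, passed = n_wrong == 0L,
                                t0 = 0L, n_selfcorr = 0L,
                                interval_ms = 500L) {
  pattern <- seq(0L, level - 1L)
  off <- setdiff(0:15, pattern)
  act <- character(0); tgt <- integer(0); cor <- logical(0)
  for (pos in seq_len(level)) {
    if (pos <= n_selfcorr) {
      act <- c(act, "select", "deselect", "select")
      tgt <- c(tgt, off[pos], off[pos], pattern[pos])
      cor <- c(cor, FALSE, FALSE, TRUE)
    } else if (pos <= n_selfcorr + n_wrong) {
      act <- c(act, "select")
      tgt <- c(tgt, off[pos])
      cor <- c(cor, FALSE)
    } else {
      act <- c(act, "select")
      tgt <- c(tgt, pattern[pos])
      cor <- c(cor, TRUE)
    }
  }
  t <- t0 + cumsum(rep(interval_ms, length(act)))
  spatial_attempt(level, pattern, tap_events(t, act, tgt, cor), passed)
}

# A spatial trial from a compact spec: list of c(level, n_wrong, passed).
fix_spatial_trial <- function(stage, specs, subject = "s1",
                              time = "2024-01-01T09:00:00Z") {
  t0 <- 0L
  attempts <- lapply(specs, function(s) {
    a <- fix_spatial_attempt(s[[1]], n_wrong = s[[2]], passed = s[[3]],
                             t0 = t0)
    t0 <<- max(a$events$t) + 2000L
    a
  })
  trial_record(subject, stage, time, attempts)
}

# A verbal trial whose first attempt has `n_correct` of 10 correct.
fix_verbal_trial <- function(n_correct = 10L, stage = "verbal_immediate",
                             interval_ms = 700L, subject = "s1") {
  cor <- rep(FALSE, 10); cor[seq_len(n_correct)] <- TRUE
  ev <- tap_events(cumsum(rep(interval_ms, 10)), rep("select", 10),
                   rep(0:3, length.out = 10), cor)
  trial_record(subject, stage, "2024-01-01T09:00:00Z",
               list(verbal_attempt(ev)))
}

# A single-attempt spatial trial with explicit inter-tap intervals (sec);
# spatial attempts carry no tap-count constraint, so the interval stream
# is exactly the one supplied.
fix_interval_trial <- function(intervals_s, stage = "spatial_static") {
  t <- as.integer(round(cumsum(c(0.5, intervals_s)) * 1000))
  n <- length(t)
  ev <- tap_events(t, rep("select", n), rep(0:3, length.out = n),
                   rep(TRUE, n))
  trial_record("s1", stage, "2024-01-01T09:00:00Z",
               list(spatial_attempt(4L, 0:3, ev, passed = TRUE)))
}

fix_profile <- function(motor_floor = 0.35, motor_jitter = 2,
                        cog = 0.4, capacity = 7, lapse = 0.05,
                        selfcorr = 0.3) {
  latent_profile(motor_floor, motor_jitter, cog, capacity, lapse, selfcorr)
}
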
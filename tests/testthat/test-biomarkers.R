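test_that("iSMPT is the minimum inter-tap interval of the trial", {
  tr <- fix_interval_trial(c(0.9, 0.45, 1.2))
  expect_equal(ismpt(tr), 0.45)
  expect_equal(ismpt(fix_interval_trial(0.7)), 0.7)
  # no attempt with >= 2 taps propagates as missing
  expect_true(is.na(ismpt(fix_interval_trial(numeric(0)))))
  # bound property: iSMPT never exceeds any interval
  set.seed(11)
  for (i in 1:20) {
    iv <- runif(sample(2:30, 1), 0.2, 2)
    tr <- fix_interval_trial(round(iv, 3))
    expect_true(all(ismpt(tr) <= unlist(inter_tap_intervals(tr)) + 1e-12))
  }
})

test_that("adjusted latency is mean interval minus iSMPT, >= 0", {
  tr <- fix_interval_trial(c(0.9, 0.45, 1.2))
  expect_equal(adjusted_latency(tr), mean(c(0.9, 0.45, 1.2)) - 0.45)
  # oracle: equals the mean of per-interval excesses over the floor
  iv <- unlist(inter_tap_intervals(tr))
  expect_equal(adjusted_latency(tr), mean(iv - min(iv)))
  # all intervals equal -> zero
  expect_equal(adjusted_latency(fix_interval_trial(c(0.8, 0.8, 0.8))), 0)
})

test_that("pure motor slowing shifts iSMPT but leaves adjusted latency fixed", {
  base <- c(0.5, 0.8, 1.1, 0.65)
  tr0 <- fix_interval_trial(base)
  tr1 <- fix_interval_trial(base + 0.25)
  expect_equal(ismpt(tr1), ismpt(tr0) + 0.25)
  expect_equal(adjusted_latency(tr1), adjusted_latency(tr0))
})

test_that("verbal recall impairment follows the inverted log10 transform", {
  expect_equal(verbal_recall_impairment(fix_verbal_trial(10)), 0)
  expect_equal(verbal_recall_impairment(fix_verbal_trial(9)), log10(11))
  expect_equal(verbal_recall_impairment(fix_verbal_trial(0)), log10(101))
  # only the first attempt counts
  first <- fix_verbal_trial(7)
  ev2 <- tap_events(max(first$attempts[[1]]$events$t) + 1:10 * 600L,
                    rep("select", 10), rep(0:3, length.out = 10),
                    rep(TRUE, 10))
  first$attempts[[2]] <- verbal_attempt(ev2)
  expect_equal(verbal_recall_impairment(first), log10(100 - 70 + 1))
})

test_that("static partial credit reproduces the worked scoring rule", {
  tr <- fix_spatial_trial("spatial_static",
                          list(list(4, 0, TRUE), list(5, 0, TRUE),
                               list(6, 3, FALSE), list(6, 1, FALSE)))
  expect_equal(static_partial_credit(tr), 13)

  flawless <- fix_spatial_trial("spatial_static",
                                lapply(4:8, function(l) list(l, 0, TRUE)))
  expect_equal(static_partial_credit(flawless), 30)

  # floor at zero when mistakes swamp the level
  floored <- fix_spatial_trial("spatial_static",
                               list(list(4, 0, TRUE), list(5, 5, FALSE),
                                    list(5, 5, FALSE)))
  expect_equal(static_partial_credit(floored), 4)
})

test_that("dynamic partial credit double-weights levels and mistakes", {
  lvl6 <- fix_spatial_trial("spatial_dynamic",
                            list(list(6, 2, FALSE)))
  expect_equal(dynamic_partial_credit(lvl6), 12 - 2 * 2)

  flawless <- fix_spatial_trial("spatial_dynamic",
                                lapply(4:8, function(l) list(l, 0, TRUE)))
  expect_equal(dynamic_partial_credit(flawless), 60)

  tr <- fix_spatial_trial("spatial_dynamic",
                          list(list(4, 0, TRUE), list(5, 1, FALSE)))
  expect_equal(dynamic_partial_credit(tr), 8 + (10 - 2))
})

test_that("partial credit is non-increasing in any attempt's mistakes", {
  score_with <- function(stage, wrongs) {
    fn <- if (stage == "spatial_static") static_partial_credit
          else dynamic_partial_credit
    fn(fix_spatial_trial(stage, list(list(4, 0, TRUE),
                                     list(6, wrongs[1], FALSE),
                                     list(6, wrongs[2], FALSE))))
  }
  for (stage in c("spatial_static", "spatial_dynamic")) {
    prev <- Inf
    for (w in 0:6) {
      cur <- score_with(stage, c(w, 1))
      expect_lte(cur, prev)
      prev <- cur
    }
  }
})

test_that("spatial recall impairment anchors flawless runs at zero", {
  expect_equal(spatial_recall_impairment(30, 30), 0)
  expect_equal(spatial_recall_impairment(13, 30), log10(18))
  expect_equal(spatial_recall_impairment(0, 60), log10(61))
  expect_error(spatial_recall_impairment(31, 30), "\\[0, max\\]")
  # monotone decreasing in the raw score
  sri <- spatial_recall_impairment(0:30, 30)
  expect_true(all(diff(sri) < 0))
})

test_that("SRM counts only self-corrected errors, log10(+1)-scaled", {
  none <- fix_spatial_trial("spatial_static", list(list(4, 2, FALSE),
                                                   list(4, 1, FALSE)))
  expect_equal(spatial_recall_mistakes(none), 0)

  t0 <- 0L
  atts <- lapply(1:3, function(i) {
    a <- fix_spatial_attempt(5, n_wrong = 1, passed = FALSE, t0 = t0,
                             n_selfcorr = 3)
    t0 <<- max(a$events$t) + 2000L
    a
  })
  tr <- trial_record("s", "spatial_static", "2024-01-01", atts)
  expect_equal(spatial_recall_mistakes(tr), log10(9 + 1))
})

test_that("all log-scaled biomarkers stay finite at the extremes", {
  expect_true(is.finite(verbal_recall_impairment(fix_verbal_trial(10))))
  expect_true(is.finite(verbal_recall_impairment(fix_verbal_trial(0))))
  expect_true(is.finite(spatial_recall_impairment(0, 60)))
  expect_true(is.finite(spatial_recall_impairment(60, 60)))
})

test_that("biomarker_vector composes stage-wise metrics, never imputing", {
  p <- fix_profile()
  vb <- simulate_verbal_session(p, seed = 4)
  st <- simulate_spatial_session(p, "spatial_static", seed = 5)
  dy <- simulate_spatial_session(p, "spatial_dynamic", seed = 6)
  full <- biomarker_vector(list(vb$immediate, vb$delayed, st, dy))
  expect_equal(sum(is.na(full[, 3:16])), 0)
  # stage-wise recomputation matches the assembled vector
  stv <- validate_trial(st)
  expect_equal(full$iSMPT_S_static, ismpt(stv))
  expect_equal(full$StaticSRLa, adjusted_latency(stv))
  expect_equal(full$StaticSRI,
               spatial_recall_impairment(static_partial_credit(stv), 30))
  expect_equal(full$StaticSRM, spatial_recall_mistakes(stv))

  verbal_only <- biomarker_vector(list(vb$immediate, vb$delayed))
  expect_equal(sum(!is.na(verbal_only[, 3:16])), 6)
  expect_false(verbal_only$valid_spatial_static)
})

test_that("quadrant stratification splits at medians with ties low", {
  # symmetric 2x2 grid: one subject per quadrant
  q <- quadrant_stratify(c(-1, -1, 1, 1), c(-1, 1, -1, 1))
  expect_equal(as.character(q), c("Q3", "Q2", "Q4", "Q1"))
  # a subject exactly at both medians lands in Q3 (ties are "low")
  q2 <- quadrant_stratify(c(0, -2, 2, 2, -2), c(0, -2, 2, -2, 2))
  expect_equal(as.character(q2)[1], "Q3")
  # high motor floor with preserved cognition is Q4 by definition
  expect_equal(as.character(q)[3], "Q4")
  expect_warning(quadrant_stratify(rep(1, 4), c(1, 2, 3, 4)), "degenerate")
})
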
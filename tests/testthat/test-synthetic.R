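test_that("the generator is fully deterministic given (config, seed)", {
  cfg <- sim_config(groups = default_group_specs(n = 4L), seed = 202)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$biomarkers, b$biomarkers)
  expect_identical(lapply(a$trials, write_trial_log),
                   lapply(b$trials, write_trial_log))
  # and sensitive to the seed
  c2 <- simulate_cohort(sim_config(groups = default_group_specs(n = 4L),
                                   seed = 203))
  expect_false(identical(a$biomarkers$iSMPT_S_static,
                         c2$biomarkers$iSMPT_S_static))
})

test_that("zero between-subject SDs put all subjects at the group means", {
  g <- default_group_specs(n = 5L)[[1]]
  g$sds <- lapply(g$sds, function(x) 0)
  cohort <- sample_cohort(sim_config(groups = list(g), seed = 5))
  expect_equal(unique(cohort$profiles$motor_floor), g$means$motor_floor)
  expect_equal(unique(cohort$profiles$memory_capacity),
               g$means$memory_capacity)
})

test_that("default groups encode the ordered impairment gradient", {
  specs <- default_group_specs()
  cog <- vapply(specs, function(g) g$means$cog_latency_scale, numeric(1))
  cap <- vapply(specs, function(g) g$means$memory_capacity, numeric(1))
  expect_true(all(diff(cog) > 0))   # HD < RR-MS < P-MS slowing
  expect_true(all(diff(cap) < 0))   # capacity declines along the continuum
})

test_that("generated trials always satisfy the event-log invariants", {
  set.seed(77)
  for (i in 1:15) {
    p <- latent_profile(runif(1, 0.1, 0.6), runif(1, 1, 4),
                        runif(1, 0.1, 1.2), runif(1, 3, 9),
                        runif(1, 0, 0.2), runif(1, 0, 1))
    st <- simulate_spatial_session(p, sample(c("spatial_static",
                                               "spatial_dynamic"), 1),
                                   seed = 1000 + i)
    # reconstruction through the strict parser must succeed unchanged
    back <- read_trial_log(write_trial_log(st))
    attr(st, "sim_truth") <- NULL
    expect_equal(back, st)
    expect_lte(length(st$attempts), 5L)
    vb <- simulate_verbal_session(p, seed = 2000 + i)
    expect_equal(read_trial_log(write_trial_log(vb$immediate)),
                 vb$immediate)
  }
})

test_that("intervals respect the motor floor and iSMPT recovers it", {
  p <- fix_profile(motor_floor = 0.4, cog = 0.2)
  tr <- simulate_spatial_session(p, "spatial_static", seed = 31)
  iv <- unlist(inter_tap_intervals(tr))
  expect_true(all(iv >= 0.4 + 0.2 - 0.001))
  # recovery: median session iSMPT within 15% of the floor (reduced scale)
  est <- vapply(1:150, function(s) {
    min(ismpt(simulate_spatial_session(fix_profile(motor_floor = 0.35),
                                       "spatial_static", seed = 3000 + s)),
        ismpt(simulate_spatial_session(fix_profile(motor_floor = 0.35),
                                       "spatial_dynamic", seed = 7000 + s)))
  }, numeric(1))
  expect_lt(abs(median(est) - (0.35 + 0.4)) / (0.35 + 0.4), 0.15)
})

test_that("capacity extremes produce flawless and floor-level trials", {
  ace <- simulate_spatial_session(fix_profile(capacity = 30, lapse = 0),
                                  "spatial_static", seed = 3)
  expect_equal(static_partial_credit(ace), 30)
  dyn <- simulate_spatial_session(fix_profile(capacity = 30, lapse = 0),
                                  "spatial_dynamic", seed = 4)
  expect_equal(dynamic_partial_credit(dyn), 60)

  dud <- simulate_spatial_session(fix_profile(capacity = -5),
                                  "spatial_static", seed = 5)
  lev <- vapply(dud$attempts, function(a) a$level, integer(1))
  expect_true(all(lev == 4L))
  expect_gte(static_partial_credit(dud), 0)
})

test_that("simulator bookkeeping matches the derived mistake biomarkers", {
  for (s in 1:10) {
    tr <- simulate_spatial_session(fix_profile(capacity = 5, lapse = 0.1,
                                               selfcorr = 0.6),
                                   "spatial_static", seed = 400 + s)
    truth <- attr(tr, "sim_truth")
    expect_equal(spatial_recall_mistakes(tr),
                 log10(sum(truth$n_self_corrected) + 1))
    # per-attempt incorrect-tap counts drive the partial credit
    mist <- vapply(tr$attempts, function(a) {
      sum(a$events$action == "select" & !a$events$correct)
    }, numeric(1))
    expect_equal(mist, truth$n_incorrect)
  }
})

test_that("delayed recall accuracy is attenuated relative to immediate", {
  p <- fix_profile(capacity = 5.5)
  acc <- vapply(1:300, function(s) {
    vb <- simulate_verbal_session(p, seed = 5000 + s)
    first_acc <- function(tr) {
      ev <- tr$attempts[[1]]$events
      mean(ev$correct[ev$action == "select"])
    }
    c(first_acc(vb$immediate), first_acc(vb$delayed))
  }, numeric(2))
  expect_gt(mean(acc[1, ]) - mean(acc[2, ]), 0.02)
})

test_that("a perfect-memory profile yields one attempt and VRI 0", {
  vb <- simulate_verbal_session(fix_profile(capacity = 30, lapse = 0),
                                seed = 9)
  expect_length(vb$immediate$attempts, 1L)
  expect_equal(verbal_recall_impairment(vb$immediate), 0)
})

test_that("SDMT links to latent slowing and degrades into noise", {
  slow <- fix_profile(motor_floor = 0.6, cog = 1.2)
  fast <- fix_profile(motor_floor = 0.2, cog = 0.2)
  s_slow <- simulate_sdmt(slow, noise_sd = 0, seed = 1)
  s_fast <- simulate_sdmt(fast, noise_sd = 0, seed = 1)
  expect_gt(s_fast, s_slow)
  # zero noise is deterministic in the latents
  expect_equal(simulate_sdmt(slow, noise_sd = 0, seed = 5),
               simulate_sdmt(slow, noise_sd = 0, seed = 6))
  expect_true(all(vapply(1:20, function(s) {
    x <- simulate_sdmt(fast, noise_sd = 50, seed = s)
    x >= 0 && x <= 110
  }, logical(1))))
})

test_that("cohort directories contain logs, metadata and marked truth", {
  cfg <- sim_config(groups = default_group_specs(n = 2L), seed = 88)
  cohort <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  files <- list.files(dir)
  expect_true("subjects.csv" %in% files)
  expect_true("latent_truth_synthetic.csv" %in% files)
  jsons <- grep("\\.json$", files, value = TRUE)
  expect_length(jsons, length(cohort$trials))
  back <- read_trial_log(file.path(dir, jsons[1]))
  expect_s3_class(back, "trial_record")
  subj <- read_subjects(file.path(dir, "subjects.csv"))
  expect_equal(nrow(subj), nrow(cohort$subjects))
})

test_that("the full pipeline recovers the injected group ordering", {
  cfg <- sim_config(groups = default_group_specs(n = 25L), seed = 99)
  cohort <- simulate_cohort(cfg)
  b <- cohort$biomarkers
  feats <- c("StaticSRLa", "DynamicSRLa", "StaticSRI", "DynamicSRI",
             "StaticSRM", "DynamicSRM")
  m <- fit_ordinal_composite(b, feats, folds = 5, seed = 12)
  sc <- composite_score(m, b)
  mu <- tapply(sc, b$group, mean)
  expect_true(mu[["HD"]] < mu[["RR-MS"]] && mu[["RR-MS"]] < mu[["P-MS"]])
})

test_that("spatial-only signal dominates a global verbal+spatial model", {
  # verbal biomarkers carry no class signal here by construction
  set.seed(314)
  n <- 120
  d <- data.frame(diagnosis = rep(c("HD", "RR-MS", "PP-MS"), each = n),
                  ImmVRLa = rnorm(3 * n), DelVRLa = rnorm(3 * n),
                  StaticSRLa = rep(c(0, 1, 2), each = n) + rnorm(3 * n),
                  DynamicSRLa = rep(c(0, 1, 2), each = n) + rnorm(3 * n))
  m <- fit_ordinal_composite(d, c("ImmVRLa", "DelVRLa", "StaticSRLa",
                                  "DynamicSRLa"), folds = 5, seed = 1)
  co <- abs(m$coefficients)
  expect_gt(min(co[c("StaticSRLa", "DynamicSRLa")]),
            max(co[c("ImmVRLa", "DelVRLa")]))
})
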
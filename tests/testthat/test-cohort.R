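test_that("cohort spec validation names the offending field", {
  expect_error(cohort_spec(n_active = 0), "n_active")
  expect_error(cohort_spec(baseline_followup_corr = 1), "baseline_followup_corr")
  expect_error(cohort_spec(rl = list(alpha_win = c(0.3, -1),
                                     alpha_loss = c(0.3, 0.8),
                                     rho_win = c(3, 0.4),
                                     rho_loss = c(3, 0.4))),
               "alpha_win")
  expect_error(cohort_spec(group_shift = c(0.2)), "group_shift")
})

test_that("population sampling is deterministic and respects parameter
           domains", {
  spec <- small_spec()
  t1 <- sample_population(spec)
  t2 <- sample_population(spec)
  expect_identical(t1, t2)
  expect_equal(nrow(t1), spec$n_active + spec$n_placebo)
  for (v in c("baseline", "followup")) {
    expect_true(all(t1[[paste0("alpha_win_", v)]] > 0 &
                      t1[[paste0("alpha_win_", v)]] < 1))
    expect_true(all(t1[[paste0("rho_loss_", v)]] > 0))
    for (cond in c("control", "positive", "aversive")) {
      expect_true(all(t1[[paste0("z_", cond, "_", v)]] > 0 &
                        t1[[paste0("z_", cond, "_", v)]] < 1))
      expect_true(all(t1[[paste0("a_", cond, "_", v)]] > 0))
    }
  }
})

test_that("a null group shift leaves follow-up distributions matched and the
           injected shift moves only the active group's targets", {
  null_spec <- cohort_spec(n_active = 400, n_placebo = 400,
                           group_shift = numeric(0), seed = 5)
  tr <- sample_population(null_spec)
  act <- tr$group == "active"
  expect_equal(mean(log(tr$rho_loss_followup[act])),
               mean(log(tr$rho_loss_followup[!act])), tolerance = 0.1)
  shift_spec <- cohort_spec(n_active = 400, n_placebo = 400,
                            group_shift = c(rho_loss = -0.4,
                                            z_aversive = -0.5), seed = 5)
  ts <- sample_population(shift_spec)
  expect_equal(mean(log(ts$rho_loss_followup[act])) -
                 mean(log(ts$rho_loss_followup[!act])), -0.4,
               tolerance = 0.08)
  # placebo follow-up and all baselines are untouched by the shift
  expect_equal(ts$rho_loss_baseline, tr$rho_loss_baseline)
  expect_equal(ts$rho_loss_followup[!act], tr$rho_loss_followup[!act])
  # z shifted in the aversive condition only
  expect_equal(mean(qlogis(ts$z_aversive_followup[act])) -
                 mean(qlogis(tr$z_aversive_followup[act])), -0.5,
               tolerance = 1e-10)
  expect_equal(ts$z_control_followup, tr$z_control_followup)
})

test_that("cross-visit correlation is controlled by the spec", {
  spec <- cohort_spec(n_active = 250, n_placebo = 250,
                      baseline_followup_corr = 0.99,
                      group_shift = numeric(0), seed = 6)
  tr <- sample_population(spec)
  expect_gt(cor(qlogis(tr$alpha_win_baseline), qlogis(tr$alpha_win_followup)),
            0.9)
  expect_gt(cor(log(tr$rho_loss_baseline), log(tr$rho_loss_followup)), 0.9)
  lo <- cohort_spec(n_active = 250, n_placebo = 250,
                    baseline_followup_corr = 0, group_shift = numeric(0),
                    seed = 6)
  tl <- sample_population(lo)
  expect_lt(abs(cor(log(tl$rho_loss_baseline), log(tl$rho_loss_followup))),
            0.15)
})

test_that("learning-task tables have the design dimensions and outcome
           domains", {
  spec <- small_spec()
  truth <- sample_population(spec)
  trials <- generate_pilt(truth[1:2, ])
  one <- trials[trials$subject == truth$subject[1] &
                  trials$visit == "baseline", ]
  expect_equal(nrow(one), 180L)
  expect_equal(sum(one$condition == "win"), 90L)
  expect_equal(sum(one$condition == "loss"), 90L)
  expect_equal(sort(unique(one$block)), 1:3)
  expect_true(all(one$outcome[one$condition == "win"] %in% c(0, 1)))
  expect_true(all(one$outcome[one$condition == "loss"] %in% c(-1, 0)))
  expect_identical(generate_pilt(truth[1:2, ]), trials)
})

test_that("favourable outcomes follow the 70/30 reciprocal schedule", {
  spec <- cohort_spec(n_active = 15, n_placebo = 15, seed = 8)
  truth <- sample_population(spec)
  trials <- generate_pilt(truth)
  win_high <- trials[trials$condition == "win" & trials$choice == "high", ]
  expect_equal(mean(win_high$outcome == 1), 0.7, tolerance = 0.02)
  loss_high <- trials[trials$condition == "loss" & trials$choice == "high", ]
  expect_equal(mean(loss_high$outcome == 0), 0.7, tolerance = 0.02)
  win_low <- trials[trials$condition == "win" & trials$choice == "low", ]
  expect_lt(abs(mean(win_low$outcome == 1) - 0.3), 0.02)
})

test_that("go/no-go tables have the design dimensions and censoring contract", {
  spec <- small_spec()
  truth <- sample_population(spec)
  trials <- generate_gng(truth[1:2, ])
  one <- trials[trials$subject == truth$subject[1] &
                  trials$visit == "followup", ]
  expect_equal(nrow(one), 480L)
  expect_equal(sum(one$trial_type == "nogo"), 96L)
  expect_equal(as.integer(table(one$condition)), rep(160L, 3))
  rts <- one$rt_ms[!is.na(one$rt_ms)]
  expect_true(all(rts <= 400 + 1e-6))
  ters <- unlist(truth[1, grep("^ter_.*_followup$", names(truth))])
  expect_true(all(rts >= 1000 * min(ters)))
  expect_true(all(is.na(one$rt_ms[one$response == "none"])))
  expect_true(all(one$correct == ((one$trial_type == "go" &
                                     one$response == "press") |
                                    (one$trial_type == "nogo" &
                                       one$response == "none"))))
})

test_that("a no-go-ward start-point shift slows aversive go responses", {
  spec <- cohort_spec(n_active = 40, n_placebo = 10,
                      group_shift = c(z_aversive = -0.8), seed = 12)
  truth <- sample_population(spec)
  act <- truth[truth$group == "active", ]
  trials <- generate_gng(act)
  fu <- trials[trials$visit == "followup" & trials$trial_type == "go" &
                 trials$response == "press", ]
  rt_av <- mean(fu$rt_ms[fu$condition == "aversive"])
  rt_ct <- mean(fu$rt_ms[fu$condition == "control"])
  expect_gt(rt_av, rt_ct)
})

test_that("summary outcome tables respect the instrument ranges", {
  spec <- small_spec()
  truth <- sample_population(spec)
  so <- generate_summary_outcomes(truth, spec)
  avlt <- so$outcomes[so$outcomes$outcome == "avlt_recall", ]
  expect_true(all(avlt$value >= 0 & avlt$value <= 15))
  expect_setequal(unique(avlt$condition),
                  c(paste0("learning", 1:5), "distraction",
                    "delayed1", "delayed2"))
  nb <- so$outcomes[so$outcomes$outcome == "nback_correct", ]
  expect_setequal(unique(nb$condition), paste0("load", 0:3))
  expect_true(all(nb$value >= 0 & nb$value <= 40))
  expect_equal(sort(unique(so$daily$day)), seq_len(spec$n_days))
})

test_that("cohort tables survive a write/read round trip losslessly", {
  spec <- small_spec()
  cohort <- simulate_cohort(spec, tasks = "pilt")
  dir <- tempfile("cohort")
  paths <- write_cohort(cohort["pilt"], dir)
  back <- read_trial_table(paths[["pilt"]])
  expect_equal(back, cohort$pilt, tolerance = 1e-12)
})
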
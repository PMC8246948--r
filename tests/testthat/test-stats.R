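# a moderate truth-contour session shared by the model tests
stats_run <- local({
  cfg <- pipeline_config(n_participants = 12, trials_per_condition = 2,
                         master_seed = 29, use_truth_contours = TRUE,
                         fit_smooths = FALSE)
  quietly(run_all(cfg))
})

test_that("condition contrasts recover the injected ordering and sex gap", {
  ce <- stats_run$models$condition_env
  est <- ce$estimates
  b_w <- est$b[est$term == "conditionwrist"]
  b_a <- est$b[est$term == "conditionarm"]
  expect_gt(b_w, 0)
  expect_gt(b_a, b_w)
  expect_true(all(est$se > 0))
  expect_true(all(est$p >= 0 & est$p <= 1))
  cf <- stats_run$models$condition_f0
  sex <- cf$estimates[cf$estimates$term == "sexmale", ]
  expect_lt(abs(sex$b - (-73)), 2 * sex$se + 2 * 15 / sqrt(12))
  # refitting the same data reproduces the estimates exactly
  ce2 <- quietly(fit_condition_effects(stats_run$trial_summaries, "env_z"))
  expect_equal(ce$estimates$b, ce2$estimates$b, tolerance = 1e-8)
  expect_error(fit_condition_effects(
    stats_run$trial_summaries[stats_run$trial_summaries$condition == "arm", ], "env_z"),
    "2 conditions")
})

test_that("switching the reference level relabels contrasts but not fitted values", {
  ce <- stats_run$models$condition_env
  d <- ce$fit@frame
  d$condition <- stats::relevel(d$condition, ref = "arm")
  refit <- quietly(lmerTest::lmer(formula(ce$fit), data = d))
  expect_equal(unname(fitted(refit)), unname(fitted(ce$fit)), tolerance = 1e-8)
  est2 <- summary(refit)$coefficients
  b_wp <- ce$estimates$b[ce$estimates$term == "conditionarm"]
  expect_equal(unname(est2["conditionpassive", "Estimate"]), -b_wp, tolerance = 1e-6)
})

test_that("trajectory smooths return per-condition fits and difference peaks", {
  edf <- as_epochs_df(stats_run$epochs)
  sm <- quietly(fit_trajectory_smooths(edf, "env", k = 12))
  expect_s3_class(sm, "gs_trajectory_smooths")
  expect_equal(sm$reference, "surrogate")
  expect_setequal(unique(sm$fitted$condition), unique(edf$condition))
  expect_equal(sort(unique(sm$fitted$rel_t_ms)), sort(unique(edf$rel_t_ms)))
  expect_true(all(sm$difference$peak_rel_t_ms >= -400 & sm$difference$peak_rel_t_ms <= 400))
  expect_true(all(sm$smooth_tests[["p-value"]] >= 0 & sm$smooth_tests[["p-value"]] <= 1))
  # arm sits above wrist in the parametric condition effects (injected ordering)
  pa <- sm$parametric
  expect_gt(pa$b[pa$term == "conditionarm"], pa$b[pa$term == "conditionwrist"])
  # too few epochs per condition is an error
  tiny <- edf[edf$cycle_index <= 2 & edf$trial_id == edf$trial_id[1], ]
  expect_error(fit_trajectory_smooths(rbind(tiny), "env"), "fewer than 10")
})

test_that("deceleration models recover constructed slopes and interactions", {
  set.seed(91)
  n_pp <- 10; n_tr <- 8
  d <- expand.grid(participant_id = sprintf("P%02d", 1:n_pp), trial = 1:n_tr,
                   condition = c("wrist", "arm"), stringsAsFactors = FALSE)
  d$trial_id <- paste0("T", seq_len(nrow(d)))
  base_decel <- ifelse(d$condition == "arm", 5000, 2500)
  d$max_decel <- rnorm(nrow(d), base_decel, 900)
  intercepts <- rnorm(n_pp, 0, 0.2)
  names(intercepts) <- sprintf("P%02d", 1:n_pp)
  beta_env <- 4e-5
  d$max_env <- 0.5 + intercepts[d$participant_id] + beta_env * d$max_decel +
    rnorm(nrow(d), 0, 0.08)
  # F0 coupling only in the arm condition
  beta_f0 <- 3e-4
  d$max_f0 <- 1 + intercepts[d$participant_id] +
    ifelse(d$condition == "arm", beta_f0 * d$max_decel, 0) + rnorm(nrow(d), 0, 0.3)
  fit <- quietly(fit_deceleration_effects(d))
  env_slope <- fit$env$estimates[fit$env$estimates$term == "decel_s", ]
  # slope is reported per SD of deceleration
  expect_lt(abs(env_slope$b - beta_env * fit$decel_scale["sd"]), 2 * env_slope$se)
  expect_lt(env_slope$p, 0.05)
  inter <- fit$f0$estimates[fit$f0$estimates$term == "conditionarm:decel_s", ]
  expect_gt(inter$b, 0)
  expect_lt(inter$p, 0.05)
  expect_true(all(fit$env$estimates$se > 0) && all(fit$f0$estimates$se > 0))
  expect_error(quietly(fit_deceleration_effects(d[d$condition == "wrist", ])),
               "both movement conditions")
})
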
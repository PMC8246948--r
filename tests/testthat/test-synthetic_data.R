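kp_pure <- kinematics_params(freq_sd = 0, beat_sharpness = 1,
                             amp_trial_cv = 0, amp_cycle_cv = 0,
                             sensor_noise_sd_cm = 0)

test_that("the sharpness-1 noiseless generator is a pure sinusoid", {
  g <- generate_kinematics(kp_pure, "wrist", 60, seed = 5)
  kin <- smooth_and_differentiate(g$motion)
  interior <- kin$t > 2 & kin$t < 58
  expect_equal(max(abs(kin$a[interior])), 10 * (2 * pi * 4 / 3)^2, tolerance = 0.02)
  # 60 s at 1.33 Hz: number of beats within 1 of 79.8
  expect_lte(abs(length(g$truth$beat_times) - 79.8), 1)
  # beat times sit at the position minima
  z_at_beats <- approx(g$motion$t, g$motion$z, xout = g$truth$beat_times)$y
  expect_lt(max(z_at_beats), -9.9)
})

test_that("larger strokes produce larger decelerations, sharper beats sharper stops", {
  ga <- generate_kinematics(kinematics_params(), "arm", 30, seed = 7)
  gw <- generate_kinematics(kinematics_params(), "wrist", 30, seed = 7)
  expect_gt(mean(ga$truth$max_decel_values), mean(gw$truth$max_decel_values))
  # phase-warped beat exceeds the equal-amplitude sinusoid's deceleration
  g1 <- generate_kinematics(kp_pure, "wrist", 30, seed = 9)
  kp2 <- kinematics_params(freq_sd = 0, beat_sharpness = 2, amp_trial_cv = 0,
                           amp_cycle_cv = 0, sensor_noise_sd_cm = 0)
  g2 <- generate_kinematics(kp2, "wrist", 30, seed = 9)
  expect_gt(mean(g2$truth$max_decel_values), mean(g1$truth$max_decel_values))
  expect_error(kinematics_params(beat_sharpness = 0.5), "beat_sharpness")
})

test_that("injected bump heights equal mass_factor x beta x deceleration exactly", {
  cp <- coupling_params()
  truth <- list(beat_times = c(2, 4, 6), max_decel_values = rep(3000, 3),
                decel_onset_times = c(1.8, 3.8, 5.8))
  tr <- generate_speech_tracks(speaker_params("female"), cp, truth, "arm", 10, seed = 2)
  expect_equal(tr$injected_bump_gains_env,
               rep(cp$mass_factor[["arm"]] * cp$beta_env * 3000, 3))
  expect_equal(tr$injected_bump_gains_f0,
               rep(cp$mass_factor[["arm"]] * cp$beta_f0[["arm"]] * 3000, 3))
  # passive trials must not carry beats
  expect_error(generate_speech_tracks(speaker_params("female"), cp, truth,
                                      "passive", 10, seed = 2), "passive")
  expect_error(coupling_params(bump_center_offset_ms = -600), "bump_center")
  expect_error(coupling_params(mass_factor = c(passive = 0, wrist = 2, arm = 1)),
               "mass_factor")
})

test_that("zero coupling leaves no beat-locked envelope structure; gain is monotone", {
  cp0 <- coupling_params(beta_env = 0, beta_f0 = c(passive = 0, wrist = 0, arm = 0),
                         env_offset = c(passive = 0, wrist = 0, arm = 0),
                         f0_offset = c(passive = 0, wrist = 0, arm = 0))
  g <- generate_kinematics(kinematics_params(), "arm", 120, seed = 31)
  peak_dev <- function(cp, seed_sp = 32) {
    tr <- generate_speech_tracks(speaker_params("female"), cp, g$truth, "arm",
                                 120, seed = seed_sp)
    env <- make_env_track(tr$true_env)
    beats <- data.frame(t_ext = g$truth$beat_times,
                        cycle_index = seq_along(g$truth$beat_times))
    ep <- extract_epochs(beats, env, NULL)
    m <- rowMeans(ep$env)
    se <- apply(ep$env, 1, sd) / sqrt(ncol(ep$env))
    i <- which.max(abs(m - mean(m)))
    c(dev = abs(m[i] - mean(m)), se = se[i], peak = max(m) - mean(m))
  }
  null_stat <- peak_dev(cp0)
  expect_lt(null_stat["dev"], 3 * null_stat["se"])
  # increasing beta_env strictly increases the beat-locked peak (same seeds)
  peaks <- sapply(c(1e-5, 3e-5, 6e-5), function(b) {
    peak_dev(coupling_params(beta_env = b))["peak"]
  })
  expect_true(all(diff(peaks) > 0))
})

test_that("voiced-run durations give trial speech rates near 6 Hz", {
  tr <- generate_speech_tracks(speaker_params("female"), coupling_params(),
                               NULL, "passive", 60, seed = 12)
  f0 <- make_f0_track(tr$voiced_intervals, 60)
  events <- segment_vocalizations(f0, NULL)
  rate <- 1000 / mean(events$duration_ms)
  expect_gt(rate, 5); expect_lt(rate, 8)
})

test_that("sessions are deterministic in the master seed and have the right layout", {
  s1 <- generate_session(2, trials_per_condition = 1, master_seed = 77,
                         duration_mean_s = 8, duration_sd_s = 0, render = FALSE)
  s2 <- generate_session(2, trials_per_condition = 1, master_seed = 77,
                         duration_mean_s = 8, duration_sd_s = 0, render = FALSE)
  expect_identical(s1$manifest, s2$manifest)
  k <- names(s1$trials)[1]
  expect_identical(s1$trials[[k]]$truth$true_env, s2$trials[[k]]$truth$true_env)
  expect_equal(nrow(s1$manifest), 2 * 1 * 3)
  expect_equal(unname(table(s1$manifest$condition)["passive"]), 2, ignore_attr = TRUE)
  # a different seed changes the data
  s3 <- generate_session(2, trials_per_condition = 1, master_seed = 78,
                         duration_mean_s = 8, duration_sd_s = 0, render = FALSE)
  expect_false(identical(s1$trials[[k]]$truth$true_env, s3$trials[[k]]$truth$true_env))
})

test_that("trial durations center on the instructed retelling length", {
  s <- generate_session(6, trials_per_condition = 3, master_seed = 41, render = FALSE)
  durs <- vapply(s$trials, `[[`, numeric(1), "duration_s")
  expect_equal(length(durs), 54)
  expect_lt(abs(mean(durs) - 26), 2)
})

test_that("ground-truth invariants hold across seeds", {
  cp <- coupling_params()
  for (seed in 1:20) {
    cond <- if (seed %% 2) "arm" else "wrist"
    g <- generate_kinematics(kinematics_params(), cond, 8, seed = seed)
    expect_true(all(diff(g$truth$beat_times) > 0))
    expect_true(all(g$truth$max_decel_values >= 0))
    expect_true(all(g$truth$decel_onset_times < g$truth$beat_times))
    tr <- generate_speech_tracks(speaker_params("female"), cp, g$truth, cond,
                                 8, seed = seed + 1000)
    expect_equal(tr$injected_bump_gains_env,
                 cp$mass_factor[[cond]] * cp$beta_env * tr$max_decel_values)
    # F0 is defined exactly on the voiced set
    voiced <- rep(FALSE, length(tr$t))
    for (i in seq_len(nrow(tr$voiced_intervals))) {
      voiced[tr$t >= tr$voiced_intervals[i, 1] & tr$t < tr$voiced_intervals[i, 2]] <- TRUE
    }
    expect_identical(!is.na(tr$true_f0), voiced)
  }
})

test_that("rendering rejects out-of-range F0 and silent trials track as unvoiced", {
  truth <- list(t = (0:2399) / 240, true_f0 = rep(2000, 2400),
                true_env = rep(0.5, 2400))
  expect_error(render_audio(truth, fs = 16000), "range")
  silent <- list(t = (0:2399) / 240, true_f0 = rep(NA_real_, 2400),
                 true_env = rep(0.005, 2400))
  au <- render_audio(silent, fs = 16000, seed = 3)
  f0 <- track_f0(au, "female")
  expect_equal(sum(!is.na(f0$f0)), 0)
})
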
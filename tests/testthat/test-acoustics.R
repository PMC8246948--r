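test_that("envelope of constant-amplitude tones, silence, and homogeneity", {
  env <- compute_envelope(make_tone(440, dur = 1, amp = 0.5))
  interior <- env$t > 0.15 & env$t < 0.85
  expect_true(all(abs(env$env[interior] - 0.5) < 0.01))   # 2% of amplitude
  # silence maps to zero
  z <- compute_envelope(audio_track(numeric(4410) + 0, fs = 44100))
  expect_true(all(z$env < 1e-12))
  # positive homogeneity: envelope(a x) = a envelope(x)
  a <- make_tone(300, dur = 0.5, amp = 0.2)
  e1 <- compute_envelope(a)
  a3 <- audio_track(3 * a$samples, a$fs)
  e3 <- compute_envelope(a3)
  expect_equal(e3$env, 3 * e1$env, tolerance = 1e-10)
  expect_error(audio_track(numeric(0)), "at least one sample")
  expect_error(compute_envelope(make_tone(220, dur = 0.5, fs = 4000)), "8 kHz")
})

test_that("envelope tracks a slow amplitude modulator", {
  fs <- 44100
  tt <- (0:(2 * fs - 1)) / fs
  mod <- 0.5 * (1 - cos(2 * pi * 2 * tt)) / 2 + 0.05   # 2-Hz raised cosine
  env <- compute_envelope(audio_track(mod * sin(2 * pi * 440 * tt), fs))
  mod240 <- approx(tt, mod, xout = env$t)$y
  interior <- env$t > 0.2 & env$t < 1.8
  expect_gt(cor(env$env[interior], mod240[interior]), 0.99)
})

test_that("F0 tracking recovers known tones and respects range and voicing", {
  f0 <- track_f0(make_harmonic(200, dur = 2), "female")
  expect_lt(abs(median(f0$f0, na.rm = TRUE) - 200), 2)
  expect_gt(mean(!is.na(f0$f0)), 0.9)
  # no frame-to-frame octave jumps inside voiced runs
  v <- f0$f0[!is.na(f0$f0)]
  expect_true(all(abs(diff(v) / v[-length(v)]) <= 0.4))
  # low-level white noise: no voiced frames
  set.seed(4)
  noise <- audio_track(rnorm(44100) * 0.01, 44100)
  expect_equal(sum(!is.na(track_f0(noise, "female")$f0)), 0)
  # tone below the female range floor is not tracked
  expect_equal(sum(!is.na(track_f0(make_harmonic(60, dur = 1), "female")$f0)), 0)
  expect_error(track_f0(make_harmonic(200), "child"), "sex")
})

test_that("vocalization segmentation partitions the voiced set", {
  spans <- rbind(c(0, 0.2), c(0.5, 0.8))
  f0 <- make_f0_track(spans, dur = 1)
  env_v <- rep(0.1, nrow(f0))
  env_v[round(0.10 * 240) + 1] <- 1        # peaks at 0.10 s and 0.60 s
  env_v[round(0.60 * 240) + 1] <- 1.2
  env <- make_env_track(env_v)
  ev <- segment_vocalizations(f0, env)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$duration_ms, c(200, 300), tolerance = 1e-6)
  expect_equal(ev$peak_env_time, c(0.10, 0.60), tolerance = 1e-6)
  sm <- trial_acoustic_summary(ev, f0, env)
  expect_equal(sm$voc_interval_hz, 1000 / 500, tolerance = 1e-6)

  # a single voiced frame is one event of one grid step
  f1 <- make_f0_track(rbind(c(0.5, 0.5 + 1 / 240)), dur = 1)
  ev1 <- segment_vocalizations(f1, NULL)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$duration_ms, 1000 / 240, tolerance = 1e-6)

  # gap merging: 20-ms gap < 50-ms threshold merges runs
  f2 <- make_f0_track(rbind(c(0, 0.2), c(0.22, 0.4)), dur = 1)
  expect_equal(nrow(segment_vocalizations(f2, NULL, min_gap_ms = 0)), 2)
  expect_equal(nrow(segment_vocalizations(f2, NULL, min_gap_ms = 50)), 1)

  # property: events are disjoint, ordered, and cover the voiced set
  set.seed(11)
  for (i in 1:10) {
    ft <- make_f0_track(matrix(numeric(0), 0, 2), dur = 2)
    voiced <- rbinom(nrow(ft), 1, 0.4) == 1
    ft$f0[voiced] <- 150
    ev <- segment_vocalizations(ft, NULL)
    dt <- 1 / 240
    frames <- unlist(lapply(seq_len(nrow(ev)), function(j) {
      seq(round(ev$onset[j] * 240), length.out = round(ev$duration_ms[j] / 1000 * 240))
    }))
    expect_identical(as.integer(sort(frames)) + 1L, which(voiced))
    expect_true(all(diff(ev$onset) > 0))
    expect_true(all(ev$offset[-nrow(ev)] < ev$onset[-1] + 1e-9))
  }
})

test_that("trial summaries convert rates and flag degenerate scaling", {
  f0 <- make_f0_track(rbind(c(0, 0.2)), dur = 1)
  env <- make_env_track(rep(0.3, nrow(f0)))
  ev <- data.frame(onset = c(0, 0.5), offset = c(0.2, 0.7),
                   duration_ms = c(200, 200), peak_env_time = c(0.1, 0.6),
                   peak_env_value = c(1, 1), max_f0 = c(200, 210))
  sm <- trial_acoustic_summary(ev, f0, env)
  expect_equal(sm$voc_duration_hz, 5)
  expect_equal(sm$n_events, 2)
  # no events: rates are missing, not zero
  sm0 <- trial_acoustic_summary(ev[0, ], f0, env)
  expect_true(is.na(sm0$voc_duration_hz) && is.na(sm0$voc_interval_hz))
  # a participant with zero envelope variance cannot be z-scaled
  expect_error(trial_acoustic_summary(ev, f0, env,
                                      participant_env_stats = list(mean = 0.3, sd = 0)),
               "z-scale|degenerate")
})

test_that("rendered speech audio is recovered end to end", {
  kp <- kinematics_params()
  g <- generate_kinematics(kp, "arm", 12, seed = 21)
  tr <- generate_speech_tracks(speaker_params("female"), coupling_params(),
                               g$truth, "arm", 12, seed = 22)
  au <- render_audio(tr, fs = 16000, seed = 23)
  env <- compute_envelope(au)
  f0 <- track_f0(au, "female")
  n <- min(nrow(env), length(tr$true_env))
  sm_truth <- smooth_truth_envelope(tr$true_env)[1:n]
  ok <- !is.na(sm_truth)
  expect_gt(cor(env$env[1:n][ok], sm_truth[ok]), 0.95)
  both <- !is.na(f0$f0[1:n]) & !is.na(tr$true_f0[1:n])
  rmse <- sqrt(mean((f0$f0[1:n][both] - tr$true_f0[1:n][both])^2))
  expect_lt(rmse, 3)
})
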
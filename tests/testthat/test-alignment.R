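test_that("epochs live on an exact shared 193-sample grid with edge skipping", {
  env <- make_env_track(rep(0.7, 20 * 240 + 1))
  beats <- data.frame(t_ext = c(0.2, 10.0, 19.9), cycle_index = 1:3)
  ep <- extract_epochs(beats, env)
  expect_equal(length(ep$rel_t_ms), 193)
  expect_equal(ncol(ep$env), 1)              # 0.2 s and 19.9 s are skipped
  expect_equal(ep$n_skipped, 2)
  expect_true(all(ep$env == 0.7))
  # the epoch spans [9.6, 10.4] s on the track grid
  i0 <- round(10.0 * 240) + 1
  expect_equal(env$t[i0 - 96], 9.6, tolerance = 1e-9)
  expect_equal(env$t[i0 + 96], 10.4, tolerance = 1e-9)
  # grids are bitwise identical across independently built epoch sets
  ep2 <- extract_epochs(data.frame(t_ext = 5, cycle_index = 1), env)
  expect_identical(ep$rel_t_ms, ep2$rel_t_ms)
  expect_identical(ep$rel_t_ms, epoch_rel_grid_ms())
})

test_that("surrogate pairing is deterministic, within participant, movement donors only", {
  idx <- data.frame(participant_id = rep(c("P1", "P2"), each = 4),
                    trial_id = rep(paste0("T", 1:4), 2),
                    condition = rep(c("passive", "passive", "wrist", "arm"), 2))
  p1 <- build_surrogate_pairing(idx, pairing_seed = 9)
  p2 <- build_surrogate_pairing(idx, pairing_seed = 9)
  expect_identical(p1, p2)
  expect_true(all(p1$donor_condition %in% c("wrist", "arm")))
  expect_equal(nrow(p1), 4)                  # one pair per passive trial
  merged <- merge(p1, idx, by.x = c("participant_id", "donor_trial_id"),
                  by.y = c("participant_id", "trial_id"))
  expect_equal(nrow(merged), 4)              # donors exist within participant
  # no participant with both conditions -> error
  expect_error(build_surrogate_pairing(idx[idx$condition == "passive", ]),
               "passive and a movement")
})

test_that("surrogate epochs reuse the speech trial's samples under the edge rule", {
  # donor movement of 30 s paired with 20-s speech: only beats < 19.6 s usable
  donor_beats <- data.frame(t_ext = seq(1, 29, by = 0.75),
                            cycle_index = seq_along(seq(1, 29, by = 0.75)))
  set.seed(2)
  env_vals <- runif(20 * 240 + 1)
  env <- make_env_track(env_vals)
  ep <- extract_epochs(donor_beats, env)
  expect_equal(ncol(ep$env), sum(donor_beats$t_ext >= 0.4 & donor_beats$t_ext <= 19.6))
  # marginals preserved: every epoch sample is a sample of the speech trial
  expect_true(all(ep$env %in% env_vals))
})

test_that("deceleration-window features follow the closed overlap rules", {
  env <- make_env_track(rep(0.2, 10 * 240 + 1))
  env$env[env$t >= 4.85 & env$t <= 4.95] <- seq(0.3, 1.1,
                                                length.out = sum(env$t >= 4.85 & env$t <= 4.95))
  f0 <- make_f0_track(rbind(c(4.85, 4.95), c(5.05, 5.30)), dur = 10, f0_hz = 220)
  beats <- data.frame(t_ext = 5.0, cycle_index = 1, t_decel_onset = 4.8,
                      max_decel = 900, valid = TRUE)
  ev <- segment_vocalizations(f0, env)
  obs <- impulse_window_features(beats, ev, env, f0)
  # only the vocalization inside [4.8, 5.0] contributes
  expect_equal(nrow(obs), 1)
  expect_equal(obs$max_decel, 900)
  expect_equal(obs$max_env, max(env$env[env$t >= 4.85 & env$t < 4.95]))
  expect_equal(obs$max_f0, 220)
  # two vocalizations overlapping one window both contribute
  f0b <- make_f0_track(rbind(c(4.82, 4.88), c(4.90, 4.96)), dur = 10)
  evb <- segment_vocalizations(f0b, env)
  expect_equal(nrow(impulse_window_features(beats, evb, env, f0b)), 2)
  # aggregation averages within trial
  obs$participant_id <- "P1"; obs$trial_id <- "T1"; obs$condition <- "arm"
  tm <- aggregate_impulse_observations(obs)
  expect_equal(tm$n_obs, 1)
  expect_equal(tm$max_decel, 900)
})

test_that("coupled sessions show deceleration scaling; trajectories peak before extension", {
  cfg <- pipeline_config(n_participants = 8, trials_per_condition = 2, master_seed = 19,
                         use_truth_contours = TRUE, fit_smooths = FALSE)
  run <- quietly(run_all(cfg))
  tm <- run$impulse_trial_means
  mv <- tm[tm$condition %in% c("wrist", "arm"), ]
  expect_gt(cor(mv$max_decel, mv$max_env, method = "spearman"), 0)
  # pooled mean envelope trajectory peaks inside the deceleration window
  traj <- run$trajectory_means$pooled
  for (cc in c("wrist", "arm")) {
    s <- traj[traj$condition == cc, ]
    pk <- s$rel_t_ms[which.max(s$mean)]
    expect_gte(pk, -200); expect_lte(pk, 0)
  }
})

test_that("under zero coupling, real and surrogate peak statistics agree", {
  cp0 <- coupling_params(beta_env = 0, beta_f0 = c(passive = 0, wrist = 0, arm = 0),
                         env_offset = c(passive = 0, wrist = 0, arm = 0),
                         f0_offset = c(passive = 0, wrist = 0, arm = 0))
  cfg <- pipeline_config(n_participants = 12, trials_per_condition = 2, master_seed = 23,
                         cp = cp0, use_truth_contours = TRUE, fit_smooths = FALSE)
  run <- quietly(run_all(cfg))
  ep <- run$epochs
  key <- interaction(ep$meta$participant_id, ep$meta$trial_id, ep$meta$condition)
  peak_stat <- sapply(levels(key), function(k) {
    cols <- which(key == k)
    if (!length(cols)) return(NA_real_)
    m <- rowMeans(ep$env[, cols, drop = FALSE])
    max(m) - mean(m)
  })
  is_surr <- grepl("surrogate$", levels(key))
  real <- peak_stat[!is_surr & !is.na(peak_stat)]
  surr <- peak_stat[is_surr & !is.na(peak_stat)]
  expect_gt(stats::wilcox.test(real, surr)$p.value, 0.01)
})
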
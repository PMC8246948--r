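# End-to-end orchestration: generate (or load) a session, extract acoustic
# and kinematic signals, epoch, build the surrogate baseline, and fit the
# statistical models, as one reproducible run.

track_from_truth <- function(truth) {
  # the envelope is by definition a 5-Hz-smoothed quantity, so the ideal
  # (extraction-free) envelope track is the smoothed truth contour
  env_sm <- smooth_truth_envelope(truth$true_env)
  env_sm[is.na(env_sm)] <- truth$true_env[is.na(env_sm)]
  env <- data.frame(t = truth$t, env = env_sm)
  attr(env, "fs") <- 240; class(env) <- c("envelope_track", "data.frame")
  f0 <- data.frame(t = truth$t, f0 = truth$true_f0)
  attr(f0, "fs") <- 240; class(f0) <- c("f0_track", "data.frame")
  list(env = env, f0 = f0)
}

zscale_track <- function(env, stats) {
  env$env <- (env$env - stats$mean) / stats$sd
  env
}

#' Run configuration for the full pipeline
#'
#' Collects every tunable of the pipeline with its default. The config plus
#' the master seed determine all outputs.
#'
#' @param n_participants,trials_per_condition Session layout (defaults 8, 2).
#' @param master_seed Master RNG seed (default 1).
#' @param kp,cp,sp_args Generator parameter objects / overrides.
#' @param duration_mean_s,duration_sd_s Trial duration distribution.
#' @param use_truth_contours Skip audio synthesis/extraction and analyze the
#'   generator's ground-truth contours directly (fast path for calibration
#'   studies; default FALSE).
#' @param audio_fs Audio sampling rate when rendering (default 44100).
#' @param cutoff_hz Kinematic filter cutoff (default 30).
#' @param min_period_s,min_amplitude_cm Beat-detection settings.
#' @param epoch_window_ms Epoch window (default `c(-400, 400)`).
#' @param impulse_window_ms Deceleration window (default `c(-200, 0)`).
#' @param min_gap_ms Vocalization merge threshold (default 0).
#' @param voicing_threshold F0 voicing threshold (default 0.45).
#' @param max_epochs_per_trial Deterministic cap on epochs entering the
#'   trajectory models (default `Inf`).
#' @param estimate_frequency Run the wavelet movement-tempo manipulation
#'   check per movement trial (default TRUE).
#' @param fit_smooths Fit the trajectory GAMs (default TRUE).
#' @param smooth_k Spline basis dimension (default 20).
#' @param out_dir Optional run directory for CSV/JSON outputs.
#' @return A `gs_config` list.
#' @export
pipeline_config <- function(n_participants = 8, trials_per_condition = 2,
                            master_seed = 1,
                            kp = kinematics_params(), cp = coupling_params(),
                            sp_args = list(),
                            duration_mean_s = 26, duration_sd_s = 7.06,
                            use_truth_contours = FALSE, audio_fs = 44100,
                            cutoff_hz = 30, min_period_s = 0.4, min_amplitude_cm = 2,
                            epoch_window_ms = c(-400, 400),
                            impulse_window_ms = c(-200, 0),
                            min_gap_ms = 0, voicing_threshold = 0.45,
                            max_epochs_per_trial = Inf,
                            estimate_frequency = TRUE,
                            fit_smooths = TRUE, smooth_k = 20,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "gs_config")
}

#' Run the full pipeline on a synthetic session
#'
#' Executes generate -> extract -> kinematics -> epoch (real + surrogate) ->
#' impulse features -> statistical models, deterministically for a fixed
#' config and master seed. When `config$out_dir` is set, all stage outputs
#' are written as tidy CSV tables plus a JSON run report.
#'
#' @param config A [pipeline_config()].
#' @return A `gs_run` list: `trial_summaries`, `beats`, `movement_frequency`,
#'   `epochs` (an `epoch_set`, surrogate epochs labelled
#'   `condition = "surrogate"`), `trajectory_means` (pooled and
#'   participant-weighted), `impulse_observations`, `impulse_trial_means`,
#'   `models` (condition effects, trajectory smooths, deceleration effects),
#'   `report`.
#' @export
run_all <- function(config = pipeline_config()) {
  cfg <- config
  session <- generate_session(
    n_participants = cfg$n_participants,
    trials_per_condition = cfg$trials_per_condition,
    kp = cfg$kp, sp_args = cfg$sp_args, cp = cfg$cp,
    master_seed = cfg$master_seed,
    duration_mean_s = cfg$duration_mean_s, duration_sd_s = cfg$duration_sd_s,
    render = !cfg$use_truth_contours, audio_fs = cfg$audio_fs,
    out_dir = cfg$out_dir)
  analyze_session(session, cfg)
}

#' Analyze a session (in-memory core of the pipeline)
#'
#' @param session A `gs_session` from [generate_session()].
#' @param cfg A [pipeline_config()].
#' @return A `gs_run` list; see [run_all()].
#' @export
analyze_session <- function(session, cfg = pipeline_config()) {
  trials <- session$trials
  keys <- names(trials)

  # --- stage 1: per-trial signal extraction -------------------------------
  extracted <- list()
  for (key in keys) {
    tr <- trials[[key]]
    tracks <- if (cfg$use_truth_contours || is.null(tr$audio)) {
      track_from_truth(tr$truth)
    } else {
      list(env = compute_envelope(tr$audio),
           f0 = track_f0(tr$audio, tr$sex, voicing_threshold = cfg$voicing_threshold))
    }
    kin <- NULL; beats <- NULL; freq <- NULL
    if (!is.null(tr$motion)) {
      kin <- smooth_and_differentiate(tr$motion, cutoff_hz = cfg$cutoff_hz)
      beats <- annotate_deceleration(
        kin, detect_max_extensions(kin, cfg$min_period_s, cfg$min_amplitude_cm),
        window_ms = -cfg$impulse_window_ms[1])
      if (isTRUE(cfg$estimate_frequency)) {
        freq <- tryCatch(estimate_movement_frequency(kin), error = function(e) NULL)
      }
    }
    extracted[[key]] <- list(env = tracks$env, f0 = tracks$f0, beats = beats, freq = freq)
  }

  # --- stage 2: participant-level pooled scaling stats --------------------
  pids <- vapply(trials, `[[`, character(1), "participant_id")
  env_stats <- f0_stats <- list()
  for (p in unique(pids)) {
    env_all <- unlist(lapply(keys[pids == p], function(k) extracted[[k]]$env$env))
    f0_all <- unlist(lapply(keys[pids == p], function(k) extracted[[k]]$f0$f0))
    f0_all <- f0_all[!is.na(f0_all)]
    env_stats[[p]] <- list(mean = mean(env_all), sd = stats::sd(env_all))
    f0_stats[[p]] <- list(mean = mean(f0_all), sd = stats::sd(f0_all))
  }

  # --- stage 3: summaries, epochs, impulse features -----------------------
  rel_grid <- epoch_rel_grid_ms(cfg$epoch_window_ms)
  summaries <- list(); epoch_sets <- list(); epoch_meta <- list()
  obs <- list(); beat_rows <- list(); freq_rows <- list()
  n_skipped <- 0L
  for (key in keys) {
    tr <- trials[[key]]
    ex <- extracted[[key]]
    es <- env_stats[[tr$participant_id]]
    fs0 <- f0_stats[[tr$participant_id]]
    events <- segment_vocalizations(ex$f0, ex$env, min_gap_ms = cfg$min_gap_ms)
    sm <- trial_acoustic_summary(events, ex$f0, ex$env, participant_env_stats = es)
    sm <- cbind(data.frame(participant_id = tr$participant_id, trial_id = tr$trial_id,
                           sex = tr$sex, condition = tr$condition,
                           duration_s = tr$duration_s), sm)
    if (!is.null(ex$freq)) {
      sm$move_freq_mean <- ex$freq$trial_mean
      sm$move_freq_sd <- ex$freq$trial_sd
      sm$move_compliance <- ex$freq$compliance
      freq_rows[[key]] <- data.frame(participant_id = tr$participant_id,
                                     trial_id = tr$trial_id, condition = tr$condition,
                                     freq_mean = ex$freq$trial_mean,
                                     freq_sd = ex$freq$trial_sd,
                                     compliance = ex$freq$compliance)
    } else {
      sm$move_freq_mean <- NA_real_; sm$move_freq_sd <- NA_real_
      sm$move_compliance <- NA_real_
    }
    summaries[[key]] <- sm
    if (!is.null(ex$beats) && nrow(ex$beats)) {
      beats <- ex$beats
      beat_rows[[key]] <- cbind(data.frame(participant_id = tr$participant_id,
                                           trial_id = tr$trial_id,
                                           condition = tr$condition), beats)
      env_z <- zscale_track(ex$env, es)
      if (is.finite(cfg$max_epochs_per_trial) && sum(beats$valid) > cfg$max_epochs_per_trial) {
        sel <- which(beats$valid)
        keep <- sel[round(seq(1, length(sel), length.out = cfg$max_epochs_per_trial))]
        beats$valid <- beats$valid & seq_len(nrow(beats)) %in% keep
      }
      ep <- extract_epochs(beats, env_z, ex$f0, window_ms = cfg$epoch_window_ms)
      n_skipped <- n_skipped + ep$n_skipped
      epoch_sets[[length(epoch_sets) + 1L]] <- ep
      epoch_meta[[length(epoch_meta) + 1L]] <-
        data.frame(participant_id = tr$participant_id, trial_id = tr$trial_id,
                   sex = tr$sex, condition = as.character(tr$condition))
      o <- impulse_window_features(ex$beats, events, env_z, ex$f0,
                                   window_ms = cfg$impulse_window_ms)
      if (nrow(o)) {
        o$max_f0_z <- (o$max_f0 - fs0$mean) / fs0$sd
        obs[[key]] <- cbind(data.frame(participant_id = tr$participant_id,
                                       trial_id = tr$trial_id, sex = tr$sex,
                                       condition = as.character(tr$condition)), o)
      }
    }
  }
  trial_summaries <- do.call(rbind, c(summaries, list(make.row.names = FALSE)))

  # --- stage 4: surrogate pairing -----------------------------------------
  idx <- trial_summaries[, c("participant_id", "trial_id", "condition")]
  surrogate_seed <- derive_seeds(cfg$master_seed + 1L, 1L)
  pairs <- tryCatch(build_surrogate_pairing(idx, pairing_seed = surrogate_seed),
                    error = function(e) NULL)
  if (!is.null(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      sp_key <- paste(pairs$participant_id[i], pairs$speech_trial_id[i], sep = "_")
      dn_key <- paste(pairs$participant_id[i], pairs$donor_trial_id[i], sep = "_")
      sp_ex <- extracted[[sp_key]]
      beats <- extracted[[dn_key]]$beats
      es <- env_stats[[pairs$participant_id[i]]]
      ep <- extract_epochs(beats, zscale_track(sp_ex$env, es), sp_ex$f0,
                           window_ms = cfg$epoch_window_ms)
      epoch_sets[[length(epoch_sets) + 1L]] <- ep
      epoch_meta[[length(epoch_meta) + 1L]] <-
        data.frame(participant_id = pairs$participant_id[i],
                   trial_id = pairs$speech_trial_id[i],
                   sex = trials[[sp_key]]$sex, condition = "surrogate")
    }
  }
  epochs <- if (length(epoch_sets)) {
    bind_epoch_sets(epoch_sets, do.call(rbind, epoch_meta))
  } else NULL

  # --- stage 5: trajectory means and models -------------------------------
  trajectory_means <- NULL
  if (!is.null(epochs) && ncol(epochs$env)) {
    trajectory_means <- list(
      pooled = average_trajectories(epochs, "env", weights = "pooled"),
      participant = average_trajectories(epochs, "env", weights = "participant"),
      f0_pooled = average_trajectories(epochs, "f0", weights = "pooled"))
  }
  impulse_observations <- if (length(obs)) {
    do.call(rbind, c(obs, list(make.row.names = FALSE)))
  } else NULL
  impulse_trial_means <- if (!is.null(impulse_observations)) {
    tm <- aggregate_impulse_observations(impulse_observations)
    tmz <- aggregate_impulse_observations(
      transform(impulse_observations, max_f0 = max_f0_z))
    tm$max_f0_z <- tmz$max_f0
    tm
  } else NULL

  models <- list()
  models$condition_env <- tryCatch(fit_condition_effects(trial_summaries, "env_z"),
                                   error = function(e) e)
  models$condition_f0 <- tryCatch(fit_condition_effects(trial_summaries, "f0"),
                                  error = function(e) e)
  if (!is.null(impulse_trial_means)) {
    dz <- impulse_trial_means
    dz$max_f0 <- dz$max_f0_z            # both responses on the z scale
    models$deceleration <- tryCatch(fit_deceleration_effects(dz),
                                    error = function(e) e)
  }
  if (cfg$fit_smooths && !is.null(epochs)) {
    edf <- as_epochs_df(epochs)   # surrogate epochs act as the passive reference
    models$smooth_env <- tryCatch(
      fit_trajectory_smooths(edf, "env", k = cfg$smooth_k), error = function(e) e)
    models$smooth_f0 <- tryCatch(
      fit_trajectory_smooths(edf, "f0", k = cfg$smooth_k), error = function(e) e)
  }

  report <- list(
    master_seed = cfg$master_seed,
    n_participants = length(unique(trial_summaries$participant_id)),
    n_trials = nrow(trial_summaries),
    trials_per_condition = as.list(table(trial_summaries$condition)),
    n_epochs = if (is.null(epochs)) 0L else ncol(epochs$env),
    epoch_length_samples = length(rel_grid),
    n_epochs_skipped_at_edges = n_skipped,
    surrogate_pairs = if (is.null(pairs)) 0L else nrow(pairs),
    model_fallbacks = list(
      deceleration_env = if (!is.null(models$deceleration) &&
                             !inherits(models$deceleration, "error"))
        models$deceleration$env$fallback else NA,
      deceleration_f0 = if (!is.null(models$deceleration) &&
                            !inherits(models$deceleration, "error"))
        models$deceleration$f0$fallback else NA))

  run <- structure(list(
    trial_summaries = trial_summaries,
    beats = if (length(beat_rows)) do.call(rbind, c(beat_rows, list(make.row.names = FALSE))) else NULL,
    movement_frequency = if (length(freq_rows)) do.call(rbind, c(freq_rows, list(make.row.names = FALSE))) else NULL,
    epochs = epochs,
    trajectory_means = trajectory_means,
    impulse_observations = impulse_observations,
    impulse_trial_means = impulse_trial_means,
    surrogate_pairs = pairs,
    models = models,
    report = report,
    session = session), class = "gs_run")
  if (!is.null(cfg$out_dir)) write_run_outputs(run, cfg$out_dir)
  run
}

#' @export
print.gs_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("<gs_run> %d participants, %d trials, %d epochs (%d samples each)\n",
              r$n_participants, r$n_trials, r$n_epochs, r$epoch_length_samples))
  invisible(x)
}

write_run_outputs <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(d, f) if (!is.null(d)) utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
  w(run$trial_summaries, "trial_summaries.csv")
  w(run$beats, "beats.csv")
  w(run$movement_frequency, "movement_frequency.csv")
  if (!is.null(run$epochs)) w(as_epochs_df(run$epochs), "epochs.csv")
  if (!is.null(run$trajectory_means)) {
    w(run$trajectory_means$pooled, "trajectory_means.csv")
    w(run$trajectory_means$participant, "trajectory_means_by_participant.csv")
  }
  w(run$impulse_observations, "impulse_observations.csv")
  w(run$impulse_trial_means, "impulse_trial_means.csv")
  w(run$surrogate_pairs, "surrogate_pairs.csv")
  for (nm in c("condition_env", "condition_f0")) {
    m <- run$models[[nm]]
    if (!is.null(m) && !inherits(m, "error")) {
      w(m$estimates, paste0(nm, "_effects.csv"))
    }
  }
  if (!is.null(run$models$deceleration) && !inherits(run$models$deceleration, "error")) {
    w(rbind(cbind(model = "env", run$models$deceleration$env$estimates),
            cbind(model = "f0", run$models$deceleration$f0$estimates)),
      "deceleration_effects.csv")
  }
  for (nm in c("smooth_env", "smooth_f0")) {
    m <- run$models[[nm]]
    if (!is.null(m) && !inherits(m, "error")) {
      w(m$fitted, paste0(nm, "_fitted.csv"))
      w(m$smooth_tests, paste0(nm, "_tests.csv"))
    }
  }
  jsonlite::write_json(run$report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
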
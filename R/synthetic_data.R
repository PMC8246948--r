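# Synthetic session generator: rhythmic vertical limb movement with an
# abrupt stop ("beat") at maximum extension, alternating voiced/unvoiced
# speech with sex-dependent F0, and an injected transient acoustic boost at
# each beat whose gain scales with deceleration magnitude and an
# effector-mass factor (arm > wrist > passive = 0). The generator records
# full ground truth so every downstream stage can be validated.

#' Kinematics generator parameters
#'
#' @param freq_mean Mean movement frequency in Hz (default 4/3, the 80-BPM
#'   instructed tempo).
#' @param freq_sd Cycle-to-cycle SD of the slow frequency random walk in Hz
#'   (default 0.04).
#' @param amplitude_cm Named vector of movement half-amplitudes per condition
#'   in cm; arm strokes are larger than wrist strokes.
#' @param beat_sharpness Downstroke phase-warp exponent (>= 1); 1 gives a pure
#'   sinusoid, larger values make the stop at maximum extension more abrupt.
#' @param amp_trial_cv,amp_cycle_cv Coefficients of variation of the
#'   trial-level and cycle-level amplitude multipliers (defaults 0.2, 0.1):
#'   movers do not reproduce stroke amplitude exactly, which is what spreads
#'   peak deceleration within a condition.
#' @param sensor_noise_sd_cm Additive sensor noise SD in cm (default 0.05).
#' @return A `kinematics_params` list.
#' @export
kinematics_params <- function(freq_mean = 4 / 3, freq_sd = 0.04,
                              amplitude_cm = c(wrist = 10, arm = 25),
                              beat_sharpness = 2, amp_trial_cv = 0.2,
                              amp_cycle_cv = 0.1, sensor_noise_sd_cm = 0.05) {
  if (beat_sharpness < 1) stop("beat_sharpness must be >= 1")
  if (!all(c("wrist", "arm") %in% names(amplitude_cm))) {
    stop("amplitude_cm must name wrist and arm")
  }
  structure(list(freq_mean = freq_mean, freq_sd = freq_sd,
                 amplitude_cm = amplitude_cm, beat_sharpness = beat_sharpness,
                 amp_trial_cv = amp_trial_cv, amp_cycle_cv = amp_cycle_cv,
                 sensor_noise_sd_cm = sensor_noise_sd_cm),
            class = "kinematics_params")
}

#' Speaker parameters
#'
#' @param sex `"female"` or `"male"`.
#' @param f0_base Baseline F0 in Hz; defaults to 187 Hz for female speakers
#'   and 73 Hz lower for male speakers, matching typical adult values.
#' @param f0_sd SD of the slow within-trial F0 drift in Hz (default 6).
#' @param f0_jitter_sd Fast frame-to-frame F0 jitter SD in Hz (default 1.5).
#' @param env_base Baseline voiced envelope level, arbitrary units (default 1).
#' @param env_drift_sd SD of the slow envelope drift (default 0.08).
#' @param env_jitter_sd Fast envelope jitter SD (default 0.04).
#' @param voiced_dur_mean_ms,voiced_dur_sd_ms Lognormal vocalization-duration
#'   moments in ms (defaults 160 / 120).
#' @param pause_dur_mean_ms,pause_dur_sd_ms Lognormal pause-duration moments
#'   in ms (defaults 200 / 150).
#' @param f0_intercept,env_intercept Participant-level random offsets.
#' @return A `speaker_params` list.
#' @export
speaker_params <- function(sex = "female",
                           f0_base = if (sex == "male") 114 else 187,
                           f0_sd = 6, f0_jitter_sd = 1.5,
                           env_base = 1, env_drift_sd = 0.08, env_jitter_sd = 0.04,
                           voiced_dur_mean_ms = 160, voiced_dur_sd_ms = 120,
                           pause_dur_mean_ms = 200, pause_dur_sd_ms = 150,
                           f0_intercept = 0, env_intercept = 0) {
  if (!sex %in% c("female", "male")) stop("unknown sex label: ", sex)
  if (voiced_dur_mean_ms <= 0 || pause_dur_mean_ms <= 0) stop("durations must be positive")
  rng <- f0_range_for_sex(sex)
  if (f0_base + f0_intercept < rng[1] || f0_base + f0_intercept > rng[2]) {
    stop("f0_base outside the sex-appropriate tracking range")
  }
  structure(as.list(environment()), class = "speaker_params")
}

#' Gesture-speech coupling parameters
#'
#' The injected acoustic boost at each beat has height
#' `mass_factor[condition] * beta * max_decel`, centered
#' `bump_center_offset_ms` before maximum extension with temporal FWHM
#' `bump_width_ms`. Defaults place the bump at -100 ms (the middle of the
#' 200-ms deceleration window) and give F0 coupling only for arm movement,
#' reflecting that F0 is uniformly less affected than the envelope and that
#' F0-deceleration scaling is an arm (high effector mass) phenomenon.
#' Condition-level baseline offsets (`env_offset`, `f0_offset`) model the
#' sustained acoustic elevation under movement.
#'
#' @param beta_env Envelope boost per unit deceleration (env units per
#'   cm/s^2); default 3e-5.
#' @param beta_f0 Named per-condition F0 boost per unit deceleration (Hz per
#'   cm/s^2); default wrist 0, arm 1e-3.
#' @param mass_factor Named map condition -> nonnegative scalar with
#'   `arm > wrist > 0` and `passive = 0`; default 0/1/2.
#' @param bump_center_offset_ms Bump center relative to maximum extension in
#'   ms, in \[-400, 0\]; default -100.
#' @param bump_width_ms Bump FWHM in ms; default 120.
#' @param env_offset,f0_offset Named per-condition baseline offsets (env
#'   units / Hz); defaults wrist +0.10 / +1.6 and arm +0.20 / +3.5.
#' @return A `coupling_params` list.
#' @export
coupling_params <- function(beta_env = 3e-5,
                            beta_f0 = c(passive = 0, wrist = 0, arm = 1e-3),
                            mass_factor = c(passive = 0, wrist = 1, arm = 2),
                            bump_center_offset_ms = -100, bump_width_ms = 120,
                            env_offset = c(passive = 0, wrist = 0.10, arm = 0.20),
                            f0_offset = c(passive = 0, wrist = 1.6, arm = 3.5)) {
  if (mass_factor[["passive"]] != 0) stop("mass_factor for passive must be 0")
  if (!(mass_factor[["arm"]] > mass_factor[["wrist"]] && mass_factor[["wrist"]] > 0)) {
    stop("mass_factor must satisfy arm > wrist > 0")
  }
  if (bump_center_offset_ms < -400 || bump_center_offset_ms > 0) {
    stop("bump_center_offset_ms must lie in [-400, 0]")
  }
  if (length(beta_f0) == 1L && is.null(names(beta_f0))) {
    beta_f0 <- c(passive = 0, wrist = unname(beta_f0), arm = unname(beta_f0))
  }
  structure(list(beta_env = beta_env, beta_f0 = beta_f0, mass_factor = mass_factor,
                 bump_center_offset_ms = bump_center_offset_ms,
                 bump_width_ms = bump_width_ms,
                 env_offset = env_offset, f0_offset = f0_offset),
            class = "coupling_params")
}

# lognormal parameterized by arithmetic mean and SD
rlnorm_ms <- function(n, mean_ms, sd_ms) {
  cv2 <- (sd_ms / mean_ms)^2
  sdlog <- sqrt(log(1 + cv2))
  meanlog <- log(mean_ms) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}

# smooth slow drift: white noise low-passed by a long moving average
# (computed via cumulative sums), rescaled to a target SD
slow_drift <- function(n, sd, fs, tau_s = 3) {
  if (sd <= 0 || n < 8L) return(numeric(n))
  w <- max(3L, round(tau_s * fs))
  cs <- c(0, cumsum(stats::rnorm(n + w)))
  x <- (cs[(w + 1L):(w + n)] - cs[1:n]) / w
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(numeric(n))
  x / s * sd
}

#' Generate a rhythmic beat-movement trace
#'
#' Quasi-periodic vertical movement: per-cycle frequency follows a slow
#' random walk around `freq_mean`; within each cycle the downstroke phase is
#' power-law warped (`beat_sharpness`) so the stroke ends in an abrupt stop
#' at the position minimum (maximum extension). Sensor noise is added last;
#' all ground truth (beat times, deceleration onsets, maximum decelerations)
#' is computed on the noiseless trace.
#'
#' @param kp A [kinematics_params()].
#' @param condition `"wrist"` or `"arm"` (selects the amplitude).
#' @param duration_s Trial duration in s (>= 5).
#' @param seed Integer RNG seed.
#' @param fs Sampling rate in Hz (default 240).
#' @return List with `motion` (a [motion_trace()], noisy) and `truth`: a list
#'   with `beat_times`, `decel_onset_times`, `max_decel_values`, and the
#'   noiseless trace `z_clean`.
#' @export
generate_kinematics <- function(kp, condition, duration_s, seed, fs = 240) {
  if (duration_s < 5) stop("duration must be at least 5 s")
  if (!condition %in% c("wrist", "arm")) stop("kinematics is generated for movement conditions only")
  A <- kp$amplitude_cm[[condition]]
  p <- kp$beat_sharpness
  set.seed(as.integer(seed))
  # per-cycle frequencies: reflected random walk inside [1, 1.8] Hz
  n_cycles <- ceiling(duration_s * 1.8) + 2L   # covers the walk's upper bound
  f <- numeric(n_cycles)
  f[1L] <- kp$freq_mean
  if (n_cycles > 1L) {
    steps <- stats::rnorm(n_cycles - 1L, 0, kp$freq_sd)
    for (i in 2:n_cycles) {
      fi <- f[i - 1L] + steps[i - 1L]
      # soft reflection toward the target keeps the walk near the tempo
      fi <- fi + 0.1 * (kp$freq_mean - fi)
      f[i] <- min(1.8, max(1, fi))
    }
  }
  periods <- 1 / f
  starts <- cumsum(c(0, periods))
  # per-trial and per-cycle amplitude variability (lognormal multipliers)
  lcv <- function(cv) if (cv > 0) sqrt(log(1 + cv^2)) else 0
  A_trial <- A * stats::rlnorm(1, -lcv(kp$amp_trial_cv)^2 / 2, lcv(kp$amp_trial_cv))
  A_cyc <- A_trial * stats::rlnorm(n_cycles + 1L, -lcv(kp$amp_cycle_cv)^2 / 2,
                                   lcv(kp$amp_cycle_cv))
  n <- floor(duration_s * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  cyc <- findInterval(t, starts)
  u <- (t - starts[cyc]) / periods[cyc]     # cycle phase fraction in [0, 1)
  # downstroke (u < 1/2): phase pi * (2u)^p  -> abrupt arrival at the minimum
  # upstroke  (u >= 1/2): phase pi * (1 + (2u - 1))
  ph <- ifelse(u < 0.5, pi * (2 * u)^p, pi * (2 * u))
  # amplitude interpolated across the cycle keeps the trace continuous
  A_t <- A_cyc[cyc] + (A_cyc[cyc + 1L] - A_cyc[cyc]) * u
  z_clean <- A_t * cos(ph)
  beat_times <- starts[-1L] - periods / 2   # minima: middle of each cycle
  beat_times <- beat_times[beat_times > 0 & beat_times < duration_s]
  # truth deceleration measures from derivatives of the noiseless trace
  kin_clean <- smooth_and_differentiate(motion_trace(z_clean, fs = fs, t = t))
  tr_decel <- vapply(beat_times, function(tb) {
    iw <- which(t >= tb - 0.2 & t <= tb)
    io <- which(t >= tb - 0.5 & t < tb)
    c(max(0, max(kin_clean$a[iw])), t[io[which.min(kin_clean$v[io])]])
  }, numeric(2))
  z <- z_clean + stats::rnorm(n, 0, kp$sensor_noise_sd_cm)
  list(motion = motion_trace(z, fs = fs, t = t),
       truth = list(beat_times = beat_times,
                    max_decel_values = tr_decel[1, ],
                    decel_onset_times = tr_decel[2, ],
                    z_clean = z_clean))
}

#' Generate ground-truth speech contours with injected beat coupling
#'
#' Speech is an alternating sequence of voiced and pause runs (lognormal
#' durations). The baseline F0 contour is the speaker's base plus participant
#' intercept, condition offset, slow drift and fast jitter; the envelope
#' contour likewise, gated to near zero outside voiced intervals (with 10-ms
#' raised-cosine edges). At each beat a Gaussian bump of height
#' `mass_factor[condition] * beta * max_decel` is added to the envelope and
#' F0 inside voiced intervals; bumps falling wholly in pauses are recorded in
#' the truth but leave no acoustic trace, mirroring an analysis that only
#' sees vocalized windows.
#'
#' @param sp A [speaker_params()].
#' @param cp A [coupling_params()].
#' @param truth Partial truth from [generate_kinematics()], or `NULL`/empty
#'   beats for passive trials.
#' @param condition Condition label.
#' @param duration_s Trial duration in s.
#' @param seed Integer RNG seed.
#' @param fs Contour rate in Hz (default 240).
#' @return Completed truth list, adding `voiced_intervals` (matrix onset,
#'   offset), `true_f0`, `true_env` (240-Hz contours; `true_f0` is `NA` when
#'   unvoiced), `injected_bump_gains_env`, `injected_bump_gains_f0`, `t`.
#' @export
generate_speech_tracks <- function(sp, cp, truth, condition, duration_s, seed, fs = 240) {
  beats <- if (is.null(truth)) numeric(0) else truth$beat_times
  if (condition == "passive" && length(beats)) {
    stop("passive trials must not carry beat events")
  }
  set.seed(as.integer(seed))
  n <- floor(duration_s * fs) + 1L
  t <- (seq_len(n) - 1) / fs
  # alternating voiced / pause runs
  n_runs <- ceiling(duration_s * 1000 / (sp$voiced_dur_mean_ms + sp$pause_dur_mean_ms)) * 2L + 8L
  vd <- rlnorm_ms(n_runs, sp$voiced_dur_mean_ms, sp$voiced_dur_sd_ms) / 1000
  pd <- rlnorm_ms(n_runs, sp$pause_dur_mean_ms, sp$pause_dur_sd_ms) / 1000
  bounds <- cumsum(as.vector(rbind(pd, vd)))
  onsets <- bounds[seq(1, length(bounds), by = 2)]
  offsets <- bounds[seq(2, length(bounds), by = 2)]
  keep <- onsets < duration_s
  onsets <- onsets[keep]; offsets <- pmin(offsets[keep], duration_s)
  voiced <- rep(FALSE, n)
  for (i in seq_along(onsets)) {
    i0 <- min(n, as.integer(ceiling(onsets[i] * fs - 1e-9)) + 1L)
    i1 <- min(n, as.integer(ceiling(offsets[i] * fs - 1e-9)))
    if (i1 >= i0) voiced[i0:i1] <- TRUE
  }

  cond_env <- cp$env_offset[[condition]]
  cond_f0 <- cp$f0_offset[[condition]]
  f0_level <- sp$f0_base + sp$f0_intercept + cond_f0 +
    slow_drift(n, sp$f0_sd, fs) + stats::rnorm(n, 0, sp$f0_jitter_sd)
  env_level <- sp$env_base + sp$env_intercept + cond_env +
    slow_drift(n, sp$env_drift_sd, fs) + stats::rnorm(n, 0, sp$env_jitter_sd)
  env_level <- pmax(env_level, 0.05)

  gains_env <- gains_f0 <- numeric(length(beats))
  bump_env <- bump_f0 <- numeric(n)
  if (length(beats)) {
    mass <- cp$mass_factor[[condition]]
    sigma <- cp$bump_width_ms / 1000 / (2 * sqrt(2 * log(2)))
    centers <- beats + cp$bump_center_offset_ms / 1000
    gains_env <- mass * cp$beta_env * truth$max_decel_values
    gains_f0 <- mass * cp$beta_f0[[condition]] * truth$max_decel_values
    for (i in seq_along(beats)) {
      i0 <- max(1L, as.integer(floor((centers[i] - 4 * sigma) * fs)) + 1L)
      i1 <- min(n, as.integer(ceiling((centers[i] + 4 * sigma) * fs)) + 1L)
      sel <- i0:i1
      g <- exp(-0.5 * ((t[sel] - centers[i]) / sigma)^2)
      bump_env[sel] <- bump_env[sel] + gains_env[i] * g
      bump_f0[sel] <- bump_f0[sel] + gains_f0[i] * g
    }
  }
  # smooth voicing gate (10-ms raised-cosine edges) for the envelope
  gate <- fft_convolve_same(as.numeric(voiced), hann_window(max(3L, round(0.01 * fs) * 2L + 1L)))
  gate <- gate / max(gate, 1e-12)
  gate <- pmin(1, pmax(0, gate))
  true_env <- (env_level + bump_env) * gate + 0.005
  true_f0 <- f0_level + bump_f0
  true_f0[!voiced] <- NA_real_

  out <- if (is.null(truth)) list() else truth
  out$t <- t
  out$voiced_intervals <- cbind(onset = onsets, offset = offsets)
  out$true_f0 <- true_f0
  out$true_env <- true_env
  out$injected_bump_gains_env <- gains_env
  out$injected_bump_gains_f0 <- gains_f0
  out$condition <- condition
  out
}

#' Render audio from ground-truth contours
#'
#' Synthesizes a harmonic complex (6 harmonics, 1/k amplitude roll-off) whose
#' instantaneous frequency follows `true_f0` inside voiced intervals, scaled
#' by `true_env`, with low-level white noise in pauses. Control contours are
#' upsampled to `fs` by linear interpolation.
#'
#' @param truth Completed truth from [generate_speech_tracks()].
#' @param fs Audio sampling rate in Hz (default 44100).
#' @param seed Integer RNG seed for the pause noise.
#' @param n_harmonics Number of harmonics (default 6).
#' @return An [audio_track()].
#' @export
render_audio <- function(truth, fs = 44100, seed = 1, n_harmonics = 6) {
  f0c <- truth$true_f0
  if (any(!is.na(f0c) & (f0c < 30 | f0c > 1000))) {
    stop("true F0 outside the synthesizable range [30, 1000] Hz")
  }
  set.seed(as.integer(seed))
  t240 <- truth$t
  dur <- t240[length(t240)]
  n <- floor(dur * fs) + 1L
  tt <- (seq_len(n) - 1) / fs
  # instantaneous frequency: interpolate within voiced spans, neutral elsewhere
  f_filled <- f0c
  if (all(is.na(f_filled))) f_filled <- rep(100, length(f_filled))
  f_filled <- stats::approx(t240[!is.na(f_filled)], f_filled[!is.na(f_filled)],
                            xout = t240, rule = 2)$y
  f_inst <- stats::approx(t240, f_filled, xout = tt, rule = 2)$y
  env <- stats::approx(t240, truth$true_env, xout = tt, rule = 2)$y
  voiced240 <- !is.na(f0c)
  vo <- stats::approx(t240, as.numeric(voiced240), xout = tt, rule = 2)$y > 0.5
  phase <- 2 * pi * cumsum(f_inst) / fs
  amp <- 1 / seq_len(n_harmonics)
  carrier <- numeric(n)
  for (k in seq_len(n_harmonics)) carrier <- carrier + amp[k] * sin(k * phase)
  carrier <- carrier / sum(amp)
  # fixed global gain (not per-trial normalization, which would distort
  # between-condition level differences); clipping is essentially impossible
  # at realistic envelope levels
  x <- env * carrier / 4
  x[!vo] <- 0
  x <- x + stats::rnorm(n, 0, 0.001)        # low noise floor in pauses
  x[x > 1] <- 1; x[x < -1] <- -1
  audio_track(x, fs = fs)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seeds <- function(master_seed, n) {
  set.seed(as.integer(master_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a complete synthetic session
#'
#' Lays out `n_participants` speakers, each performing
#' `trials_per_condition` trials in each of the three conditions (randomized
#' order), with sex assigned roughly 2:1 female:male, participant random
#' intercepts for F0 and envelope, and trial durations drawn around 26 s
#' (SD 7 s, truncated at 10 s). All per-trial randomness is driven by
#' sub-seeds derived deterministically from `master_seed`. When `out_dir` is
#' given, WAV/CSV/manifest files are written through the session I/O layer.
#'
#' @param n_participants Number of participants (>= 1).
#' @param trials_per_condition Trials per condition per participant.
#' @param kp,sp_args,cp [kinematics_params()], a list of [speaker_params()]
#'   overrides shared by all speakers, and [coupling_params()].
#' @param master_seed Integer master seed.
#' @param duration_mean_s,duration_sd_s Trial duration distribution (s).
#' @param render Render audio (`TRUE`) or keep truth contours only.
#' @param audio_fs Audio sampling rate when rendering (default 44100).
#' @param out_dir Optional output directory for WAV/CSV/manifest.
#' @param f0_intercept_sd,env_intercept_sd Participant random-intercept SDs.
#' @return A `gs_session`: list with `manifest` (data frame), `trials` (named
#'   list with `audio`, `motion`, `truth`, `sex`, `condition`, ...), and
#'   `params`.
#' @export
generate_session <- function(n_participants, trials_per_condition = 4,
                             kp = kinematics_params(), sp_args = list(),
                             cp = coupling_params(), master_seed = 1,
                             duration_mean_s = 26, duration_sd_s = 7.06,
                             render = TRUE, audio_fs = 44100, out_dir = NULL,
                             f0_intercept_sd = 15, env_intercept_sd = 0.08) {
  if (n_participants < 1) stop("need at least one participant")
  n_trials_pp <- trials_per_condition * 3L
  seeds <- derive_seeds(master_seed, n_participants * (n_trials_pp * 3L + 2L) + 1L)
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }

  set.seed(as.integer(master_seed))
  sexes <- sample(c("female", "male"), n_participants, replace = TRUE, prob = c(2, 1) / 3)
  f0_int <- stats::rnorm(n_participants, 0, f0_intercept_sd)
  env_int <- stats::rnorm(n_participants, 0, env_intercept_sd)

  manifest <- list()
  trials <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    sp <- do.call(speaker_params,
                  c(list(sex = sexes[p], f0_intercept = f0_int[p],
                         env_intercept = env_int[p]), sp_args))
    set.seed(next_seed())
    conds <- sample(rep(.gs_conditions, trials_per_condition))
    durs <- pmax(10, stats::rnorm(n_trials_pp, duration_mean_s, duration_sd_s))
    for (k in seq_len(n_trials_pp)) {
      cond <- conds[k]
      tid <- sprintf("T%02d", k)
      kin <- NULL; truth0 <- NULL
      if (cond != "passive") {
        kin <- generate_kinematics(kp, cond, durs[k], seed = next_seed())
        truth0 <- kin$truth
      } else {
        next_seed()                        # keep the seed stream aligned
      }
      truth <- generate_speech_tracks(sp, cp, truth0, cond, durs[k], seed = next_seed())
      audio <- if (render) render_audio(truth, fs = audio_fs, seed = next_seed()) else {
        next_seed(); NULL
      }
      key <- paste(pid, tid, sep = "_")
      trials[[key]] <- list(participant_id = pid, trial_id = tid, sex = sexes[p],
                            condition = cond, duration_s = durs[k],
                            audio = audio, motion = if (is.null(kin)) NULL else kin$motion,
                            truth = truth)
      manifest[[key]] <- data.frame(
        participant_id = pid, sex = sexes[p], condition = cond, trial_id = tid,
        audio_path = file.path(pid, paste0(tid, ".wav")),
        motion_path = if (cond == "passive") "" else file.path(pid, paste0(tid, "_motion.csv")),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (key in names(trials)) {
      tr <- trials[[key]]
      pdir <- file.path(out_dir, tr$participant_id)
      if (!dir.exists(pdir)) dir.create(pdir)
      if (!is.null(tr$audio)) {
        write_wav(tr$audio, file.path(pdir, paste0(tr$trial_id, ".wav")))
      }
      if (!is.null(tr$motion)) {
        write_motion_csv(tr$motion, file.path(pdir, paste0(tr$trial_id, "_motion.csv")))
      }
    }
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
    write_session_truth(trials, file.path(out_dir, "truth.csv"))
  }
  structure(list(manifest = manifest, trials = trials,
                 params = list(kp = kp, cp = cp, sp_args = sp_args,
                               master_seed = master_seed)),
            class = "gs_session")
}

#' @export
print.gs_session <- function(x, ...) {
  cat(sprintf("<gs_session> %d trials, %d participants\n",
              nrow(x$manifest), length(unique(x$manifest$participant_id))))
  print(table(x$manifest$condition))
  invisible(x)
}

#' Smooth a ground-truth envelope contour like the extraction pipeline
#'
#' The pipeline's envelope is by definition a 5-Hz-Hann-smoothed quantity, so
#' end-to-end envelope recovery is judged against the same smoothing applied
#' to the generator's truth contour (which contains syllable gates and
#' frame-rate jitter faster than the smoother can follow).
#'
#' @param true_env Ground-truth envelope contour on the 240-Hz grid.
#' @param smooth_hz Hann smoothing frequency (default 5).
#' @param fs Contour rate (default 240).
#' @return Smoothed contour (`NA` at the unsupported edges).
#' @export
smooth_truth_envelope <- function(true_env, smooth_hz = 5, fs = 240) {
  k <- hann_window(max(3L, round(fs / smooth_hz)))
  as.numeric(stats::filter(true_env, k / sum(k), sides = 2))
}

# per-beat truth table for a session (one row per ground-truth beat)
write_session_truth <- function(trials, path) {
  rows <- lapply(trials, function(tr) {
    bt <- tr$truth$beat_times
    if (is.null(bt) || !length(bt)) return(NULL)
    data.frame(participant_id = tr$participant_id, trial_id = tr$trial_id,
               condition = tr$condition, beat_time = bt,
               decel_onset_time = tr$truth$decel_onset_times,
               max_decel = tr$truth$max_decel_values,
               bump_gain_env = tr$truth$injected_bump_gains_env,
               bump_gain_f0 = tr$truth$injected_bump_gains_f0)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows)) rows <- data.frame()
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
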
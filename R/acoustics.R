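# Acoustic prosody extraction: amplitude envelope and F0 on a 240-Hz grid.

# Modulus of the analytic signal via frequency-domain Hilbert construction.
# Zero-padding to a highly composite FFT length; the pad only perturbs the
# first/last few samples, which every consumer treats as edge region.
analytic_modulus <- function(x) {
  n <- length(x)
  nfft <- stats::nextn(n)
  X <- stats::fft(c(x, numeric(nfft - n)))
  h <- numeric(nfft)
  if (nfft %% 2L == 0L) {
    h[1L] <- 1; h[nfft / 2L + 1L] <- 1; h[2:(nfft / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2:((nfft + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE)[seq_len(n)] / nfft)
}

# Centered ("same") FFT convolution with a finite kernel.
fft_convolve_same <- function(x, k) {
  n <- length(x); m <- length(k)
  nfft <- stats::nextn(n + m - 1L)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                     stats::fft(c(k, numeric(nfft - m))), inverse = TRUE)) / nfft
  j0 <- floor((m + 1L) / 2L)
  y[j0:(j0 + n - 1L)]
}

hann_window <- function(n) {
  if (n < 2L) return(rep(1, n))
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Extract the smoothed amplitude envelope of an audio track
#'
#' The envelope is the modulus of the analytic signal (Hilbert transform),
#' smoothed with a Hann kernel whose duration corresponds to the named
#' smoothing frequency (kernel length = `fs / smooth_hz` samples, i.e. a
#' "5-Hz Hann window" spans 200 ms), then resampled onto a common low-rate
#' grid shared with the motion data.
#'
#' @param audio An [audio_track()] (mono, `fs >= 8000`).
#' @param smooth_hz Hann smoothing frequency in Hz; default 5.
#' @param out_fs Output grid rate in Hz; default 240, matching motion capture.
#' @return An `envelope_track`: data frame with columns `t` (s) and `env`
#'   (nonnegative amplitude), with attribute `fs = out_fs`.
#' @export
compute_envelope <- function(audio, smooth_hz = 5, out_fs = 240) {
  if (length(audio$samples) == 0L) stop("empty audio")
  if (audio$fs < 8000) stop("audio sampling rate must be at least 8 kHz")
  am <- analytic_modulus(audio$samples)
  L <- max(3L, round(audio$fs / smooth_hz))
  k <- hann_window(L)
  sm <- fft_convolve_same(am, k / sum(k))
  t_in <- (seq_along(sm) - 1) / audio$fs
  n_out <- floor(t_in[length(t_in)] * out_fs) + 1L
  t_out <- (seq_len(n_out) - 1) / out_fs
  env <- stats::approx(t_in, sm, xout = t_out, rule = 2)$y
  out <- data.frame(t = t_out, env = pmax(env, 0))
  attr(out, "fs") <- out_fs
  class(out) <- c("envelope_track", "data.frame")
  out
}

#' Sex-appropriate F0 search ranges
#'
#' Preset pitch-tracking ranges: male 50--400 Hz, female 80--640 Hz.
#'
#' @param sex `"male"` or `"female"`.
#' @return Numeric length-2 vector `c(fmin, fmax)` in Hz.
#' @export
f0_range_for_sex <- function(sex) {
  switch(as.character(sex),
         male = c(50, 400),
         female = c(80, 640),
         stop("unknown sex label: ", sex, " (expected 'male' or 'female')"))
}

#' Track the fundamental frequency (F0) of a mono audio track
#'
#' Frame-wise autocorrelation pitch tracker evaluated at every point of the
#' common 240-Hz grid. The audio is first decimated to roughly 8 kHz (pitch
#' information lives far below that), frames of 2.5 periods of the range
#' floor are autocorrelated via FFT, and the strongest bias-corrected
#' normalized autocorrelation peak within the sex-appropriate lag range is
#' taken, with a small per-octave cost discouraging subharmonic picks and
#' parabolic interpolation of the peak lag for sub-sample resolution.
#' Frames whose periodicity strength falls below `voicing_threshold` are
#' unvoiced (`NA`). A post-pass suppresses octave jumps: within a voiced run,
#' a frame-to-frame change exceeding 40% is corrected to the halved/doubled
#' candidate when possible, otherwise the frame is unvoiced.
#'
#' @param audio An [audio_track()].
#' @param sex `"male"` or `"female"`, selecting the preset range
#'   ([f0_range_for_sex()]).
#' @param voicing_threshold Minimum normalized autocorrelation at the chosen
#'   lag for a frame to count as voiced; default 0.45.
#' @param out_fs Output grid rate in Hz (default 240).
#' @return An `f0_track`: data frame with `t` (s) and `f0` (Hz, `NA` when
#'   unvoiced), attribute `fs = out_fs`.
#' @export
track_f0 <- function(audio, sex, voicing_threshold = 0.45, out_fs = 240) {
  rng <- f0_range_for_sex(sex)
  fmin <- rng[1]; fmax <- rng[2]
  x <- audio$samples; fs <- audio$fs
  q <- max(1L, floor(fs / 8000))
  if (q > 1L) {
    bf <- signal::butter(4, 0.8 / q, type = "low")
    x <- signal::filtfilt(bf, x)
    x <- x[seq(1L, length(x), by = q)]
  }
  fs_a <- fs / q
  L <- round(2.5 * fs_a / fmin)
  lag_min <- max(2L, floor(fs_a / fmax))
  lag_max <- ceiling(fs_a / fmin)
  nfft <- stats::nextn(L + lag_max + 1L)

  dur <- (length(audio$samples) - 1) / fs   # grid shared with compute_envelope
  n_out <- floor(dur * out_fs) + 1L
  t_out <- (seq_len(n_out) - 1) / out_fs
  f0 <- rep(NA_real_, n_out)
  strength <- rep(NA_real_, n_out)

  centers <- round(t_out * fs_a) + 1L
  starts <- centers - floor(L / 2)
  ok <- starts >= 1L & (starts + L - 1L) <= length(x)
  # energy pre-gate: frames far below the trial's loudest frames cannot be
  # voiced, and skipping them costs nothing in the autocorrelation pass
  cs <- c(0, cumsum(x^2))
  rms <- rep(0, length(starts))
  rms[ok] <- sqrt((cs[starts[ok] + L] - cs[starts[ok]]) / L)
  ok <- ok & rms >= max(0.01 * max(rms), 1e-7)
  idx_ok <- which(ok)
  if (length(idx_ok)) {
    lags <- lag_min:lag_max
    bias <- L / (L - lags)                 # short-frame ACF bias correction
    octave_cost <- 0.01 * log2(lags / lag_min)
    chunk <- 1500L
    for (b in seq(1L, length(idx_ok), by = chunk)) {
      ii <- idx_ok[b:min(b + chunk - 1L, length(idx_ok))]
      fr <- x[outer(0:(L - 1L), starts[ii], "+")]
      dim(fr) <- c(L, length(ii))
      fr <- sweep(fr, 2L, colMeans(fr))
      Fr <- stats::mvfft(rbind(fr, matrix(0, nfft - L, ncol(fr))))
      ac <- Re(stats::mvfft(Fr * Conj(Fr), inverse = TRUE)) / nfft
      r0 <- ac[1L, ]
      r0[r0 <= 0] <- Inf                   # silent frame -> strength 0
      # candidate selection uses the *biased* normalized ACF (its natural
      # decay with lag discourages subharmonic/octave-down picks); voicing
      # strength uses the bias-corrected value at the chosen lag
      rn <- ac[lags + 1L, , drop = FALSE] / rep(r0, each = length(lags))
      sc <- rn - octave_cost
      best <- max.col(t(sc), ties.method = "first")
      st <- rn[cbind(best, seq_along(ii))] * bias[best]
      # parabolic interpolation of the ACF peak for sub-sample lag
      lag_hat <- lags[best]
      interior <- best > 1L & best < length(lags)
      if (any(interior)) {
        j <- which(interior)
        ya <- rn[cbind(best[j] - 1L, j)]
        yb <- rn[cbind(best[j], j)]
        yc <- rn[cbind(best[j] + 1L, j)]
        den <- ya - 2 * yb + yc
        delta <- ifelse(abs(den) > 1e-12, 0.5 * (ya - yc) / den, 0)
        delta[abs(delta) > 1] <- 0
        lag_hat[j] <- lag_hat[j] + delta
      }
      f <- fs_a / lag_hat
      voiced <- st >= voicing_threshold & f >= fmin & f <= fmax
      f0[ii[voiced]] <- f[voiced]
      strength[ii] <- st
    }
  }
  f0 <- suppress_octave_jumps(f0, fmin, fmax)
  out <- data.frame(t = t_out, f0 = f0)
  attr(out, "fs") <- out_fs
  attr(out, "strength") <- strength
  class(out) <- c("f0_track", "data.frame")
  out
}

# Enforce continuity within voiced runs: no frame-to-frame jump > 40%.
suppress_octave_jumps <- function(f0, fmin, fmax, max_jump = 0.4) {
  n <- length(f0)
  if (n < 2L) return(f0)
  for (i in 2:n) {
    if (is.na(f0[i]) || is.na(f0[i - 1L])) next
    ratio <- f0[i] / f0[i - 1L]
    if (abs(ratio - 1) <= max_jump) next
    cand <- c(f0[i], f0[i] / 2, f0[i] * 2)
    cand <- cand[cand >= fmin & cand <= fmax]
    if (length(cand)) {
      dev <- abs(log(cand / f0[i - 1L]))
      best <- cand[which.min(dev)]
      if (abs(best / f0[i - 1L] - 1) <= max_jump) {
        f0[i] <- best
        next
      }
    }
    f0[i] <- NA_real_                      # unresolvable jump splits the run
  }
  f0
}

#' Segment vocalization events from an F0 track
#'
#' A vocalization event is a maximal uninterrupted run of voiced (F0-bearing)
#' frames. Runs separated by fewer than `min_gap_ms` of unvoiced frames are
#' merged first (`min_gap_ms = 0`, the default, keeps the strict
#' uninterrupted-run definition). Each event is annotated with its duration,
#' the time and value of its amplitude-envelope peak, and its maximum F0.
#'
#' @param f0 An `f0_track` from [track_f0()].
#' @param env An `envelope_track` on the same grid, or `NULL` (envelope
#'   annotations become `NA`).
#' @param min_gap_ms Merge threshold in ms; default 0.
#' @return Data frame with one row per event: `onset`, `offset` (s),
#'   `duration_ms`, `peak_env_time`, `peak_env_value`, `max_f0`.
#' @export
segment_vocalizations <- function(f0, env = NULL, min_gap_ms = 0) {
  voiced <- !is.na(f0$f0)
  n <- length(voiced)
  out0 <- data.frame(onset = numeric(0), offset = numeric(0), duration_ms = numeric(0),
                     peak_env_time = numeric(0), peak_env_value = numeric(0),
                     max_f0 = numeric(0))
  if (!any(voiced)) return(out0)
  dt <- if (n > 1L) f0$t[2] - f0$t[1] else 1 / 240
  if (!is.null(env) && nrow(env) != n) stop("f0 and env must share a grid")
  r <- rle(voiced)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (min_gap_ms > 0 && nrow(runs) > 1L) {
    merged <- runs[1L, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap_ms <- (runs$start[i] - merged$end[nrow(merged)] - 1L) * dt * 1000
      if (gap_ms < min_gap_ms) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  n_runs <- nrow(runs)
  onset <- nf <- pe_t <- pe_v <- mx <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    frames <- runs$start[i]:runs$end[i]
    onset[i] <- f0$t[runs$start[i]]
    nf[i] <- length(frames)
    if (!is.null(env)) {
      pk <- frames[which.max(env$env[frames])]
      pe_t[i] <- env$t[pk]; pe_v[i] <- env$env[pk]
    } else {
      pe_t[i] <- NA_real_; pe_v[i] <- NA_real_
    }
    mx[i] <- max(f0$f0[frames], na.rm = TRUE)
  }
  data.frame(onset = onset, offset = onset + nf * dt, duration_ms = nf * dt * 1000,
             peak_env_time = pe_t, peak_env_value = pe_v, max_f0 = mx)
}

#' Per-trial acoustic summary
#'
#' Computes the per-trial measures entering the condition-contrast models:
#' mean F0 over voiced frames, mean envelope (raw and, when participant-level
#' pooled statistics are supplied, z-scaled per participant), and the two
#' speech-rate measures: vocalization duration and vocalization interval,
#' each expressed in Hz as `1000 / mean(ms)`. The interval is the time
#' between envelope peaks of consecutive vocalization events.
#'
#' @param events Event table from [segment_vocalizations()].
#' @param f0 The trial's `f0_track`.
#' @param env The trial's `envelope_track`.
#' @param participant_env_stats Optional list/row with `mean` and `sd` of the
#'   participant's pooled envelope samples (all trials, all conditions); used
#'   for z-scaling. A zero SD is flagged as an error.
#' @return One-row data frame: `mean_f0`, `mean_env`, `mean_env_z`,
#'   `voc_duration_hz`, `voc_interval_hz`, `n_events`. Rates are `NA` (not
#'   zero) when too few events exist.
#' @export
trial_acoustic_summary <- function(events, f0, env, participant_env_stats = NULL) {
  n_ev <- nrow(events)
  mean_f0 <- if (any(!is.na(f0$f0))) mean(f0$f0, na.rm = TRUE) else NA_real_
  mean_env <- mean(env$env)
  mean_env_z <- NA_real_
  if (!is.null(participant_env_stats)) {
    s <- participant_env_stats
    if (!is.finite(s$sd) || s$sd <= 0) {
      stop("degenerate envelope: participant-level SD is zero, cannot z-scale")
    }
    mean_env_z <- (mean_env - s$mean) / s$sd
  }
  voc_duration_hz <- if (n_ev >= 1L) 1000 / mean(events$duration_ms) else NA_real_
  voc_interval_hz <- if (n_ev >= 2L) {
    1000 / mean(diff(events$peak_env_time) * 1000)
  } else NA_real_
  data.frame(mean_f0 = mean_f0, mean_env = mean_env, mean_env_z = mean_env_z,
             voc_duration_hz = voc_duration_hz, voc_interval_hz = voc_interval_hz,
             n_events = n_ev)
}
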
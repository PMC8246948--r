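# Kinematic processing of the vertical motion trace: zero-phase filtering,
# differentiation, beat (maximum extension) detection, deceleration
# annotation, and wavelet-ridge movement-frequency estimation.
#
# Sign convention: z increases upward. The instructed beat is a sudden halt
# at the *bottom* of the downstroke, so maximum extension = local minimum of
# z, and braking of the downstroke appears as positive (upward) acceleration.

# forward-backward filtering with odd (point-mirrored) edge padding so that
# constants and ramps pass through without edge transients
zp_filtfilt <- function(bf, x, np) {
  n <- length(x)
  np <- min(n - 1L, np)
  if (np < 1L) return(signal::filtfilt(bf, x))
  head_pad <- 2 * x[1L] - x[(np + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(np + 1L):(np + n)]
}

central_gradient <- function(y, dt) {
  n <- length(y)
  g <- numeric(n)
  if (n >= 3L) g[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (2 * dt)
  g[1L] <- (y[2L] - y[1L]) / dt
  g[n] <- (y[n] - y[n - 1L]) / dt
  g
}

#' Filter a motion trace and compute its derivatives
#'
#' Applies a zero-phase (forward-backward) first-order Butterworth low-pass
#' at `cutoff_hz` to the vertical position, then derives velocity and
#' acceleration by central differences, re-filtering each derivative with the
#' same filter. Zero-phase application keeps event times unshifted.
#'
#' @param motion A [motion_trace()].
#' @param cutoff_hz Low-pass cutoff in Hz (default 30).
#' @return A `kinematic_derivatives` data frame: `t` (s), `z_f` (cm),
#'   `v` (cm/s), `a` (cm/s^2), with attribute `fs`.
#' @export
smooth_and_differentiate <- function(motion, cutoff_hz = 30) {
  fs <- motion$fs
  if (fs <= 2 * cutoff_hz) stop("sampling rate must exceed twice the filter cutoff")
  bf <- signal::butter(1, cutoff_hz / (fs / 2), type = "low")
  dt <- 1 / fs
  np <- max(60L, 3L * ceiling(fs / cutoff_hz))
  z_f <- zp_filtfilt(bf, motion$z, np)
  v <- zp_filtfilt(bf, central_gradient(z_f, dt), np)
  a <- zp_filtfilt(bf, central_gradient(v, dt), np)
  out <- data.frame(t = motion$t, z_f = z_f, v = v, a = a)
  attr(out, "fs") <- fs
  class(out) <- c("kinematic_derivatives", "data.frame")
  out
}

#' Detect maximum-extension (beat) events
#'
#' Maximum extension is the lowest point of the downward stroke: a local
#' minimum of the filtered position whose excursion relative to the enclosing
#' cycle's flanking maxima is at least `min_amplitude_cm`, with successive
#' events at least `min_period_s` apart (deeper minima win ties).
#'
#' @param kin A `kinematic_derivatives` from [smooth_and_differentiate()].
#' @param min_period_s Minimum inter-beat spacing in s (default 0.4, well
#'   below the instructed 0.75-s cycle).
#' @param min_amplitude_cm Minimum cycle excursion in cm (default 2).
#' @return Data frame of events: `t_ext` (s), `cycle_index`.
#' @export
detect_max_extensions <- function(kin, min_period_s = 0.4, min_amplitude_cm = 2) {
  z <- kin$z_f
  n <- length(z)
  empty <- data.frame(t_ext = numeric(0), cycle_index = integer(0))
  if (n < 3L) return(empty)
  dz <- diff(z)
  is_min <- which(dz[-1L] >= 0 & dz[-(n - 1L)] < 0) + 1L
  if (!length(is_min)) return(empty)
  # excursion of the enclosing cycle: rise to the highest position within one
  # minimum period on each side (robust to micro-maxima from sensor noise)
  fs <- attr(kin, "fs")
  if (is.null(fs)) fs <- round(1 / stats::median(diff(kin$t)))
  w <- max(1L, round(min_period_s * fs))
  excursion <- vapply(is_min, function(i) {
    up_l <- max(z[max(1L, i - w):i])
    up_r <- max(z[i:min(n, i + w)])
    min(up_l, up_r) - z[i]
  }, numeric(1))
  cand <- is_min[excursion >= min_amplitude_cm]
  if (!length(cand)) return(empty)
  # enforce spacing, keeping deeper minima
  cand <- cand[order(z[cand])]
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || all(abs(kin$t[kept] - kin$t[i]) >= min_period_s)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  data.frame(t_ext = kin$t[kept], cycle_index = seq_along(kept))
}

#' Annotate beats with deceleration onset and magnitude
#'
#' For each maximum extension, the deceleration onset is the moment of peak
#' downward speed (the velocity minimum, i.e. the acceleration zero-crossing
#' into braking) in the preceding half second, and the maximum deceleration
#' is the absolutized extreme of the upward (braking) acceleration within the
#' `window_ms` window ending at the extension. Events closer than `edge_s` to
#' either end of the trace are flagged invalid and excluded from epoching.
#'
#' @param kin A `kinematic_derivatives`.
#' @param events Event table from [detect_max_extensions()].
#' @param window_ms Deceleration window before maximum extension (default 200).
#' @param search_s Lookback for the deceleration onset (default 0.5).
#' @param edge_s Edge exclusion margin in s (default 0.4).
#' @return `events` with added columns `t_decel_onset` (s), `max_decel`
#'   (cm/s^2, >= 0) and `valid` (logical).
#' @export
annotate_deceleration <- function(kin, events, window_ms = 200, search_s = 0.5,
                                  edge_s = 0.4) {
  if (!nrow(events)) {
    events$t_decel_onset <- numeric(0)
    events$max_decel <- numeric(0)
    events$valid <- logical(0)
    return(events)
  }
  t <- kin$t
  n <- length(t)
  t_end <- t[n]
  fs <- attr(kin, "fs")
  if (is.null(fs)) fs <- round(1 / stats::median(diff(t)))
  w <- round(window_ms / 1000 * fs)
  ws <- round(search_s * fs)
  onset <- decel <- numeric(nrow(events))
  for (j in seq_len(nrow(events))) {
    ie <- round((events$t_ext[j] - t[1L]) * fs) + 1L
    iw <- max(1L, ie - w):min(n, ie)
    decel[j] <- max(0, max(kin$a[iw]))
    io <- max(1L, ie - ws):max(1L, ie - 1L)
    onset[j] <- t[io[which.min(kin$v[io])]]
  }
  events$t_decel_onset <- onset
  events$max_decel <- decel
  events$valid <- events$t_ext - t[1L] >= edge_s & t_end - events$t_ext >= edge_s &
    !is.na(events$t_decel_onset)
  events
}

#' Cycle period implied by a target movement tempo
#'
#' @param target_hz Target movement frequency in Hz (default 80 BPM = 4/3 Hz,
#'   conventionally printed as 1.33 Hz).
#' @return Cycle period in ms.
#' @export
cycle_period_ms <- function(target_hz = 1.33) 1000 / target_hz

#' Tempo feedback-region bounds
#'
#' The feedback bar used in this paradigm keeps the mover inside a symmetric
#' region around the target tempo: a `region_fraction` of 0.2 around 80 BPM
#' spans 72--88 BPM.
#'
#' @param target_bpm Target tempo in beats per minute (default 80).
#' @param region_fraction Total relative width of the region (default 0.2).
#' @return Named vector `c(lower, upper)` in BPM.
#' @export
tempo_region_bounds <- function(target_bpm = 80, region_fraction = 0.2) {
  c(lower = target_bpm * (1 - region_fraction / 2),
    upper = target_bpm * (1 + region_fraction / 2))
}

#' Estimate time-varying movement frequency by wavelet ridge
#'
#' Continuous Morlet wavelet transform (omega0 = 6) of the filtered position
#' over `freq_range`; the ridge is the per-sample power argmax across
#' frequencies. Ridge statistics (mean, SD) and compliance -- the fraction of
#' ridge samples inside the target region `target_hz * (1 +/- region_fraction/2)`
#' -- are computed after trimming `trim_s` from each edge.
#'
#' @param kin A `kinematic_derivatives`.
#' @param target_hz Target frequency in Hz (default 4/3).
#' @param region_fraction Relative width of the compliance region (default 0.2).
#' @param freq_range Analyzed band in Hz (default 0.5--3).
#' @param n_freq Number of log-spaced frequencies (default 96).
#' @param omega0 Morlet center frequency parameter (default 6).
#' @param trim_s Edge trim for ridge statistics in s (default 1).
#' @return A `frequency_estimate` list: `t`, `freq` (ridge, Hz),
#'   `trial_mean`, `trial_sd`, `compliance`, `region_hz`.
#' @export
estimate_movement_frequency <- function(kin, target_hz = 4 / 3, region_fraction = 0.2,
                                        freq_range = c(0.5, 3), n_freq = 96,
                                        omega0 = 6, trim_s = 1) {
  fs <- attr(kin, "fs")
  if (is.null(fs)) fs <- round(1 / stats::median(diff(kin$t)))
  n <- nrow(kin)
  if (n / fs < 3 / freq_range[1]) {
    stop("trace shorter than 3 cycles at the lowest analyzed frequency")
  }
  x <- kin$z_f - mean(kin$z_f)
  nfft <- stats::nextn(n)
  X <- stats::fft(c(x, numeric(nfft - n)))
  w <- 2 * pi * fs * c(0:(nfft %/% 2), -((nfft - nfft %/% 2 - 1):1)) / nfft
  freqs <- exp(seq(log(freq_range[1]), log(freq_range[2]), length.out = n_freq))
  power <- matrix(0, nrow = n, ncol = n_freq)
  for (j in seq_len(n_freq)) {
    s <- omega0 / (2 * pi * freqs[j])
    psi <- ifelse(w > 0, exp(-0.5 * (s * w - omega0)^2), 0)
    Wt <- stats::fft(X * psi, inverse = TRUE)[seq_len(n)] / nfft
    power[, j] <- Mod(Wt)^2
  }
  ridge <- freqs[max.col(power, ties.method = "first")]
  keep <- kin$t >= kin$t[1L] + trim_s & kin$t <= kin$t[n] - trim_s
  region <- c(target_hz * (1 - region_fraction / 2), target_hz * (1 + region_fraction / 2))
  rk <- ridge[keep]
  structure(list(t = kin$t, freq = ridge,
                 trial_mean = mean(rk), trial_sd = stats::sd(rk),
                 compliance = mean(rk >= region[1] & rk <= region[2]),
                 region_hz = region),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("<frequency_estimate> mean %.3f Hz (SD %.3f), compliance %.2f in [%.3f, %.3f] Hz\n",
              x$trial_mean, x$trial_sd, x$compliance, x$region_hz[1], x$region_hz[2]))
  invisible(x)
}
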
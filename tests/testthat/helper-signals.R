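# shared fixture builders (all fixtures are generated in code)

make_tone <- function(freq, dur = 1, fs = 44100, amp = 0.5) {
  audio_track(amp * sin(2 * pi * freq * (0:(round(dur * fs) - 1)) / fs), fs)
}

# harmonic complex with 1/k roll-off, peak-normalized to `amp`
make_harmonic <- function(f0, dur = 1, fs = 44100, n_h = 6, amp = 0.3) {
  tt <- (0:(round(dur * fs) - 1)) / fs
  x <- 0
  for (k in 1:n_h) x <- x + sin(2 * pi * f0 * k * tt) / k
  audio_track(amp * x / max(abs(x)), fs)
}

# f0 track with voiced spans given as a matrix of (onset, offset) in s
make_f0_track <- function(spans, dur, f0_hz = 200, fs = 240) {
  n <- floor(dur * fs) + 1L
  t <- (0:(n - 1)) / fs
  f0 <- rep(NA_real_, n)
  for (i in seq_len(nrow(spans))) {
    f0[t >= spans[i, 1] & t < spans[i, 2]] <- f0_hz
  }
  out <- data.frame(t = t, f0 = f0)
  attr(out, "fs") <- fs
  class(out) <- c("f0_track", "data.frame")
  out
}

make_env_track <- function(env, fs = 240) {
  out <- data.frame(t = (seq_along(env) - 1) / fs, env = env)
  attr(out, "fs") <- fs
  class(out) <- c("envelope_track", "data.frame")
  out
}

# one-to-one beat matching at a tolerance; returns recall and precision.
# Matching is evaluated on the trace interior: beats at the very edges are
# unobservable in principle and are excluded downstream by the edge rule.
match_beats <- function(detected, truth, tol = 0.025, interior = NULL) {
  if (!is.null(interior)) {
    detected <- detected[detected >= interior[1] & detected <= interior[2]]
    truth <- truth[truth >= interior[1] & truth <= interior[2]]
  }
  if (!length(truth)) return(c(recall = NA, precision = NA))
  used <- rep(FALSE, length(detected))
  hit <- 0L
  for (b in truth) {
    d <- abs(detected - b)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol) { used[j] <- TRUE; hit <- hit + 1L }
  }
  c(recall = hit / length(truth),
    precision = if (length(detected)) sum(used) / length(detected) else NA)
}

quietly <- function(expr) suppressMessages(suppressWarnings(expr))
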
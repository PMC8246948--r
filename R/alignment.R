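# Beat-locked epoching of acoustic trajectories, condition averages, the
# surrogate random-pairing baseline, and deceleration-window feature
# extraction.

#' The fixed epoch grid in ms
#'
#' Epochs span an 800-ms window (-400 to +400 ms) around maximum extension on
#' the 240-Hz grid: 193 samples. The grid is computed once so it is bitwise
#' identical across all epochs.
#'
#' @param window_ms Length-2 window in ms (default `c(-400, 400)`).
#' @param fs Grid rate in Hz (default 240).
#' @return Numeric vector of relative times in ms.
#' @export
epoch_rel_grid_ms <- function(window_ms = c(-400, 400), fs = 240) {
  i0 <- round(window_ms[1] * fs / 1000)
  i1 <- round(window_ms[2] * fs / 1000)
  (i0:i1) * 1000 / fs
}

#' Extract beat-locked epochs of the acoustic tracks
#'
#' One epoch per valid beat whose full window lies inside the trial. Tracks
#' are sliced by nearest-grid alignment (the beat time is snapped to the
#' nearest 240-Hz sample; no interpolation beyond one sample). F0 retains its
#' missingness (unvoiced frames stay `NA`).
#'
#' @param beats Beat table with `t_ext`, `cycle_index` and optionally `valid`
#'   (from [annotate_deceleration()]).
#' @param env The trial's `envelope_track` (possibly z-scaled).
#' @param f0 The trial's `f0_track`, or `NULL`.
#' @param window_ms Epoch window in ms (default `c(-400, 400)`).
#' @return An `epoch_set`: list with `rel_t_ms` (shared grid), `env` and `f0`
#'   matrices (`length(rel_t_ms)` rows, one column per epoch), `meta` (data
#'   frame: `cycle_index`, `t_ext`), and `n_skipped` (beats too close to a
#'   trial edge).
#' @export
extract_epochs <- function(beats, env, f0 = NULL, window_ms = c(-400, 400)) {
  fs <- attr(env, "fs")
  if (is.null(fs)) fs <- 240
  rel_ms <- epoch_rel_grid_ms(window_ms, fs)
  half_lo <- round(window_ms[1] * fs / 1000)
  half_hi <- round(window_ms[2] * fs / 1000)
  n <- nrow(env)
  use <- if ("valid" %in% names(beats)) which(beats$valid) else seq_len(nrow(beats))
  i0 <- round(beats$t_ext[use] * fs) + 1L
  inside <- (i0 + half_lo) >= 1L & (i0 + half_hi) <= n
  keep <- use[inside]
  idx <- outer(half_lo:half_hi, round(beats$t_ext[keep] * fs) + 1L, "+")
  env_m <- matrix(env$env[idx], nrow = length(rel_ms))
  f0_m <- if (!is.null(f0)) matrix(f0$f0[idx], nrow = length(rel_ms)) else
    matrix(numeric(0), nrow = length(rel_ms), ncol = 0)
  structure(list(
    rel_t_ms = rel_ms,
    env = env_m,
    f0 = f0_m,
    meta = data.frame(cycle_index = beats$cycle_index[keep], t_ext = beats$t_ext[keep]),
    n_skipped = sum(!inside)), class = "epoch_set")
}

#' Combine epoch sets across trials
#'
#' @param sets List of `epoch_set` objects.
#' @param meta_extra Data frame with one row per set (e.g. participant,
#'   trial, condition), recycled across that set's epochs.
#' @return A single `epoch_set` whose `meta` carries the extra keys.
#' @export
bind_epoch_sets <- function(sets, meta_extra) {
  keep <- vapply(sets, function(s) ncol(s$env) > 0L, logical(1))
  if (!any(keep)) {
    return(structure(list(rel_t_ms = sets[[1L]]$rel_t_ms,
                          env = sets[[1L]]$env, f0 = sets[[1L]]$f0,
                          meta = cbind(meta_extra[0, , drop = FALSE], sets[[1L]]$meta),
                          n_skipped = sum(vapply(sets, `[[`, integer(1), "n_skipped"))),
                     class = "epoch_set"))
  }
  grid <- sets[[which(keep)[1L]]]$rel_t_ms
  meta <- do.call(rbind, lapply(which(keep), function(i) {
    m <- sets[[i]]$meta
    cbind(meta_extra[rep(i, nrow(m)), , drop = FALSE], m, row.names = NULL)
  }))
  structure(list(rel_t_ms = grid,
                 env = do.call(cbind, lapply(sets[keep], `[[`, "env")),
                 f0 = do.call(cbind, lapply(sets[keep], `[[`, "f0")),
                 meta = meta,
                 n_skipped = sum(vapply(sets, `[[`, integer(1), "n_skipped"))),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs x %d samples (%.0f..%.0f ms), %d skipped at edges\n",
              ncol(x$env), length(x$rel_t_ms), min(x$rel_t_ms), max(x$rel_t_ms), x$n_skipped))
  invisible(x)
}

#' Long-format data frame of an epoch set
#'
#' @param epochs An `epoch_set` with keyed `meta`.
#' @return Data frame with one row per (epoch, grid point): `rel_t_ms`,
#'   `env`, `f0`, plus all `meta` columns.
#' @export
as_epochs_df <- function(epochs) {
  n_ep <- ncol(epochs$env)
  n_t <- length(epochs$rel_t_ms)
  if (n_ep == 0L) {
    return(cbind(epochs$meta[0, , drop = FALSE],
                 data.frame(rel_t_ms = numeric(0), env = numeric(0), f0 = numeric(0))))
  }
  meta <- epochs$meta[rep(seq_len(n_ep), each = n_t), , drop = FALSE]
  out <- cbind(meta,
               data.frame(rel_t_ms = rep(epochs$rel_t_ms, n_ep),
                          env = as.vector(epochs$env),
                          f0 = if (length(epochs$f0)) as.vector(epochs$f0) else NA_real_),
               row.names = NULL)
  out
}

#' Average beat-locked trajectories
#'
#' Pointwise mean and standard error of the epoch trajectories per group.
#' Missing F0 samples are ignored pointwise. Two aggregations are available:
#' `"pooled"` treats every epoch as one observation; `"participant"` first
#' averages within participant, then across participants (equal weight per
#' participant).
#'
#' @param epochs An `epoch_set` whose `meta` contains the `by` columns (and
#'   `participant_id` for the participant weighting).
#' @param response `"env"` or `"f0"`.
#' @param by Grouping columns in `meta` (default `"condition"`).
#' @param weights `"pooled"` or `"participant"`.
#' @return Data frame: grouping columns, `rel_t_ms`, `mean`, `se`, `n`.
#' @export
average_trajectories <- function(epochs, response = c("env", "f0"),
                                 by = "condition", weights = c("pooled", "participant")) {
  response <- match.arg(response)
  weights <- match.arg(weights)
  mat <- epochs[[response]]
  if (ncol(mat) == 0L) {
    warning("no epochs to average")
    return(NULL)
  }
  grp <- interaction(epochs$meta[, by, drop = FALSE], drop = TRUE, sep = ":")
  out <- lapply(levels(grp), function(g) {
    cols <- which(grp == g)
    sub <- mat[, cols, drop = FALSE]
    if (weights == "participant") {
      pid <- epochs$meta$participant_id[cols]
      sub <- do.call(cbind, lapply(unique(pid), function(p) {
        rowMeans(sub[, pid == p, drop = FALSE], na.rm = TRUE)
      }))
    }
    n <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    key <- epochs$meta[cols[1L], by, drop = FALSE]
    cbind(key[rep(1L, length(m)), , drop = FALSE],
          data.frame(rel_t_ms = epochs$rel_t_ms, mean = m,
                     se = s / sqrt(pmax(n, 1L)), n = n),
          row.names = NULL)
  })
  do.call(rbind, out)
}

#' Plot averaged beat-locked trajectories
#'
#' @param x Output of [average_trajectories()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_trajectories <- function(x, ...) {
  by_col <- setdiff(names(x), c("rel_t_ms", "mean", "se", "n"))[1L]
  groups <- unique(x[[by_col]])
  grid <- sort(unique(x$rel_t_ms))
  m <- sapply(groups, function(g) x$mean[x[[by_col]] == g][order(x$rel_t_ms[x[[by_col]] == g])])
  graphics::matplot(grid, m, type = "l", lty = 1, xlab = "time from maximum extension (ms)",
                    ylab = "mean response", ...)
  graphics::abline(v = 0, lty = 2)
  graphics::legend("topleft", legend = as.character(groups), col = seq_along(groups),
                   lty = 1, bty = "n")
  invisible(m)
}

#' Build the surrogate random-pairing baseline
#'
#' Each passive-condition trial's speech is paired, uniformly at random
#' within participant, with the beat times of one of that participant's
#' movement trials -- without permuting either time series. Donor beats
#' beyond the reach of the speech trial are dropped by the usual edge rule.
#' Participants lacking a passive or a movement trial are excluded.
#'
#' @param trial_index Data frame with one row per trial: `participant_id`,
#'   `trial_id`, `condition`.
#' @param pairing_seed Integer seed making the pairing reproducible.
#' @return Data frame of pairs: `participant_id`, `speech_trial_id`
#'   (passive), `donor_trial_id` (movement), `donor_condition`.
#' @export
build_surrogate_pairing <- function(trial_index, pairing_seed = 1) {
  set.seed(as.integer(pairing_seed))
  out <- list()
  for (p in unique(trial_index$participant_id)) {
    sub <- trial_index[trial_index$participant_id == p, ]
    passive <- sub$trial_id[sub$condition == "passive"]
    movement <- sub[sub$condition != "passive", ]
    if (!length(passive) || !nrow(movement)) next
    pick <- sample.int(nrow(movement), length(passive), replace = TRUE)
    out[[p]] <- data.frame(participant_id = p, speech_trial_id = passive,
                           donor_trial_id = movement$trial_id[pick],
                           donor_condition = as.character(movement$condition[pick]),
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no participant has both a passive and a movement trial")
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Deceleration-window acoustic features
#'
#' For every valid beat, the closed window `[t_ext - 200 ms, t_ext]` is
#' intersected with each vocalization event overlapping it; one observation
#' is produced per (beat, vocalization) pair, carrying the acoustic maxima
#' over the overlap and the beat's maximum deceleration.
#'
#' @param beats Annotated beat table ([annotate_deceleration()]).
#' @param events Vocalization events ([segment_vocalizations()]).
#' @param env The trial's `envelope_track` (possibly z-scaled).
#' @param f0 The trial's `f0_track`.
#' @param window_ms Length-2 window relative to `t_ext` in ms (default
#'   `c(-200, 0)`).
#' @return Data frame: `cycle_index`, `vocalization_id`, `max_decel`,
#'   `max_env`, `max_f0`.
#' @export
impulse_window_features <- function(beats, events, env, f0, window_ms = c(-200, 0)) {
  out <- data.frame(cycle_index = integer(0), vocalization_id = integer(0),
                    max_decel = numeric(0), max_env = numeric(0), max_f0 = numeric(0))
  if (!nrow(beats) || !nrow(events)) return(out)
  use <- if ("valid" %in% names(beats)) which(beats$valid) else seq_len(nrow(beats))
  fs <- attr(env, "fs")
  if (is.null(fs)) fs <- 240
  t1 <- env$t[1L]
  n_env <- nrow(env)
  eps <- 1e-9
  rows <- list()
  for (j in use) {
    w0 <- beats$t_ext[j] + window_ms[1] / 1000
    w1 <- beats$t_ext[j] + window_ms[2] / 1000
    hits <- which(events$onset <= w1 & events$offset > w0)
    for (h in hits) {
      # window closed at both ends; the event interval is half-open at its
      # offset (the offset frame itself is unvoiced)
      lo <- max(events$onset[h], w0)
      hi <- min(events$offset[h] - 1 / (2 * fs), w1)
      i0 <- max(1L, as.integer(ceiling((lo - t1) * fs - eps)) + 1L)
      i1 <- min(n_env, as.integer(floor((hi - t1) * fs + eps)) + 1L)
      if (i1 < i0) next
      sel <- i0:i1
      f0v <- f0$f0[sel]
      rows[[length(rows) + 1L]] <- c(beats$cycle_index[j], h, beats$max_decel[j],
                                     max(env$env[sel]),
                                     if (any(!is.na(f0v))) max(f0v, na.rm = TRUE) else NA_real_)
    }
  }
  if (length(rows)) {
    m <- do.call(rbind, rows)
    data.frame(cycle_index = as.integer(m[, 1]), vocalization_id = as.integer(m[, 2]),
               max_decel = m[, 3], max_env = m[, 4], max_f0 = m[, 5])
  } else out
}

#' Trial-level aggregation of deceleration-window observations
#'
#' Averages the per-(beat, vocalization) maxima within trial, the unit of
#' analysis of the deceleration regression.
#'
#' @param obs Data frame of observations with keys `participant_id`,
#'   `trial_id`, `condition` plus the feature columns.
#' @return One row per trial with means of `max_decel`, `max_env`, `max_f0`
#'   and the observation count `n_obs`.
#' @export
aggregate_impulse_observations <- function(obs) {
  if (!nrow(obs)) {
    return(data.frame(participant_id = character(0), trial_id = character(0),
                      condition = character(0), max_decel = numeric(0),
                      max_env = numeric(0), max_f0 = numeric(0), n_obs = integer(0)))
  }
  key <- interaction(obs$participant_id, obs$trial_id, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    sub <- obs[key == k, ]
    data.frame(participant_id = sub$participant_id[1L], trial_id = sub$trial_id[1L],
               condition = sub$condition[1L],
               max_decel = mean(sub$max_decel, na.rm = TRUE),
               max_env = mean(sub$max_env, na.rm = TRUE),
               max_f0 = mean(sub$max_f0, na.rm = TRUE),
               n_obs = nrow(sub))
  })
  do.call(rbind, rows)
}
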
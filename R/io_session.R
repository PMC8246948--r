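#' @keywords internal
"_PACKAGE"

# ---- core containers -------------------------------------------------------

#' Construct an audio track
#'
#' A mono audio signal with its sampling rate. Samples are dimensionless
#' normalized amplitudes in \[-1, 1\].
#'
#' @param samples Numeric vector of finite sample values.
#' @param fs Sampling rate in Hz (default 44100, the recording rate used for
#'   headset microphones in this paradigm).
#' @return An object of class `audio_track`: a list with `samples` and `fs`.
#' @export
audio_track <- function(samples, fs = 44100) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("audio track must contain at least one sample")
  if (!all(is.finite(samples))) stop("audio samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  structure(list(samples = samples, fs = fs), class = "audio_track")
}

#' @export
print.audio_track <- function(x, ...) {
  cat(sprintf("<audio_track> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Duration of an audio track in seconds
#' @param audio An `audio_track`.
#' @return Duration in seconds.
#' @export
audio_duration <- function(audio) length(audio$samples) / audio$fs

#' Construct a vertical motion trace
#'
#' Uniformly sampled vertical position of the moving limb, in cm, as recorded
#' by a single motion-tracking sensor (240 Hz by convention).
#'
#' @param z Vertical position in cm.
#' @param fs Sampling rate in Hz (default 240).
#' @param t Optional time vector in seconds; defaults to a uniform grid
#'   starting at 0. Must be uniform to within one sample period.
#' @return An object of class `motion_trace`: list with `t`, `z`, `fs`.
#' @export
motion_trace <- function(z, fs = 240, t = NULL) {
  z <- as.numeric(z)
  if (length(z) < 2L) stop("motion trace needs at least 2 samples")
  if (!all(is.finite(z))) stop("motion positions must be finite")
  if (is.null(t)) {
    t <- (seq_along(z) - 1) / fs
  } else {
    t <- as.numeric(t)
    if (length(t) != length(z)) stop("t and z must have equal length")
    dt <- diff(t)
    if (any(dt <= 0)) stop("motion timestamps must be strictly increasing")
    # non-uniform sampling beyond one sample period signals dropped frames
    if (any(abs(dt - 1 / fs) > 1 / fs)) {
      stop("non-uniform motion sampling: timestamp gaps exceed one sample period")
    }
  }
  structure(list(t = t, z = z, fs = fs), class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d samples @ %g Hz (%.2f s), z in [%.2f, %.2f] cm\n",
              length(x$z), x$fs, diff(range(x$t)), min(x$z), max(x$z)))
  invisible(x)
}

# ---- WAV read/write (PCM 16-bit mono) --------------------------------------

#' Read a PCM WAV file as a mono audio track
#'
#' Minimal RIFF/WAVE reader for 16-bit PCM. Stereo files are rejected: the
#' pipeline is defined for single-channel headset recordings.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_track()] with samples scaled to \[-1, 1\].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        format    = readBin(raw_fmt[1:2], "integer", 1, size = 2, endian = "little", signed = FALSE),
        channels  = readBin(raw_fmt[3:4], "integer", 1, size = 2, endian = "little", signed = FALSE),
        fs        = readBin(raw_fmt[5:8], "integer", 1, size = 4, endian = "little"),
        bits      = readBin(raw_fmt[15:16], "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      dat <- readBin(con, "integer", sz / 2L, size = 2, endian = "little", signed = TRUE)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("malformed WAV (missing fmt/data chunk): ", path)
  if (fmt$format != 1L || fmt$bits != 16L) stop("only 16-bit PCM WAV is supported")
  if (fmt$channels != 1L) stop("stereo audio not supported: expected mono, got ",
                               fmt$channels, " channels")
  audio_track(dat / 32768, fs = fmt$fs)
}

#' Write a mono audio track as 16-bit PCM WAV
#'
#' @param audio An [audio_track()]; samples are clipped to \[-1, 1\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path) {
  x <- pmin(1, pmax(-1, audio$samples))
  pcm <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")            # PCM, mono
  writeBin(as.integer(audio$fs), con, size = 4, endian = "little")
  writeBin(as.integer(audio$fs * 2L), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")           # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# ---- motion CSV ------------------------------------------------------------

#' Read a motion-capture CSV
#'
#' Expected columns: `time_ms, x_cm, y_cm, z_cm`. Only the vertical channel
#' (z) is used downstream; time is converted from ms to s. The sampling rate
#' is inferred from the median timestamp step and validated for uniformity.
#'
#' @param path CSV path.
#' @return A [motion_trace()].
#' @export
read_motion_csv <- function(path) {
  if (!file.exists(path)) stop("motion CSV not found: ", path)
  d <- utils::read.csv(path)
  need <- c("time_ms", "z_cm")
  if (!all(need %in% names(d))) stop("motion CSV must contain columns time_ms and z_cm")
  t <- d$time_ms / 1000
  fs <- round(1 / stats::median(diff(t)))
  motion_trace(d$z_cm, fs = fs, t = t)
}

#' Write a motion trace as CSV
#'
#' Writes the repository's motion dialect (`time_ms, x_cm, y_cm, z_cm`); the
#' unused horizontal channels are zero-filled.
#'
#' @param motion A [motion_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion_csv <- function(motion, path) {
  d <- data.frame(time_ms = motion$t * 1000, x_cm = 0, y_cm = 0, z_cm = motion$z)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# ---- session manifest ------------------------------------------------------

.gs_conditions <- c("passive", "wrist", "arm")
.gs_sexes <- c("female", "male")

#' Validate a session manifest data frame
#' @noRd
validate_manifest <- function(d, base_dir = NULL, check_files = TRUE) {
  need <- c("participant_id", "sex", "condition", "trial_id", "audio_path", "motion_path")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("manifest missing columns: ", paste(miss, collapse = ", "))
  bad_cond <- setdiff(unique(d$condition), .gs_conditions)
  if (length(bad_cond)) {
    stop("unknown condition label(s): ", paste(bad_cond, collapse = ", "),
         " (allowed: ", paste(.gs_conditions, collapse = ", "), ")")
  }
  bad_sex <- setdiff(unique(d$sex), .gs_sexes)
  if (length(bad_sex)) stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "))
  key <- paste(d$participant_id, d$trial_id)
  if (anyDuplicated(key)) stop("participant/trial pairs must be unique")
  has_motion <- !is.na(d$motion_path) & nzchar(d$motion_path)
  if (any(d$condition == "passive" & has_motion)) {
    stop("passive entries must not reference a motion file (mislabeled condition?)")
  }
  if (any(d$condition != "passive" & !has_motion)) {
    stop("movement-condition entries must reference a motion file")
  }
  if (check_files) {
    paths <- c(d$audio_path, d$motion_path[has_motion])
    if (!is.null(base_dir)) paths <- file.path(base_dir, paths)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("referenced file(s) missing: ", paste(missing, collapse = ", "))
  }
  d$condition <- factor(d$condition, levels = .gs_conditions)
  d$sex <- factor(d$sex, levels = .gs_sexes)
  d
}

#' Load and validate a session manifest
#'
#' The manifest is one CSV per recording session, one row per trial, with
#' columns `participant_id, sex, condition, trial_id, audio_path, motion_path`.
#' Conditions form a closed vocabulary (`passive`, `wrist`, `arm`); passive
#' trials carry no motion file. Paths are interpreted relative to the manifest
#' location.
#'
#' @param manifest_path Path to the manifest CSV.
#' @param check_files Verify that every referenced file exists (default TRUE).
#' @return A `session_manifest`: a validated data frame with an attribute
#'   `base_dir` used to resolve relative paths.
#' @export
load_session <- function(manifest_path, check_files = TRUE) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  d <- utils::read.csv(manifest_path, colClasses = "character")
  d$motion_path[is.na(d$motion_path)] <- ""
  base_dir <- dirname(normalizePath(manifest_path))
  d <- validate_manifest(d, base_dir = base_dir, check_files = check_files)
  attr(d, "base_dir") <- base_dir
  class(d) <- c("session_manifest", "data.frame")
  d
}

#' Write a session manifest CSV
#'
#' @param manifest Data frame with the manifest columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  d <- as.data.frame(manifest)
  d <- d[, c("participant_id", "sex", "condition", "trial_id", "audio_path", "motion_path")]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Load one trial's audio (and motion, for movement conditions)
#'
#' @param entry One manifest row (data frame of one row or list).
#' @param base_dir Directory against which relative paths are resolved.
#' @return A `trial_record`: list with `entry`, `audio` ([audio_track()]) and
#'   `motion` ([motion_trace()] or `NULL` for passive trials). Motion duration
#'   must agree with audio duration to within 1 s.
#' @export
load_trial <- function(entry, base_dir = ".") {
  entry <- as.list(entry)
  audio <- read_wav(file.path(base_dir, entry$audio_path))
  motion <- NULL
  if (!is.null(entry$motion_path) && !is.na(entry$motion_path) && nzchar(entry$motion_path)) {
    motion <- read_motion_csv(file.path(base_dir, entry$motion_path))
    if (abs(diff(range(motion$t)) - audio_duration(audio)) > 1) {
      stop("motion and audio durations differ by more than 1 s for trial ", entry$trial_id)
    }
  }
  structure(list(entry = entry, audio = audio, motion = motion), class = "trial_record")
}
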
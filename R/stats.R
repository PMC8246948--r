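# The three statistical analyses of the paradigm:
#  1. mixed-effects condition contrasts on per-trial acoustic summaries,
#  2. penalized-spline (GAM) smooths of beat-locked acoustic trajectories
#     with difference smooths against the passive condition,
#  3. mixed-effects regression of deceleration-window acoustic peaks on
#     maximum deceleration (envelope: slope; F0: condition x deceleration
#     interaction, wrist as reference).
# Model fitting delegates to lmerTest/mgcv; this module owns the model
# specifications and contrasts.

lmer_coef_table <- function(fit) {
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), b = sm[, "Estimate"], se = sm[, "Std. Error"],
             df = sm[, "df"], stat = sm[, "t value"], p = sm[, "Pr(>|t|)"],
             row.names = NULL)
}

# fit with a random-slope structure, falling back to intercept-only on
# convergence failure or singular fit; returns list(fit, fallback)
fit_with_fallback <- function(formula_slope, formula_int, data) {
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(formula_slope, data = data,
                     control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) NULL)
  ok <- !is.null(fit) && !lme4::isSingular(fit, tol = 1e-4) &&
    length(fit@optinfo$conv$lme4$messages) == 0L
  if (ok) return(list(fit = fit, fallback = FALSE))
  fit <- suppressMessages(suppressWarnings(lmerTest::lmer(formula_int, data = data)))
  list(fit = fit, fallback = TRUE)
}

#' Mixed-effects condition contrasts on trial acoustic summaries
#'
#' Fits `response ~ condition + (1 | participant)` with the passive condition
#' as reference, adding a sex term for F0 responses, and returns the
#' wrist-vs-passive and arm-vs-passive contrasts.
#'
#' @param trial_summaries Data frame with one row per trial: columns
#'   `participant_id`, `sex`, `condition` and the response columns
#'   (`mean_env_z`, `mean_env`, `mean_f0`).
#' @param response One of `"env_z"`, `"env"`, `"f0"`.
#' @return A `gs_condition_effects` object: list with `estimates` (term, b,
#'   se, df, stat, p), `response`, and the underlying `fit`.
#' @export
fit_condition_effects <- function(trial_summaries,
                                  response = c("env_z", "env", "f0")) {
  response <- match.arg(response)
  ycol <- switch(response, env_z = "mean_env_z", env = "mean_env", f0 = "mean_f0")
  d <- trial_summaries
  d$y <- d[[ycol]]
  d <- d[!is.na(d$y), ]
  d$condition <- factor(as.character(d$condition), levels = .gs_conditions)
  d$condition <- droplevels(d$condition)
  if (nlevels(d$condition) < 2L) stop("condition contrasts need at least 2 conditions")
  if (length(unique(d$participant_id)) < 2L) stop("need at least 2 participants")
  d$participant_id <- factor(d$participant_id)
  form <- if (response == "f0") y ~ condition + sex + (1 | participant_id)
          else y ~ condition + (1 | participant_id)
  if (response == "f0") d$sex <- factor(as.character(d$sex), levels = .gs_sexes)
  fit <- lmerTest::lmer(form, data = d)
  structure(list(estimates = lmer_coef_table(fit), response = response, fit = fit,
                 n_trials = nrow(d)),
            class = "gs_condition_effects")
}

#' @export
print.gs_condition_effects <- function(x, digits = 4, ...) {
  cat(sprintf("Condition contrasts (%s response), %d trials\n", x$response, x$n_trials))
  est <- x$estimates
  est[, -1] <- lapply(est[, -1], signif, digits = digits)
  print(est, row.names = FALSE)
  invisible(x)
}

#' Penalized-spline smooths of beat-locked acoustic trajectories
#'
#' Fits a GAM of the epoched response over time-from-maximum-extension with
#' one independently-penalized (centered) smooth per condition, parametric
#' condition terms, a participant random intercept and -- where the data
#' support it -- a participant random slope over time. Per-condition smooth
#' p-values test nonlinearity of each trajectory. Difference curves against
#' the reference condition are computed from the fitted model with pointwise
#' standard errors (random-effect columns cancel in the difference), and the
#' location of each difference peak is reported with a Wald p-value at the
#' peak.
#'
#' Separate per-condition smooths are used rather than a shared smooth plus
#' ordered-factor difference smooths: under penalization the shared-smooth
#' construction lets the reference trajectory absorb structure common to the
#' movement conditions, which distorts both the reference curve and weak
#' difference curves.
#'
#' @param epochs_df Long-format epochs ([as_epochs_df()]) with columns
#'   `rel_t_ms`, `participant_id`, `condition`, `sex` and the response.
#' @param response `"env"` or `"f0"`.
#' @param k Spline basis dimension (default 20).
#' @param reference Reference condition. Default: `"surrogate"` when present
#'   (the passive condition enters trajectory space through the surrogate
#'   pairing, since passive trials have no beats), else `"passive"`, else
#'   the first level.
#' @param random_slopes Attempt participant random slopes (default TRUE).
#' @param use_bam Use [mgcv::bam()] for large data (default: when more than
#'   50000 rows).
#' @return A `gs_trajectory_smooths` object: `fitted` (per-condition fitted
#'   trajectory with pointwise SE over the epoch grid, random effects
#'   excluded), `difference` (condition minus reference with pointwise SE,
#'   `peak_rel_t_ms`, `peak_p`), `smooth_tests` (per-smooth nonlinearity
#'   tests), `parametric` (term, b, se, stat, p), `fallback`, `fit`.
#' @export
fit_trajectory_smooths <- function(epochs_df, response = c("env", "f0"), k = 20,
                                   reference = NULL, random_slopes = TRUE,
                                   use_bam = NULL) {
  response <- match.arg(response)
  d <- epochs_df
  d$y <- d[[response]]
  d <- d[!is.na(d$y), ]
  d$condition <- factor(as.character(d$condition))
  if (is.null(reference)) {
    reference <- if ("surrogate" %in% levels(d$condition)) "surrogate"
                 else if ("passive" %in% levels(d$condition)) "passive"
                 else levels(d$condition)[1L]
  }
  d$condition <- stats::relevel(d$condition, ref = reference)
  counts <- table(d$condition) / length(unique(d$rel_t_ms))
  if (any(counts < 10)) stop("fewer than 10 epochs for condition(s): ",
                             paste(names(counts)[counts < 10], collapse = ", "))
  d$participant_id <- factor(d$participant_id)
  has_sex <- response == "f0" && "sex" %in% names(d) && length(unique(d$sex)) > 1L
  if (has_sex) d$sex <- factor(as.character(d$sex))
  if (is.null(use_bam)) use_bam <- nrow(d) > 50000
  fitter <- if (use_bam) {
    function(f, data) mgcv::bam(f, data = data, discrete = TRUE)
  } else {
    function(f, data) mgcv::gam(f, data = data)
  }

  base <- "y ~ condition + s(rel_t_ms, by = condition, k = k) + s(participant_id, bs = 're')"
  if (has_sex) base <- paste(base, "+ sex")
  form_slope <- stats::as.formula(paste(base, "+ s(rel_t_ms, participant_id, bs = 're')"))
  form_int <- stats::as.formula(base)
  fallback <- FALSE
  fit <- NULL
  if (random_slopes) {
    fit <- tryCatch(fitter(form_slope, data = d), error = function(e) NULL)
  }
  if (is.null(fit)) {
    fallback <- random_slopes
    fit <- fitter(form_int, data = d)
  }

  sm <- summary(fit)
  st <- as.data.frame(sm$s.table)
  st$smooth <- rownames(sm$s.table)
  rownames(st) <- NULL
  pt <- as.data.frame(sm$p.table)
  parametric <- data.frame(term = rownames(sm$p.table), b = pt[, 1], se = pt[, 2],
                           stat = pt[, 3], p = pt[, 4], row.names = NULL)

  grid <- sort(unique(d$rel_t_ms))
  ref_pid <- levels(d$participant_id)[1L]
  exclude <- c("s(participant_id)", "s(rel_t_ms,participant_id)")
  newdata_for <- function(cn) {
    nd <- data.frame(rel_t_ms = grid, condition = factor(cn, levels(d$condition)),
                     participant_id = factor(ref_pid, levels(d$participant_id)))
    if (has_sex) nd$sex <- factor(levels(d$sex)[1L], levels(d$sex))
    nd
  }
  fitted <- do.call(rbind, lapply(levels(d$condition), function(cn) {
    pr <- mgcv::predict.gam(fit, newdata = newdata_for(cn), se.fit = TRUE,
                            exclude = exclude, newdata.guaranteed = TRUE)
    data.frame(condition = cn, rel_t_ms = grid, fit = as.numeric(pr$fit),
               se = as.numeric(pr$se.fit))
  }))
  # difference curves via the linear predictor matrix; RE columns are
  # identical in both rows of each pair and cancel exactly
  Vp <- stats::vcov(fit)
  cf <- stats::coef(fit)
  X_ref <- mgcv::predict.gam(fit, newdata = newdata_for(reference),
                             type = "lpmatrix", newdata.guaranteed = TRUE)
  difference <- do.call(rbind, lapply(setdiff(levels(d$condition), reference), function(cn) {
    Xd <- mgcv::predict.gam(fit, newdata = newdata_for(cn), type = "lpmatrix",
                            newdata.guaranteed = TRUE) - X_ref
    df <- as.numeric(Xd %*% cf)
    se <- sqrt(pmax(rowSums((Xd %*% Vp) * Xd), 0))
    ipk <- which.max(df)
    data.frame(condition = cn, rel_t_ms = grid, diff = df, se = se,
               peak_rel_t_ms = grid[ipk],
               peak_p = 2 * stats::pnorm(-abs(df[ipk] / se[ipk])))
  }))
  structure(list(fitted = fitted, difference = difference, smooth_tests = st,
                 parametric = parametric, response = response,
                 reference = reference, fallback = fallback, fit = fit),
            class = "gs_trajectory_smooths")
}

#' @export
print.gs_trajectory_smooths <- function(x, digits = 4, ...) {
  cat(sprintf("Trajectory smooths (%s response, reference = %s%s)\n",
              x$response, x$reference,
              if (x$fallback) ", random slopes dropped" else ""))
  cat("Parametric terms:\n")
  pe <- x$parametric
  pe[, -1] <- lapply(pe[, -1], signif, digits = digits)
  print(pe, row.names = FALSE)
  cat("Smooth terms:\n")
  st <- x$smooth_tests[, c("smooth", "edf", "F", "p-value")]
  st[, -1] <- lapply(st[, -1], signif, digits = digits)
  print(st, row.names = FALSE)
  if (!is.null(x$difference)) {
    pk <- unique(x$difference[, c("condition", "peak_rel_t_ms", "peak_p")])
    pk$peak_p <- signif(pk$peak_p, digits)
    cat("Difference-curve peaks vs", x$reference,
        "(ms relative to maximum extension):\n")
    print(pk, row.names = FALSE)
  }
  invisible(x)
}

#' Mixed-effects regression of acoustic peaks on maximum deceleration
#'
#' On trial-averaged deceleration-window features from the movement
#' conditions: the envelope model regresses the mean envelope peak on the
#' mean maximum deceleration with participant random intercept and slope;
#' the F0 model adds the condition factor (wrist as reference) and its
#' interaction with deceleration. The deceleration predictor is standardized
#' within the fit (`decel_scale` reports the SD in cm/s^2); on convergence
#' failure the random slope is dropped and flagged.
#'
#' @param trial_means Output of [aggregate_impulse_observations()] (movement
#'   trials; passive rows are ignored), with `max_env` and `max_f0` columns
#'   on whatever scale the caller prefers (z-scaled per participant in the
#'   standard pipeline).
#' @return A `gs_deceleration_effects` object with elements `env`
#'   (estimates, fit, fallback) and `f0` (likewise), plus `decel_scale`.
#' @export
fit_deceleration_effects <- function(trial_means) {
  d <- trial_means[trial_means$condition %in% c("wrist", "arm"), ]
  d <- d[is.finite(d$max_decel), ]
  d$condition <- factor(as.character(d$condition), levels = c("wrist", "arm"))
  d$participant_id <- factor(d$participant_id)
  mu <- mean(d$max_decel); sdd <- stats::sd(d$max_decel)
  if (!is.finite(sdd) || sdd == 0) stop("degenerate deceleration predictor")
  d$decel_s <- (d$max_decel - mu) / sdd

  de <- d[is.finite(d$max_env), ]
  env <- fit_with_fallback(max_env ~ decel_s + (1 + decel_s | participant_id),
                           max_env ~ decel_s + (1 | participant_id), de)
  df0 <- d[is.finite(d$max_f0), ]
  if (nlevels(droplevels(df0$condition)) < 2L) {
    stop("the F0 interaction model needs both movement conditions")
  }
  f0 <- fit_with_fallback(max_f0 ~ condition * decel_s + (1 + decel_s | participant_id),
                          max_f0 ~ condition * decel_s + (1 | participant_id), df0)
  structure(list(
    env = list(estimates = lmer_coef_table(env$fit), fallback = env$fallback, fit = env$fit),
    f0 = list(estimates = lmer_coef_table(f0$fit), fallback = f0$fallback, fit = f0$fit),
    decel_scale = c(mean = mu, sd = sdd), n_trials = nrow(d)),
    class = "gs_deceleration_effects")
}

#' @export
print.gs_deceleration_effects <- function(x, digits = 4, ...) {
  cat(sprintf("Deceleration effects on acoustic peaks (%d movement trials)\n", x$n_trials))
  cat(sprintf("(deceleration standardized: SD = %.1f cm/s^2)\n", x$decel_scale["sd"]))
  for (nm in c("env", "f0")) {
    cat(sprintf("%s model%s:\n", toupper(nm),
                if (x[[nm]]$fallback) " (random slope dropped)" else ""))
    est <- x[[nm]]$estimates
    est[, -1] <- lapply(est[, -1], signif, digits = digits)
    print(est, row.names = FALSE)
  }
  invisible(x)
}
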
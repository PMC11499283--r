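# Leaky-integrator behavioural model: exponential-decay accumulation of
# log2 TF with a response threshold, grid fitting against early-lick times
# and reaction-time prediction on hit trials.

#' Leaky integration of a log2-TF stream
#'
#' Exponential-decay accumulator on the 50-ms pulse clock:
#' `y_i = y_{i-1} * exp(-dt/tau) + s_i * dt`, i.e. each pulse contributes
#' its log2-TF value scaled by the 0.05-s bin width, and the trace decays
#' by `exp(-dt/tau)` between pulses. Thresholds are therefore in
#' integrated log2-TF units (octave-seconds).
#'
#' @param log2_tf per-pulse log2-TF values.
#' @param tau decay time, s (> 0).
#' @param dt pulse duration, s.
#' @return accumulated-evidence trace, one value per pulse.
#' @export
leaky_integrate <- function(log2_tf, tau, dt = 0.05) {
  stopifnot(tau > 0)
  n <- length(log2_tf)
  if (!n) return(numeric(0))
  a <- exp(-dt / tau)
  as.numeric(stats::filter(log2_tf * dt, a, method = "recursive"))
}

#' Decay-time grid of the integrator fit
#'
#' 50 log-spaced decay times spanning 0.05-3 s plus 8 long decay times
#' (4, 5, 6, 7, 8, 9, 20, 1000 s): 58 entries, from effectively no
#' integration (0.05 s) to near-perfect integration (1000 s).
#'
#' @return numeric vector of 58 decay times (s).
#' @export
integrator_tau_grid <- function() {
  c(exp(seq(log(0.05), log(3), length.out = 50)), 4, 5, 6, 7, 8, 9, 20, 1000)
}

#' Threshold grid of the integrator fit
#'
#' 151 linearly spaced thresholds spanning \[0.01, 0.16\] integrated
#' log2-TF units.
#'
#' @return numeric vector of 151 thresholds.
#' @export
integrator_threshold_grid <- function() seq(0.01, 0.16, length.out = 151)

#' Fit the leaky integrator on early-lick trials
#'
#' For every (decay time, threshold) pair on the 58 x 151 grid, treats the
#' model as an agent that licks at its first threshold crossing (at or
#' after `min_lick` seconds, to exclude trial-onset licks) and counts the
#' early licks whose predicted crossing falls within the second preceding
#' the actual lick onset. A model that crosses earlier in the trial, or
#' never crosses, does not predict that lick; this is what lets the grid
#' separate integration from trivially permissive parameter pairs.
#' Returns the argmax; ties are broken toward the smaller decay time,
#' then the smaller threshold.
#'
#' @param early_trials list of records, each with `log2_tf` (pulse stream
#'   up to the lick) and `lick_time` (s from baseline onset).
#' @param min_lick earliest admissible lick time (s), default 2.
#' @param pred_window seconds before the lick within which the predicted
#'   crossing counts (default 1).
#' @param dt pulse clock, s.
#' @return list with `tau`, `threshold`, `score` (count predicted),
#'   `n_licks`, and the full `score_grid` matrix (tau x threshold).
#' @export
fit_leaky_integrator <- function(early_trials, min_lick = 2,
                                 pred_window = 1, dt = 0.05) {
  taus <- integrator_tau_grid()
  thrs <- integrator_threshold_grid()
  lick <- vapply(early_trials, function(x) x$lick_time, numeric(1))
  keep <- lick >= min_lick
  early_trials <- early_trials[keep]; lick <- lick[keep]
  if (!length(early_trials)) stop("no early-lick trials after filtering")
  score <- matrix(0L, length(taus), length(thrs))
  for (tr in seq_along(early_trials)) {
    s <- early_trials[[tr]]$log2_tf
    tt <- (seq_along(s) - 1) * dt
    sub <- tt >= min_lick & tt <= lick[tr]
    if (!any(sub)) next
    t_sub <- tt[sub]
    for (i in seq_along(taus)) {
      y <- leaky_integrate(s, taus[i], dt)
      cm <- cummax(y[sub])
      # first-crossing index for every threshold via the running maximum
      idx <- findInterval(thrs, cm, left.open = TRUE) + 1
      ok <- idx <= length(t_sub)
      ct <- rep(NA_real_, length(thrs))
      ct[ok] <- t_sub[idx[ok]]
      score[i, ] <- score[i, ] +
        as.integer(!is.na(ct) & ct >= lick[tr] - pred_window &
                     ct <= lick[tr])
    }
  }
  best <- which(score == max(score), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(tau = taus[best[1]], threshold = thrs[best[2]],
       score = max(score), n_licks = length(early_trials),
       score_grid = score, taus = taus, thresholds = thrs)
}

#' Predict hit reaction times with a fitted integrator
#'
#' Predicted reaction time is the first post-change threshold crossing of
#' the integrated TF. Correlations between actual and predicted reaction
#' times are computed per change size (optionally under a reaction-time
#' cut-off), and a pooled correlation is computed after z-scoring both
#' within each change size.
#'
#' @param params list with `tau`, `threshold`.
#' @param hit_trials list of records: `log2_tf` (full stream),
#'   `change_onset` (s), `change_duration` (s), `rt` (actual reaction
#'   time, s from change onset), `change_magnitude`.
#' @param rt_cutoff optional cut-off (s); trials with actual RT above it
#'   are excluded from the correlations.
#' @param dt pulse clock, s.
#' @return list with per-trial table `pred` (`rt`, `rt_pred`, `magnitude`,
#'   `predicted_miss`), per-magnitude correlations `cor_by_size`, pooled
#'   z-scored correlation `cor_pooled`, and `n_predicted_miss`.
#' @export
predict_reaction_times <- function(params, hit_trials, rt_cutoff = Inf,
                                   dt = 0.05) {
  rt_pred <- vapply(hit_trials, function(tr) {
    y <- leaky_integrate(tr$log2_tf, params$tau, dt)
    tt <- (seq_along(y) - 1) * dt
    post <- which(tt >= tr$change_onset &
                    tt < tr$change_onset + tr$change_duration &
                    y >= params$threshold)
    if (!length(post)) NA_real_ else tt[post[1]] - tr$change_onset
  }, numeric(1))
  rt <- vapply(hit_trials, function(x) x$rt, numeric(1))
  mag <- vapply(hit_trials, function(x) x$change_magnitude, numeric(1))
  pred <- data.frame(rt = rt, rt_pred = rt_pred, magnitude = mag,
                     predicted_miss = is.na(rt_pred))
  use <- !is.na(rt_pred) & rt <= rt_cutoff
  cor_by_size <- vapply(split(which(use), mag[use]), function(ix) {
    if (length(ix) < 3 || stats::sd(rt[ix]) == 0 ||
          stats::sd(rt_pred[ix]) == 0) return(NA_real_)
    stats::cor(rt[ix], rt_pred[ix])
  }, numeric(1))
  z <- function(x) if (length(x) > 1 && stats::sd(x) > 0)
    (x - mean(x)) / stats::sd(x) else rep(0, length(x))
  za <- unlist(lapply(split(rt[use], mag[use]), z))
  zp <- unlist(lapply(split(rt_pred[use], mag[use]), z))
  cor_pooled <- if (length(za) > 2) stats::cor(za, zp) else NA_real_
  list(pred = pred, cor_by_size = cor_by_size, cor_pooled = cor_pooled,
       n_predicted_miss = sum(is.na(rt_pred)))
}

#' Generate behaviour from a leaky-integrator agent
#'
#' Licks occur at the first threshold crossing of the integrated TF (plus
#' an optional motor delay); outcomes are classified against the change
#' epoch. Used as the integration-positive ground-truth generator.
#'
#' @param sessions stimulus sessions.
#' @param tau,threshold integrator parameters.
#' @param motor_delay fixed lick lag after the crossing, s.
#' @param min_lick crossings before this time are ignored (impulsive-lick
#'   guard), s.
#' @param dt pulse clock, s.
#' @return behaviour data.frame (`trial_id`, `outcome`, `movement_onset`,
#'   `lick_time`, `change_onset`, `change_magnitude`).
#' @export
simulate_integrator_behavior <- function(sessions, tau, threshold,
                                         motor_delay = 0.1, min_lick = 0,
                                         dt = 0.05) {
  trials <- sessions$trials
  psplit <- split(sessions$pulses$log2_tf, sessions$pulses$trial_id)
  n <- nrow(trials)
  lick <- rep(NA_real_, n); mov <- rep(NA_real_, n)
  outcome <- rep("miss", n)
  for (j in seq_len(n)) {
    y <- leaky_integrate(psplit[[as.character(trials$trial_id[j])]], tau, dt)
    tt <- (seq_along(y) - 1) * dt
    cross <- which(y >= threshold & tt >= min_lick)
    if (!length(cross)) next
    mov[j] <- tt[cross[1]] + motor_delay
    lick[j] <- mov[j]
    co <- trials$change_onset[j]; dur <- trials$change_duration[j]
    outcome[j] <- if (!is.na(co) && lick[j] >= co && lick[j] <= co + dur)
      "hit" else if (is.na(co) || lick[j] < co) "early" else "miss"
    if (outcome[j] == "miss") { mov[j] <- NA; lick[j] <- NA }
  }
  data.frame(trial_id = trials$trial_id, outcome = outcome,
             movement_onset = mov, lick_time = lick,
             change_onset = trials$change_onset,
             change_magnitude = trials$change_magnitude)
}

#' Generate stimulus-independent random licks
#'
#' Null behaviour generator: each trial licks at an exponentially
#' distributed latency, independent of the stimulus.
#'
#' @param sessions stimulus sessions.
#' @param rate lick hazard, 1/s.
#' @param seed optional integer seed.
#' @return behaviour data.frame as in [simulate_integrator_behavior()].
#' @export
simulate_random_licks <- function(sessions, rate = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trials <- sessions$trials
  n <- nrow(trials)
  lat <- stats::rexp(n, rate)
  lick <- ifelse(lat < trials$duration, lat, NA_real_)
  outcome <- rep("miss", n)
  co <- trials$change_onset; dur <- trials$change_duration
  hit <- !is.na(lick) & !is.na(co) & lick >= co & lick <= co + dur
  early <- !is.na(lick) & (is.na(co) | lick < co)
  outcome[hit] <- "hit"; outcome[early] <- "early"
  lick[!(hit | early)] <- NA
  data.frame(trial_id = trials$trial_id, outcome = outcome,
             movement_onset = lick, lick_time = lick,
             change_onset = co, change_magnitude = trials$change_magnitude)
}
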
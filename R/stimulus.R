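# Synthetic task stimulus: the 50-ms lognormal temporal-frequency (TF)
# pulse stream, trial/change-epoch structure, pulse classification and the
# untrained-animal random reward schedule.

#' Default stimulus parameters
#'
#' Constants of the change-detection task: 50-ms pulse clock, baseline
#' log2-TF s.d. of 0.25 octaves around a geometric mean of 1 Hz, change
#' epochs of 2.15 s with onsets in the early (\[3, 8\] s) or late
#' (\[10.5, 15.5\] s) window, a 4-s-mean exponential onset delay, 15%
#' no-change trials and 10% probe trials, and change magnitudes drawn from
#' \{1.25, 1.35, 1.5, 2, 4\} Hz.
#'
#' @return named list of stimulus constants.
#' @export
stimulus_defaults <- function() {
  list(
    pulse_dt = 0.05,
    sigma_octaves = 0.25,
    change_duration = 2.15,
    change_magnitudes = c(1.25, 1.35, 1.5, 2, 4),
    p_nochange = 0.15,
    p_probe = 0.10,
    onset_mean_delay = 4,
    early_window = c(3, 8),
    late_window = c(10.5, 15.5),
    frame_rate = 60
  )
}

#' Draw baseline log2-TF samples
#'
#' Baseline pulses are i.i.d. normal in log2 space with mean 0 octaves
#' (geometric mean 1 Hz) and s.d. `sigma_octaves`.
#'
#' @param n_pulses number of 50-ms pulses to draw.
#' @param sigma_octaves s.d. of log2 TF in octaves (default 0.25).
#' @param seed optional integer seed.
#' @return numeric vector of log2-TF values (octaves).
#' @export
sample_baseline_tf <- function(n_pulses, sigma_octaves = 0.25, seed = NULL) {
  stopifnot(n_pulses >= 1)
  if (!is.finite(sigma_octaves) || sigma_octaves < 0)
    stop("sigma_octaves must be finite and non-negative")
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n_pulses, mean = 0, sd = sigma_octaves)
}

# Truncated-exponential draw on [0, hi - lo] with mean `mean`, shifted to lo.
rtruncexp <- function(n, mean, lo, hi) {
  u <- stats::runif(n)
  w <- hi - lo
  # inverse CDF of Exp(mean) truncated to [0, w]
  p_in <- 1 - exp(-w / mean)
  lo - mean * log(1 - u * p_in)
}

#' Assign change-epoch structure to trials
#'
#' A random 15% of trials (by default) carry no change epoch. Change onsets
#' are drawn as the start of the block's allowed window plus an
#' exponential delay (mean 4 s) truncated to the window; early-block
#' onsets fall in \[3, 8\] s and late-block onsets in \[10.5, 15.5\] s.
#' Probe trials draw their onset from the other block's window. Magnitudes
#' are uniform over the configured set.
#'
#' @param n_trials number of trials.
#' @param block "early", "late" or "none" (no-change only makes sense with
#'   `p_nochange = 1` for "none").
#' @param p_nochange probability a trial has no change epoch.
#' @param p_probe probability a change trial is a probe (other block's
#'   onset window).
#' @param params stimulus parameter list, see [stimulus_defaults()].
#' @param seed optional integer seed.
#' @return data.frame with one row per trial: `trial_id`, `has_change`,
#'   `is_probe`, `change_onset` (s, `NA` if none), `change_magnitude` (Hz,
#'   `NA` if none), `change_duration` (s).
#' @export
assign_trial_structure <- function(n_trials, block = "early",
                                   p_nochange = 0.15, p_probe = 0.10,
                                   params = stimulus_defaults(), seed = NULL) {
  stopifnot(p_nochange >= 0, p_nochange <= 1, p_probe >= 0, p_probe <= 1)
  if (!length(params$change_magnitudes)) stop("empty change-magnitude set")
  if (!is.null(seed)) set.seed(seed)
  has_change <- stats::runif(n_trials) >= p_nochange
  is_probe <- has_change & (stats::runif(n_trials) < p_probe)
  win_of <- function(b) if (b == "early") params$early_window else params$late_window
  other <- if (block == "early") "late" else "early"
  onset <- rep(NA_real_, n_trials)
  for (i in seq_len(n_trials)) {
    if (!has_change[i]) next
    w <- win_of(if (is_probe[i]) other else block)
    onset[i] <- rtruncexp(1, params$onset_mean_delay, w[1], w[2])
  }
  mag <- ifelse(has_change,
                sample(params$change_magnitudes, n_trials, replace = TRUE),
                NA_real_)
  data.frame(trial_id = seq_len(n_trials), has_change = has_change,
             is_probe = is_probe, change_onset = onset,
             change_magnitude = mag,
             change_duration = ifelse(has_change, params$change_duration, NA_real_))
}

#' Generate a set of stimulus sessions (trials)
#'
#' Each trial is a 50-ms log2-TF pulse stream: baseline samples around
#' 0 octaves and, on change trials, a 2.15-s epoch whose log2 mean is
#' shifted to `log2(change_magnitude)` (baseline noise s.d. retained).
#' Trials end at change offset (or at `nochange_duration` on no-change
#' trials).
#'
#' @param n_trials number of trials.
#' @param block "early" or "late".
#' @param params stimulus parameter list.
#' @param nochange_duration trial length (s) used for no-change trials and
#'   as the minimum trial length.
#' @param seed optional integer seed.
#' @return list with `trials` (the [assign_trial_structure()] table plus
#'   `n_pulses`, `duration`, `drift_direction`) and `pulses` (long table:
#'   `trial_id`, `t` (pulse onset, s from baseline start), `log2_tf`,
#'   `epoch` ("baseline"/"change")).
#' @export
simulate_stimulus_sessions <- function(n_trials, block = "early",
                                       params = stimulus_defaults(),
                                       nochange_duration = 17.65, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trials <- assign_trial_structure(n_trials, block, params$p_nochange,
                                   params$p_probe, params)
  dt <- params$pulse_dt
  # the TF stream is resampled every 50 ms, so a sustained change can only
  # begin on a pulse boundary: snap onsets up to the pulse grid
  trials$change_onset <- ceiling(trials$change_onset / dt - 1e-9) * dt
  trials$duration <- ifelse(trials$has_change,
                            trials$change_onset + trials$change_duration,
                            nochange_duration)
  trials$n_pulses <- floor(trials$duration / dt + 1e-9)
  trials$drift_direction <- sample(c("up", "down"), n_trials, replace = TRUE)
  total <- sum(trials$n_pulses)
  tid <- rep(trials$trial_id, trials$n_pulses)
  t <- unlist(lapply(trials$n_pulses, function(n) (seq_len(n) - 1) * dt),
              use.names = FALSE)
  lf <- stats::rnorm(total, 0, params$sigma_octaves)
  epoch <- rep("baseline", total)
  onset <- trials$change_onset[tid]
  dur <- trials$change_duration[tid]
  in_change <- !is.na(onset) & t >= onset & t < onset + dur
  epoch[in_change] <- "change"
  lf[in_change] <- lf[in_change] + log2(trials$change_magnitude[tid][in_change])
  list(trials = trials,
       pulses = data.frame(trial_id = tid, t = t, log2_tf = lf, epoch = epoch))
}

#' Classify baseline pulses as fast / slow / neutral and near-mean
#'
#' A fast pulse exceeds +1 s.d. of the baseline log2-TF distribution
#' (with the default 0.25-octave s.d., TF > 2^0.25 = 1.19 Hz); a slow
#' pulse lies below -1 s.d. (TF < 0.84 Hz). Near-mean pulses
#' (|log2 TF| <= 0.5 s.d.) are used for baseline-response subtraction.
#' Labels are only assigned within the baseline epoch.
#'
#' @param pulses pulse table with `log2_tf` and optionally `epoch`.
#' @param sigma_octaves baseline log2-TF s.d. in octaves.
#' @return the table with added logical columns `fast`, `slow`, `near_mean`
#'   and a character `label` ("fast"/"slow"/"neutral", `NA` outside
#'   baseline).
#' @export
classify_pulses <- function(pulses, sigma_octaves = 0.25) {
  stopifnot(is.finite(sigma_octaves), sigma_octaves > 0)
  base <- if ("epoch" %in% names(pulses)) pulses$epoch == "baseline" else
    rep(TRUE, nrow(pulses))
  lf <- pulses$log2_tf
  pulses$fast <- base & lf > sigma_octaves
  pulses$slow <- base & lf < -sigma_octaves
  pulses$near_mean <- base & abs(lf) <= 0.5 * sigma_octaves
  lab <- ifelse(pulses$fast, "fast", ifelse(pulses$slow, "slow", "neutral"))
  lab[!base] <- NA_character_
  pulses$label <- lab
  pulses
}

#' Random reward schedule for untrained animals
#'
#' Inter-reward intervals are i.i.d. uniform on 60 +/- `jitter` s
#' (\[45, 75\] s by default).
#'
#' @param duration session duration in seconds.
#' @param mean_interval mean inter-reward interval (s).
#' @param jitter half-width of the uniform interval distribution (s).
#' @param seed optional integer seed.
#' @return numeric vector of reward times (s from session start).
#' @export
untrained_reward_schedule <- function(duration, mean_interval = 60,
                                      jitter = 15, seed = NULL) {
  stopifnot(duration > 0, jitter >= 0, mean_interval > jitter)
  if (!is.null(seed)) set.seed(seed)
  n_max <- ceiling(duration / (mean_interval - jitter)) + 1
  iv <- stats::runif(n_max, mean_interval - jitter, mean_interval + jitter)
  tt <- cumsum(iv)
  tt[tt <= duration]
}
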
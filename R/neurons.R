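# Synthetic spike populations and motion-energy traces with stored ground
# truth, so every downstream analysis has a recoverable target.

#' Build a ground-truth unit configuration table
#'
#' Helper constructing the per-unit generative parameters consumed by
#' [simulate_population()]. TF kernels are boxcars on the 50-ms pulse grid:
#' `tf_gain` log-rate units per octave, spread uniformly over
#' `tf_width` seconds of lag.
#'
#' @param n_units number of units.
#' @param region region label.
#' @param baseline_rate baseline rate(s), Hz (recycled).
#' @param tf_gain TF kernel gain (log-rate per octave; 0 = non-coding).
#' @param tf_width TF kernel width in s (boxcar over lags `[0, tf_width)`).
#' @param prep_gain peak log-rate elevation of the pre-lick linear ramp.
#' @param prep_onset ramp start, s before lick onset.
#' @param exec_gain log-rate elevation during `[0, exec_width)` s after lick.
#' @param exec_width execution response width, s.
#' @param ou_tau intrinsic Ornstein-Uhlenbeck timescale, s (0 disables).
#' @param ou_sd stationary s.d. of the OU log-rate fluctuation.
#' @return data.frame with one row per unit; `tf_kernel` is a list column
#'   of lag weights on the 50-ms grid.
#' @export
make_unit_config <- function(n_units, region = "region1", baseline_rate = 5,
                             tf_gain = 0, tf_width = 0.3,
                             prep_gain = 0, prep_onset = 0.8,
                             exec_gain = 0, exec_width = 0.5,
                             ou_tau = 0, ou_sd = 0) {
  cfg <- data.frame(
    unit_id = seq_len(n_units), region = region,
    baseline_rate = rep_len(baseline_rate, n_units),
    tf_gain = rep_len(tf_gain, n_units),
    tf_width = rep_len(tf_width, n_units),
    prep_gain = rep_len(prep_gain, n_units),
    prep_onset = rep_len(prep_onset, n_units),
    exec_gain = rep_len(exec_gain, n_units),
    exec_width = rep_len(exec_width, n_units),
    ou_tau = rep_len(ou_tau, n_units),
    ou_sd = rep_len(ou_sd, n_units),
    stringsAsFactors = FALSE
  )
  cfg$tf_kernel <- lapply(seq_len(n_units), function(i) {
    nlag <- max(1L, round(cfg$tf_width[i] / 0.05))
    rep(cfg$tf_gain[i] / nlag * 0.05 / 0.05, nlag)  # per-lag weight
  })
  cfg$is_tf_coding <- cfg$tf_gain != 0
  stopifnot(all(cfg$baseline_rate > 0))
  cfg
}

# Exact AR(1) discretisation of a stationary OU process on lattice dt.
simulate_ou <- function(n, dt, tau, sd) {
  if (tau <= 0 || sd <= 0) return(numeric(n))
  a <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  innov <- stats::rnorm(n - 1, 0, sd * sqrt(1 - a^2))
  for (i in seq_len(n - 1)) x[i + 1] <- a * x[i] + innov[i]
  x
}

# Rate vector (Hz) for one unit on one trial, on a 1-ms lattice covering
# [-pre_pad, duration + post_pad] relative to baseline onset.
unit_trial_rate <- function(unit, pulses_t, pulses_lf, duration, lick,
                            pre_pad, post_pad, dt = 0.001, rate_max = 500) {
  tt <- seq(-pre_pad, duration + post_pad - dt, by = dt)
  n <- length(tt)
  lograte <- rep(log(unit$baseline_rate), n)
  kern <- unit$tf_kernel[[1]]
  if (any(kern != 0) && length(pulses_t)) {
    # stimulus drive: sum over lags of kernel weight x log2 TF at t - lag
    drive50 <- as.numeric(stats::filter(c(pulses_lf), kern, method = "convolution",
                                        sides = 1))
    # leading lags with incomplete history: partial sums
    for (i in seq_len(min(length(kern) - 1, length(pulses_lf)))) {
      drive50[i] <- sum(kern[seq_len(i)] * pulses_lf[i:1])
    }
    idx <- pmin(length(drive50), pmax(1L, floor(tt / 0.05) + 1L))
    drv <- drive50[idx]
    drv[tt < 0 | tt >= length(pulses_lf) * 0.05] <- 0
    lograte <- lograte + drv
  }
  if (!is.na(lick)) {
    if (unit$prep_gain != 0 && unit$prep_onset > 0) {
      ramp <- (tt - (lick - unit$prep_onset)) / unit$prep_onset
      ramp[ramp < 0 | tt > lick] <- 0
      ramp[ramp > 1] <- 1
      lograte <- lograte + unit$prep_gain * ramp
    }
    if (unit$exec_gain != 0) {
      inwin <- tt >= lick & tt < lick + unit$exec_width
      lograte[inwin] <- lograte[inwin] + unit$exec_gain
    }
  }
  if (unit$ou_tau > 0 && unit$ou_sd > 0)
    lograte <- lograte + simulate_ou(n, dt, unit$ou_tau, unit$ou_sd)
  rate <- exp(lograte)
  if (any(rate > rate_max)) {
    warning("rate clipped at ", rate_max, " Hz")
    rate <- pmin(rate, rate_max)
  }
  list(t = tt, rate = rate)
}

# Inhomogeneous-Poisson spikes by thinning against the lattice rate.
thin_spikes <- function(t0, rate_t, rate, dt = 0.001) {
  rmax <- max(rate)
  if (rmax <= 0) return(numeric(0))
  span <- length(rate) * dt
  n_cand <- stats::rpois(1, rmax * span)
  if (!n_cand) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, span))
  idx <- pmin(length(rate), floor(cand / dt) + 1L)
  keep <- stats::runif(n_cand) < rate[idx] / rmax
  t0 + rate_t[1] + cand[keep]
}

#' Simulate a spike population over a set of stimulus sessions
#'
#' Inhomogeneous-Poisson spike trains with log-rate
#' `log(baseline) + TF-kernel drive + pre-lick linear ramp +
#' post-lick execution response + OU fluctuation`. Rates are evaluated on
#' a 1-ms lattice and spikes drawn by exact thinning. Trials are laid out
#' on a session clock with `iti` seconds between baseline onsets beyond
#' each trial's duration.
#'
#' @param sessions output of [simulate_stimulus_sessions()].
#' @param behaviour behaviour table with `trial_id` and `lick_time`
#'   (s from baseline onset, `NA` when no lick).
#' @param units unit configuration from [make_unit_config()].
#' @param pre_pad,post_pad seconds of simulated activity before baseline
#'   onset and after trial end (pre_pad also sets the inter-trial window
#'   available for timescale analysis).
#' @param iti gap (s) between one trial's end (+post_pad) and the next
#'   trial's baseline onset is `pre_pad`; `iti` is retained for layout and
#'   must be >= pre_pad + post_pad.
#' @param seed optional integer seed.
#' @return list with `spikes` (unit_id, spike_time on session clock,
#'   trial_id, t_trial relative to baseline onset), `units`, and
#'   `trial_times` (trial_id, session_start = session time of baseline
#'   onset, duration).
#' @export
simulate_population <- function(sessions, behaviour, units,
                                pre_pad = 3, post_pad = 1, iti = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  iti <- iti %||% (pre_pad + post_pad)
  stopifnot(iti >= pre_pad + post_pad)
  trials <- sessions$trials
  starts <- cumsum(c(pre_pad, utils::head(trials$duration, -1) + iti))
  trial_times <- data.frame(trial_id = trials$trial_id,
                            session_start = starts,
                            duration = trials$duration)
  lick <- behaviour$lick_time[match(trials$trial_id, behaviour$trial_id)]
  psplit <- split(sessions$pulses, sessions$pulses$trial_id)
  out <- vector("list", nrow(units) * nrow(trials))
  k <- 0
  for (u in seq_len(nrow(units))) {
    unit <- units[u, ]
    for (j in seq_len(nrow(trials))) {
      pp <- psplit[[as.character(trials$trial_id[j])]]
      r <- unit_trial_rate(unit, pp$t, pp$log2_tf, trials$duration[j],
                           lick[j], pre_pad, post_pad)
      st <- thin_spikes(starts[j], r$t, r$rate)
      if (length(st)) {
        k <- k + 1
        out[[k]] <- data.frame(unit_id = unit$unit_id, spike_time = st,
                               trial_id = trials$trial_id[j],
                               t_trial = st - starts[j])
      }
    }
  }
  spikes <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(unit_id = integer(), spike_time = numeric(),
               trial_id = integer(), t_trial = numeric())
  spikes <- spikes[order(spikes$unit_id, spikes$spike_time), ]
  rownames(spikes) <- NULL
  list(spikes = spikes, units = units, trial_times = trial_times,
       pre_pad = pre_pad, post_pad = post_pad)
}

#' Simulate an orofacial reference population
#'
#' Units respond only from lick onset onward, as weighted combinations of
#' two shared temporal motifs (a fast transient and a slower bump), so the
#' population's trial-averaged activity has about two dominant principal
#' components. No TF modulation, no preparatory activity.
#'
#' @param sessions,behaviour as in [simulate_population()].
#' @param n_units number of reference units.
#' @param baseline_rate baseline rate, Hz.
#' @param exec_gain overall log-rate scale of the motifs.
#' @param seed optional integer seed.
#' @inheritParams simulate_population
#' @return as [simulate_population()]; `units` carries the motif weights.
#' @export
simulate_orofacial_population <- function(sessions, behaviour, n_units = 30,
                                          baseline_rate = 8, exec_gain = 1.2,
                                          pre_pad = 3, post_pad = 1,
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  units <- make_unit_config(n_units, region = "orofacial",
                            baseline_rate = baseline_rate)
  # two functional subgroups (transient-dominant vs sustained-dominant)
  # so the population really has two dominant activity modes
  grp <- rep(c(1, 2), length.out = n_units)
  units$motif_w1 <- ifelse(grp == 1, stats::runif(n_units, 0.7, 1),
                           stats::runif(n_units, 0, 0.25)) * exec_gain
  units$motif_w2 <- ifelse(grp == 2, stats::runif(n_units, 0.7, 1),
                           stats::runif(n_units, 0, 0.25)) * exec_gain
  # shared motifs on a 10-ms grid over [0, 1.2] s after lick
  tg <- seq(0, 1.19, by = 0.01)
  m1 <- exp(-((tg - 0.08) / 0.06)^2)           # fast transient
  m2 <- pmax(0, sin(pi * pmin(tg / 1.0, 1)))   # slow bump
  trials <- sessions$trials
  iti <- pre_pad + post_pad
  starts <- cumsum(c(pre_pad, utils::head(trials$duration, -1) + iti))
  lick <- behaviour$lick_time[match(trials$trial_id, behaviour$trial_id)]
  out <- list(); k <- 0
  for (u in seq_len(n_units)) {
    for (j in seq_len(nrow(trials))) {
      tt <- seq(-pre_pad, trials$duration[j] + post_pad - 0.001, by = 0.001)
      lograte <- rep(log(baseline_rate), length(tt))
      if (!is.na(lick[j])) {
        rel <- tt - lick[j]
        idx <- floor(rel / 0.01) + 1L
        ok <- idx >= 1 & idx <= length(tg)
        lograte[ok] <- lograte[ok] + units$motif_w1[u] * m1[idx[ok]] +
          units$motif_w2[u] * m2[idx[ok]]
      }
      st <- thin_spikes(starts[j], tt, exp(lograte))
      if (length(st)) {
        k <- k + 1
        out[[k]] <- data.frame(unit_id = u, spike_time = st,
                               trial_id = trials$trial_id[j],
                               t_trial = st - starts[j])
      }
    }
  }
  spikes <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(unit_id = integer(), spike_time = numeric(),
               trial_id = integer(), t_trial = numeric())
  spikes <- spikes[order(spikes$unit_id, spikes$spike_time), ]
  rownames(spikes) <- NULL
  list(spikes = spikes, units = units,
       trial_times = data.frame(trial_id = trials$trial_id,
                                session_start = starts,
                                duration = trials$duration),
       motifs = list(t = tg, m1 = m1, m2 = m2),
       pre_pad = pre_pad, post_pad = post_pad)
}

#' Simulate a motion-energy trace
#'
#' Emulates the videography motion-energy signal: a Gaussian noise floor
#' sampled at `fs` Hz plus a lick-locked burst starting at a known
#' ground-truth movement onset `onset_lead` seconds before each lick.
#'
#' @param behaviour behaviour table with `trial_id` and `lick_time`.
#' @param trial_times trial layout table (from [simulate_population()]),
#'   or `NULL` to lay trials out here.
#' @param durations per-trial durations when `trial_times` is `NULL`.
#' @param fs sampling rate, Hz (default 100, the front-camera frame rate).
#' @param floor_mean,floor_sd Gaussian noise-floor parameters.
#' @param burst_amp burst amplitude above the floor.
#' @param onset_lead ground-truth movement onset, s before lick.
#' @param burst_dur burst duration, s.
#' @param seed optional integer seed.
#' @return list with `trace` (data.frame `t`, `energy` on the session
#'   clock), `gt_onsets` (data.frame `trial_id`, `lick_session`,
#'   `onset_session`) and the parameters used.
#' @export
simulate_motion_energy <- function(behaviour, trial_times = NULL,
                                   durations = NULL, fs = 100,
                                   floor_mean = 1, floor_sd = 0.1,
                                   burst_amp = 5, onset_lead = 0.15,
                                   burst_dur = 1.0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(trial_times)) {
    stopifnot(!is.null(durations))
    starts <- cumsum(c(3, utils::head(durations, -1) + 4))
    trial_times <- data.frame(trial_id = behaviour$trial_id,
                              session_start = starts, duration = durations)
  }
  total <- max(trial_times$session_start + trial_times$duration) + 3
  t <- seq(0, total, by = 1 / fs)
  energy <- stats::rnorm(length(t), floor_mean, floor_sd)
  lick <- behaviour$lick_time[match(trial_times$trial_id, behaviour$trial_id)]
  lick_session <- trial_times$session_start + lick
  onset_session <- lick_session - onset_lead
  for (j in seq_along(lick_session)) {
    if (is.na(lick_session[j])) next
    inb <- t >= onset_session[j] & t < onset_session[j] + burst_dur
    energy[inb] <- energy[inb] + burst_amp
  }
  list(trace = data.frame(t = t, energy = energy),
       gt_onsets = data.frame(trial_id = trial_times$trial_id,
                              lick_session = lick_session,
                              onset_session = onset_session),
       fs = fs, onset_lead = onset_lead)
}
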
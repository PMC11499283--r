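# Behavioural summaries and pulse-probability statistics: psychometric
# curves, the lick-triggered stimulus average (psychophysical kernel) and
# the single/two-pulse conditional lick-probability analysis with the
# independence prediction and facilitation index.

#' Psychometric curve
#'
#' Hit rate per change magnitude, computed over eligible trials (those
#' without an early lick or abort). With a `session` column present, the
#' rate is computed per session and summarised as mean +/- 1.96 s.e.m.
#'
#' @param behaviour behaviour table with `outcome`, `change_magnitude`,
#'   optionally `session`.
#' @return data.frame with `magnitude`, `rate`, `n_eligible`, `ci_lo`,
#'   `ci_hi` (`NA` CIs for single sessions).
#' @export
psychometric_curve <- function(behaviour) {
  elig <- behaviour$outcome %in% c("hit", "miss") & !is.na(behaviour$change_magnitude)
  b <- behaviour[elig, ]
  if (!"session" %in% names(b)) b$session <- 1L
  per <- do.call(rbind, lapply(split(b, list(b$change_magnitude, b$session),
                                     drop = TRUE), function(g)
    data.frame(magnitude = g$change_magnitude[1], session = g$session[1],
               rate = mean(g$outcome == "hit"), n = nrow(g))))
  out <- do.call(rbind, lapply(split(per, per$magnitude), function(g) {
    m <- mean(g$rate)
    se <- if (nrow(g) > 1) stats::sd(g$rate) / sqrt(nrow(g)) else NA_real_
    data.frame(magnitude = g$magnitude[1], rate = m, n_eligible = sum(g$n),
               ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se)
  }))
  out[order(out$magnitude), ]
}

#' Lick-triggered stimulus average (psychophysical kernel)
#'
#' Mean stimulus TF (Hz) at each 50-ms lag from -1.5 to 0 s preceding
#' early licks, with parametric 95% CIs (1.96 s.e.m.), plus an
#' exponential-decay fit `A * exp(t / tau) + c` to the elevation above the
#' linear mean of the baseline lognormal (offset `c` fixed at that mean).
#'
#' @param sessions stimulus sessions.
#' @param behaviour behaviour table; early-lick trials with `lick_time`
#'   at least 1.5 s are used.
#' @param sigma_octaves baseline log2-TF s.d. (sets the fixed offset
#'   `exp((sigma * ln 2)^2 / 2)` Hz).
#' @param fit_tau fit the decay time? (needs enough licks)
#' @return list with `kernel` (data.frame `lag`, `mean_tf`, `ci_lo`,
#'   `ci_hi`, `n`), `tau` (s, `NA` if not fitted), `offset`.
#' @export
lick_triggered_average <- function(sessions, behaviour, sigma_octaves = 0.25,
                                   fit_tau = TRUE) {
  lags <- seq(-1.5, -0.05, by = 0.05)
  offset <- exp((sigma_octaves * log(2))^2 / 2)
  el <- behaviour[behaviour$outcome == "early" & !is.na(behaviour$lick_time) &
                    behaviour$lick_time >= 1.5, ]
  if (!nrow(el)) stop("need at least one early lick with 1.5 s of history")
  psplit <- split(sessions$pulses, sessions$pulses$trial_id)
  acc <- matrix(NA_real_, nrow(el), length(lags))
  for (i in seq_len(nrow(el))) {
    pp <- psplit[[as.character(el$trial_id[i])]]
    tt <- el$lick_time[i] + lags
    idx <- floor(tt / 0.05 + 1e-9) + 1
    ok <- idx >= 1 & idx <= nrow(pp)
    acc[i, ok] <- 2^pp$log2_tf[idx[ok]]
  }
  mn <- colMeans(acc, na.rm = TRUE)
  n <- colSums(!is.na(acc))
  se <- apply(acc, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n, 1))
  kernel <- data.frame(lag = lags, mean_tf = mn,
                       ci_lo = mn - 1.96 * se, ci_hi = mn + 1.96 * se, n = n)
  tau <- NA_real_
  if (fit_tau && nrow(el) >= 5) tau <- fit_kernel_decay(lags, mn, offset)
  list(kernel = kernel, tau = tau, offset = offset)
}

#' Exponential-decay fit to a psychophysical kernel
#'
#' Nonlinear least squares for `A * exp(t / tau) + offset` on lag grid
#' `t <= 0`, offset fixed; multi-start over decay times 0.05-2 s.
#'
#' @param lags lag grid (s, negative).
#' @param mean_tf kernel values (Hz).
#' @param offset fixed asymptote (Hz).
#' @return fitted `tau` (s) or `NA` on failure.
#' @export
fit_kernel_decay <- function(lags, mean_tf, offset) {
  y <- mean_tf - offset
  best <- NULL
  for (tau0 in c(0.05, 0.1, 0.27, 0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(lag / tau),
                        data = data.frame(lag = lags, y = y),
                        start = list(A = max(y), tau = tau0),
                        lower = c(-Inf, 1e-3), upper = c(Inf, 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, tau = stats::coef(fit)[["tau"]])
  }
  if (is.null(best)) NA_real_ else best$tau
}

# Per-trial pulse bookkeeping shared by the single/two-pulse analyses.
# Every baseline pulse is an observation: it "succeeds" when a counted
# early lick follows it at a lag inside [0.2, 1] s, and it is at risk
# when the trial lasted long enough for such a lick to have been
# possible. Because the 15 magnitude bins have equal occupancy, every
# class of pulse shares the same chance success rate, which is what
# makes the independence combination of deviations well-defined.
# Counts are stored per trial so the bootstrap can resample trials.
lick_pulse_counts <- function(sessions, behaviour, sigma_octaves = 0.25,
                              n_bins = 15, win = c(0.2, 1),
                              delays = seq(0.05, 0.5, by = 0.05),
                              min_lick = 2) {
  pulses <- classify_pulses(sessions$pulses, sigma_octaves)
  base <- pulses[pulses$epoch == "baseline", ]
  # equal-count bins by rank (identical to quantile bins for continuous
  # data, and still well-defined under heavy ties)
  r <- rank(base$log2_tf, ties.method = "first")
  base$bin <- pmin(n_bins, ceiling(r * n_bins / length(r)))
  qs <- stats::quantile(base$log2_tf, probs = seq(0, 1, length.out = n_bins + 1))
  central <- ceiling(n_bins / 2)
  trials <- sessions$trials
  beh <- behaviour[match(trials$trial_id, behaviour$trial_id), ]
  psplit <- split(base, base$trial_id)
  nd <- length(delays)
  n_tr <- nrow(trials)
  elig_bins <- matrix(0L, n_tr, n_bins); succ_bins <- matrix(0L, n_tr, n_bins)
  elig_fast <- integer(n_tr); succ_fast <- integer(n_tr)
  elig_all <- integer(n_tr); succ_all <- integer(n_tr)
  elig_shift <- matrix(0L, n_tr, nd); succ_shift <- matrix(0L, n_tr, nd)
  elig_allsh <- matrix(0L, n_tr, nd); succ_allsh <- matrix(0L, n_tr, nd)
  elig_pair <- matrix(0L, n_tr, nd); succ_pair <- matrix(0L, n_tr, nd)
  n_licks <- 0L
  for (j in seq_len(n_tr)) {
    pp <- psplit[[as.character(trials$trial_id[j])]]
    if (is.null(pp)) next
    lk <- beh$lick_time[j]
    licked <- !is.na(lk)
    end_e <- if (licked) lk else
      min(c(beh$change_onset[j], trials$duration[j]), na.rm = TRUE)
    counted <- licked && identical(beh$outcome[j], "early") && lk >= min_lick
    if (counted) n_licks <- n_licks + 1L
    tt <- pp$t
    succ_of <- function(lo, hi) counted & (lk - tt) >= lo & (lk - tt) <= hi
    # at risk: the success window starts inside the countable lick span
    # (>= min_lick, so no window is diluted by uncountable early times)
    # and the trial was still running when the window opened
    risk_of <- function(lo) tt + lo >= min_lick & tt + lo <= end_e
    r0 <- risk_of(win[1]); s0 <- succ_of(win[1], win[2]) & r0
    elig_bins[j, ] <- tabulate(pp$bin[r0], nbins = n_bins)
    succ_bins[j, ] <- tabulate(pp$bin[s0], nbins = n_bins)
    elig_fast[j] <- sum(pp$fast & r0); succ_fast[j] <- sum(pp$fast & s0)
    elig_all[j] <- sum(r0); succ_all[j] <- sum(s0)
    for (d in seq_len(nd)) {
      rd <- risk_of(win[1] + delays[d])
      sd_ <- succ_of(win[1] + delays[d], win[2] + delays[d]) & rd
      elig_shift[j, d] <- sum(pp$fast & rd)
      succ_shift[j, d] <- sum(pp$fast & sd_)
      elig_allsh[j, d] <- sum(rd)
      succ_allsh[j, d] <- sum(sd_)
      # pairs: fast pulse at t with a fast pulse delays[d] earlier
      idx <- match(round((tt - delays[d]) / 0.05), round(tt / 0.05))
      has_first <- !is.na(idx) & pp$fast[ifelse(is.na(idx), 1, idx)]
      pr <- r0 & pp$fast & has_first
      elig_pair[j, d] <- sum(pr)
      succ_pair[j, d] <- sum(pr & s0)
    }
  }
  list(n_trials = n_tr, n_licks = n_licks, n_bins = n_bins,
       central = central, delays = delays,
       elig_bins = elig_bins, succ_bins = succ_bins,
       elig_fast = elig_fast, succ_fast = succ_fast,
       elig_all = elig_all, succ_all = succ_all,
       elig_shift = elig_shift, succ_shift = succ_shift,
       elig_allsh = elig_allsh, succ_allsh = succ_allsh,
       elig_pair = elig_pair, succ_pair = succ_pair,
       bin_breaks = qs)
}

#' Single-pulse conditional lick probability
#'
#' Separates baseline TF pulses into `n_bins` equal-count magnitude bins
#' and computes, for each bin, the probability that a pulse of that bin
#' is followed by a counted early lick at a lag of 0.2-1 s (the summed
#' conditional lick probability over the \[-1, -0.2\] s pre-lick
#' window). Only licks at least `min_lick` seconds after baseline onset
#' count, and a pulse is at risk only if the trial lasted long enough
#' for a lick in its window. `P0` is the probability for the central
#' (mean-TF) bin -- the chance level of licking without a TF deviation --
#' and `P_fast` pools pulses beyond +1 s.d. (TF > 1.19 Hz).
#'
#' @param sessions stimulus sessions.
#' @param behaviour behaviour table; early licks at least `min_lick`
#'   seconds after baseline onset are used.
#' @param sigma_octaves baseline log2-TF s.d. (sets the fast threshold).
#' @param n_bins number of equal-count magnitude bins (default 15).
#' @param win lag window (s) over which conditional probabilities are
#'   summed.
#' @param delays two-pulse delays (s) to tabulate.
#' @param min_lick earliest admissible lick time, s.
#' @return list of class `lick_prob_table` with `P` (per-bin summed
#'   probability), `P0`, `P_fast`, `dP` (per-bin deviation from `P0`),
#'   `n_licks`, bin metadata, and the per-lick count matrices used for
#'   bootstrapping.
#' @export
single_pulse_lick_probability <- function(sessions, behaviour,
                                          sigma_octaves = 0.25, n_bins = 15,
                                          win = c(0.2, 1),
                                          delays = seq(0.05, 0.5, by = 0.05),
                                          min_lick = 2) {
  cc <- lick_pulse_counts(sessions, behaviour, sigma_octaves, n_bins, win,
                          delays, min_lick)
  if (!cc$n_licks) stop("no eligible early licks")
  P <- colSums(cc$succ_bins) / pmax(colSums(cc$elig_bins), 1)
  P[colSums(cc$elig_bins) == 0] <- NA_real_
  P0 <- P[cc$central]
  structure(list(P = P, P0 = P0,
                 P_fast = sum(cc$succ_fast) / max(sum(cc$elig_fast), 1),
                 P_marg = sum(cc$succ_all) / max(sum(cc$elig_all), 1),
                 dP = P - P0, counts = cc, n_licks = cc$n_licks,
                 bin_breaks = cc$bin_breaks, central = cc$central),
            class = "lick_prob_table")
}

#' Independent two-pulse prediction
#'
#' Expected lick probability if two pulses acted independently:
#' `P_Ind = P0 + dP1 + dP2 - dP1 * dP2`, where `dP2` is the single-pulse
#' deviation in the base window and `dP1` the deviation with the window
#' shifted by the inter-pulse delay.
#'
#' @param P0 baseline summed probability.
#' @param dP1,dP2 deviation terms of the first (shifted window) and
#'   second pulse.
#' @return predicted probability.
#' @export
two_pulse_independent_prediction <- function(P0, dP1, dP2) {
  P0 + dP1 + dP2 - dP1 * dP2
}

#' Two-pulse facilitation index with bootstrap CI
#'
#' Compares the observed early-lick probability after two fast pulses at
#' each delay with the independent prediction from the single-pulse
#' analysis: `I = (P_obs - P_Ind) / P_Ind`. Confidence intervals come
#' from resampling licks (the bootstrap unit) with replacement.
#'
#' @param table output of [single_pulse_lick_probability()].
#' @param n_boot bootstrap repetitions (default 4000).
#' @param seed optional integer seed.
#' @param probs bootstrap percentiles of the per-delay CIs (default
#'   2.5/97.5; pass Bonferroni-adjusted levels for a simultaneous band
#'   across delays).
#' @return data.frame per delay: `delay`, `P_obs`, `P_ind`, `I`,
#'   `ci_lo`, `ci_hi` (bootstrap percentiles of `I` at `probs`).
#' @export
two_pulse_facilitation <- function(table, n_boot = 4000, seed = NULL,
                                   probs = c(0.025, 0.975)) {
  if (!is.null(seed)) set.seed(seed)
  cc <- table$counts
  n <- cc$n_trials
  nd <- length(cc$delays)
  # per-trial count matrix: column sums give every ratio needed, so a
  # bootstrap draw is a multinomial weighting of trials. The reference
  # level is the marginal (all-pulse) success probability of the matching
  # window: a pulse class's deviation is then measured against exactly
  # the background it replaces, which makes the independence prediction
  # first-order exact for a memoryless lick generator.
  M <- cbind(cc$elig_all, cc$succ_all,
             cc$elig_fast, cc$succ_fast,
             cc$elig_shift, cc$succ_shift,
             cc$elig_allsh, cc$succ_allsh,
             cc$elig_pair, cc$succ_pair)
  ind_from <- function(s) {
    # s: column sums of M (one row per bootstrap draw); returns list of
    # per-delay matrices of P_obs and P_ind
    P0 <- s[, 2] / pmax(s[, 1], 1)
    dP2 <- s[, 4] / pmax(s[, 3], 1) - P0
    p_obs <- p_ind <- matrix(NA_real_, nrow(s), nd)
    for (d in seq_len(nd)) {
      e1 <- s[, 4 + d]; s1 <- s[, 4 + nd + d]
      ea <- s[, 4 + 2 * nd + d]; sa <- s[, 4 + 3 * nd + d]
      ep <- s[, 4 + 4 * nd + d]; sp <- s[, 4 + 5 * nd + d]
      dP1 <- s1 / pmax(e1, 1) - sa / pmax(ea, 1)
      pi_ <- two_pulse_independent_prediction(P0, dP1, dP2)
      po <- sp / pmax(ep, 1)
      bad <- e1 == 0 | ea == 0 | ep == 0 | pi_ <= 0
      pi_[bad] <- NA_real_; po[bad] <- NA_real_
      p_ind[, d] <- pi_; p_obs[, d] <- po
    }
    list(p_obs = p_obs, p_ind = p_ind, I = (p_obs - p_ind) / p_ind)
  }
  tot <- matrix(colSums(M), 1)
  est <- ind_from(tot)
  W <- stats::rmultinom(n_boot, n, rep(1 / n, n))
  boot <- ind_from(crossprod(W, M))$I
  ci <- apply(boot, 2, stats::quantile, probs = probs, na.rm = TRUE)
  data.frame(delay = cc$delays,
             P_obs = as.numeric(est$p_obs), P_ind = as.numeric(est$p_ind),
             I = as.numeric(est$I), ci_lo = ci[1, ], ci_hi = ci[2, ])
}
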